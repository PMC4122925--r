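# Synteny blocks along fosmids: maximal runs of genes sharing an origin
# class, the bounding-couple occurrence matrix over the k(k+1)/2 unordered
# flank-class pairs, per-class mean block lengths, and hierarchical
# clustering of flank patterns.

SYNTENY_CLASSES <- c("archaeal_core", "lineage_core", "early_hgt",
                     "late_hgt", "other")

#' Build synteny blocks from one fosmid's ordered origin classes
#'
#' A block is a maximal run of contiguous genes with the same origin class,
#' in fosmid order (plain run-length encoding of the class string).
#'
#' @param classes character vector of per-gene origin classes in gene order.
#' @param fosmid fosmid id recorded in the output.
#' @return data.frame with `fosmid`, `class`, `start`, `end` (0-based
#'   half-open gene indices) and `length` (genes).
#' @export
build_blocks <- function(classes, fosmid = "fosmid") {
  if (!length(classes))
    return(data.frame(fosmid = character(), class = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  r <- rle(as.character(classes))
  end <- cumsum(r$lengths)
  data.frame(fosmid = fosmid, class = r$values,
             start = c(0L, head(end, -1)), end = end,
             length = r$lengths, stringsAsFactors = FALSE)
}

.couple_names <- function(classes) {
  k <- length(classes)
  out <- character(0)
  for (i in seq_len(k)) for (j in i:k)
    out <- c(out, paste(classes[i], classes[j], sep = "|"))
  out
}

#' Bounding-couple occurrence matrix
#'
#' For every interior block (a block with blocks on both sides), the
#' unordered pair of flanking classes increments one of the k(k+1)/2
#' couple categories.  Terminal blocks have at most one flank and are
#' excluded from the matrix but tallied separately so totals stay
#' auditable.  With `per_gene = TRUE` each gene of an interior block
#' contributes one count instead of one per block.
#'
#' @param blocks data.frame of blocks (rbind of [build_blocks()] results,
#'   possibly over many fosmids) with a `group` column (e.g. lineage x
#'   class) used as matrix row; defaults to `class`.
#' @param k_classes class vocabulary defining the couple columns.
#' @param per_gene count couples once per gene rather than once per block.
#' @return list with `matrix` (groups x couples counts), `terminal` (per
#'   group count of excluded terminal blocks) and `interior_total`.
#' @export
couple_matrix <- function(blocks, k_classes = SYNTENY_CLASSES,
                          per_gene = FALSE) {
  if (length(k_classes) < 1) stop("k_classes must contain at least 1 class")
  couples <- .couple_names(k_classes)
  if (!"group" %in% names(blocks)) blocks$group <- blocks$class
  groups <- sort(unique(blocks$group))
  m <- matrix(0L, length(groups), length(couples),
              dimnames = list(groups, couples))
  terminal <- setNames(integer(length(groups)), groups)
  if (nrow(blocks)) {
    for (f in unique(blocks$fosmid)) {
      b <- blocks[blocks$fosmid == f, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      n <- nrow(b)
      for (i in seq_len(n)) {
        if (i == 1 || i == n) {
          terminal[b$group[i]] <- terminal[b$group[i]] + 1L
          next
        }
        pair <- c(b$class[i - 1], b$class[i + 1])
        if (!all(pair %in% k_classes))
          stop("flank class outside k_classes: ", paste(pair, collapse = ", "))
        pair <- pair[order(match(pair, k_classes))]
        cp <- paste(pair, collapse = "|")
        w <- if (per_gene) b$length[i] else 1L
        m[b$group[i], cp] <- m[b$group[i], cp] + w
      }
    }
  }
  # interior_total counts interior blocks (or genes when per_gene = TRUE)
  list(matrix = m, terminal = terminal, interior_total = sum(m))
}

#' Mean synteny block length per origin class
#'
#' @param blocks block data.frame; a `group` column (lineage) is honoured.
#' @return data.frame `group`, `class`, `mean_length`, `n_blocks`; classes
#'   absent from a group are simply absent from the table (missing, not 0).
#' @export
mean_block_length <- function(blocks) {
  if (!"group" %in% names(blocks)) blocks$group <- "all"
  agg <- aggregate(length ~ group + class, data = blocks,
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  data.frame(group = agg$group, class = agg$class,
             mean_length = agg$length[, "mean"],
             n_blocks = as.integer(agg$length[, "n"]),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering of bounding-couple patterns
#'
#' Rows of the couple matrix are normalized to fractions, then clustered
#' by average-linkage agglomeration on Euclidean distances.  Rows are
#' sorted by label first so ties resolve deterministically.
#'
#' @param m couple count matrix (groups x couples).
#' @return list with `hclust`, `order` (leaf labels in dendrogram order)
#'   and `newick` (dendrogram as a Newick string).
#' @export
cluster_couple_patterns <- function(m) {
  if (nrow(m) < 2) {
    return(list(hclust = NULL, order = rownames(m),
                newick = if (nrow(m)) paste0("(", rownames(m), ");") else ";"))
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  rs <- rowSums(m)
  norm <- sweep(m, 1, pmax(rs, 1), `/`)
  hc <- hclust(dist(norm), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}
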