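# Tree-based HGT calling: alignment trimming, neighbor-joining tree
# inference with bootstrap supports, the topology-reading verdict rules
# (nesting within a donor phylum; isolation among bacteria), early/late
# timing, and donor spectra.
#
# All topology tests work on unrooted bipartitions, so verdicts do not
# depend on how the input Newick happens to be rooted or on leaf order.

#' Taxonomy map for gene-tree leaves
#'
#' @param leaf leaf labels.
#' @param domain one of `Archaea`, `Bacteria`, `Eucarya` per leaf.
#' @param phylum phylum/class label or `NA` per leaf.
#' @param is_query logical; `TRUE` for query (fosmid) leaves.
#' @return data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(leaf, domain, phylum = NA_character_,
                         is_query = FALSE) {
  out <- data.frame(leaf = as.character(leaf), domain = as.character(domain),
                    phylum = as.character(phylum),
                    is_query = rep_len(as.logical(is_query), length(leaf)),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Remove high-gap columns from an alignment
#'
#' Drops every column whose gap fraction strictly exceeds
#' `max_gap_fraction` (a column at exactly the threshold is retained);
#' row order is preserved.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or a character matrix (rows = sequences).
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.2).
#' @param gap_chars characters counted as gaps.
#' @return trimmed alignment in the input representation.
#' @export
trim_alignment <- function(alignment, max_gap_fraction = 0.2,
                           gap_chars = c("-", ".")) {
  was_vec <- !is.matrix(alignment)
  m <- if (was_vec) {
    if (length(unique(nchar(alignment))) != 1)
      stop("aligned sequences must have equal length")
    do.call(rbind, strsplit(alignment, ""))
  } else alignment
  gapfrac <- colMeans(matrix(m %in% gap_chars, nrow(m)))
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("all columns removed by gap trimming")
  m <- m[, keep, drop = FALSE]
  if (was_vec)
    setNames(apply(m, 1, paste, collapse = ""), names(alignment))
  else m
}

# per-site match/comparable stacks for Poisson-corrected protein distances
# (pairwise deletion of gap sites); a bootstrap replicate is then a single
# matrix product with a site-weight vector
.site_stacks <- function(m, gap_chars = c("-", ".", "X")) {
  n <- nrow(m); L <- ncol(m)
  ok <- !(m %in% gap_chars); dim(ok) <- dim(m)
  match_site <- matrix(0, n * n, L)
  comp_site <- matrix(0, n * n, L)
  for (s in seq_len(L)) {
    okc <- ok[, s]
    eq <- outer(m[, s], m[, s], `==`) & outer(okc, okc, `&`)
    match_site[, s] <- as.numeric(eq)
    comp_site[, s] <- as.numeric(outer(okc, okc, `&`))
  }
  list(match = match_site, comp = comp_site, n = n)
}

.dist_from_stacks <- function(st, weights) {
  matches <- matrix(st$match %*% weights, st$n, st$n)
  comparable <- matrix(st$comp %*% weights, st$n, st$n)
  p <- pmin(1 - matches / pmax(comparable, 1), 0.95)
  d <- -log(1 - p)
  diag(d) <- 0
  as.dist(d)
}

.nj_tree <- function(d, labels) {
  dm <- as.matrix(d)
  dimnames(dm) <- list(labels, labels)
  tr <- tryCatch(ape::bionj(as.dist(dm)), error = function(e) ape::nj(as.dist(dm)))
  tr
}

#' Infer a gene tree by neighbor joining with bootstrap supports
#'
#' Computes Poisson-corrected pairwise protein distances (pairwise
#' deletion of gap sites), builds a BIONJ tree, and attaches bipartition
#' bootstrap supports in \[0,1\] as internal node labels.  Alternatively
#' parses a user-supplied Newick (`method = "external"`).
#'
#' @param alignment named character vector of aligned amino-acid sequences
#'   (>= 4 rows for inference).
#' @param method `"nj"` (default) or `"external"`.
#' @param seed integer seed for the bootstrap.
#' @param n_boot bootstrap replicates (default 100).
#' @param newick Newick string or file for `method = "external"`.
#' @return `phylo` object with `node.label` carrying supports in \[0,1\].
#' @export
infer_tree <- function(alignment, method = c("nj", "external"), seed = 1,
                       n_boot = 100, newick = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    tr <- if (file.exists(newick %||% "")) ape::read.tree(newick)
          else ape::read.tree(text = newick)
    return(tr)
  }
  if (length(alignment) < 4)
    stop("fewer than four homologous sequences; cluster must be excluded")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  st <- .site_stacks(m)
  L <- ncol(m)
  tr <- .nj_tree(.dist_from_stacks(st, rep(1, L)), rownames(m))
  if (n_boot > 0) {
    set.seed(seed)
    w <- matrix(0, L, n_boot)
    for (b in seq_len(n_boot))
      w[, b] <- tabulate(sample.int(L, L, replace = TRUE), L)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot))
      boots[[b]] <- .nj_tree(.dist_from_stacks(st, w[, b]), rownames(m))
    cnt <- ape::prop.clades(tr, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tr$node.label <- as.character(round(cnt / n_boot, 3))
  }
  tr
}

# --- bipartition machinery -------------------------------------------------

# numeric supports from node labels; percentages normalized to [0,1]
.node_supports <- function(tree) {
  nl <- tree$node.label
  nn <- tree$Nnode
  if (is.null(nl)) return(rep(0, nn))
  sup <- suppressWarnings(as.numeric(nl))
  sup[is.na(sup)] <- 0
  if (any(sup > 1)) sup <- sup / 100
  length(sup) <- nn
  sup[is.na(sup)] <- 0
  sup
}

# list every unrooted bipartition of the tree with its support.  The tree
# is traversed as given (rooted or not): in a rooted binary tree the two
# root edges represent the same split and may carry different labels, so
# splits are deduplicated and their supports merged with max.  Pendant
# edges carry no support (NA).
.edge_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  sup <- .node_supports(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  clade <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) clade[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }
  edges <- tree$edge
  all_tips <- sort(tree$tip.label)
  first <- all_tips[1]
  nr <- nrow(edges)
  keys <- character(nr); clades <- vector("list", nr)
  support_raw <- rep(NA_real_, nr)
  for (e in seq_len(nr)) {
    ch <- edges[e, 2]
    s <- sort(clade[[ch]])
    canon <- if (first %in% s) setdiff(all_tips, s) else s
    keys[e] <- paste(canon, collapse = "\r")
    clades[[e]] <- s
    if (ch > n) support_raw[e] <- sup[ch - n]
  }
  # splits cutting off a single tip are trivial: never supported
  triv <- vapply(clades, function(s)
    min(length(s), length(all_tips) - length(s)) <= 1, logical(1))
  support_raw[triv] <- NA_real_
  msup <- tapply(support_raw, keys, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- which(!duplicated(keys) & nchar(keys) > 0)
  list(tree = tree, edge = edges[keep, , drop = FALSE],
       full_edge = edges, clades = clades[keep],
       support = as.numeric(msup[keys[keep]]), tips = all_tips)
}

#' Call horizontal transfer from one gene tree
#'
#' Applies, in order, the operational rules for reading a gene tree against
#' its leaf taxonomy:
#'
#' 1. Trees with fewer than 4 informative non-query leaves are `excluded`.
#' 2. Query monophyly is tested on unrooted bipartitions: some edge must
#'    split exactly the query leaves from the rest with support at least
#'    `min_support`; otherwise the verdict is `unresolved`.  A single query
#'    leaf is trivially monophyletic with support 1.
#' 3. Nesting (criterion `nested_in_phylum`): the smallest enclosing clade
#'    of the query with at least `nest_min_nonquery` non-query leaves must
#'    be at least 90% bacterial, at least 80% one bacterial phylum, and
#'    supported; if so the verdict is `hgt` with that phylum as donor.
#'    Only clades the query branches strictly inside of count (the clade's
#'    defining edge must not touch the query's attachment node; a query
#'    merely sister to a phylum clade is not nested).  Size ties resolve to
#'    fewer non-query leaves, then to the clade whose defining edge is
#'    topologically closest to the query clade (the outward-walk order),
#'    then to the lexicographically smallest leaf set.
#' 4. Isolation (criterion `isolated_among_bacteria`): if the tree holds at
#'    least `min_bacterial_leaves` bacterial leaves from at least
#'    `min_bacterial_phyla` phyla, and either no other archaeal leaf exists
#'    or the query clade lies under at least two supported enclosing clades
#'    that contain no other archaeon and are bacterial-majority (so every
#'    path from the query to another archaeal leaf crosses them), the
#'    verdict is `hgt` with donor domain Bacteria and phylum unassigned.
#' 5. Trees mixing archaeal and bacterial leaves with no supported internal
#'    edge at all are `excluded`; everything else is `native`.
#'
#' @param tree `phylo` gene tree with supports in `node.label`
#'   (missing/blank supports count as 0; percentages are normalized).
#' @param tax [taxonomy_map()] covering every leaf.
#' @param min_support minimum bipartition support for a decision (0.8).
#' @param min_bacterial_phyla minimum distinct bacterial phyla for the
#'   isolation criterion (3).
#' @param min_bacterial_leaves minimum bacterial leaf count for the
#'   isolation criterion (10).
#' @param nest_min_nonquery smallest enclosing clade must contain at least
#'   this many non-query leaves (5).
#' @param nest_bacterial_purity minimum bacterial fraction of the enclosing
#'   clade (0.9).
#' @param nest_phylum_purity minimum single-phylum fraction of the
#'   enclosing clade (0.8).
#' @param cluster_id id recorded in the verdict.
#' @return one-row data.frame: `cluster_id`, `status` (`native`, `hgt`,
#'   `unresolved`, `excluded`), `criterion` (`nested_in_phylum`,
#'   `isolated_among_bacteria`, `none`), `donor_domain`, `donor_phylum`,
#'   `timing` (filled later by [time_transfer()]), `support_at_decision`.
#' @export
call_hgt <- function(tree, tax, min_support = 0.8, min_bacterial_phyla = 3,
                     min_bacterial_leaves = 10, nest_min_nonquery = 5,
                     nest_bacterial_purity = 0.9, nest_phylum_purity = 0.8,
                     cluster_id = "cluster") {
  verdict <- function(status, criterion = "none", donor_domain = NA_character_,
                      donor_phylum = NA_character_, support = NA_real_) {
    data.frame(cluster_id = cluster_id, status = status, criterion = criterion,
               donor_domain = donor_domain, donor_phylum = donor_phylum,
               timing = "n/a", support_at_decision = support,
               stringsAsFactors = FALSE)
  }
  leaves <- tree$tip.label
  miss <- setdiff(leaves, tax$leaf)
  if (length(miss)) stop("leaves missing from taxonomy: ",
                         paste(miss, collapse = ", "))
  dom <- setNames(tax$domain, tax$leaf)
  phy <- setNames(tax$phylum, tax$leaf)
  queries <- intersect(leaves, tax$leaf[tax$is_query])
  if (!length(queries)) stop("tree has no query leaves")
  qset <- sort(queries)
  nonq <- setdiff(leaves, queries)
  if (length(nonq) < 4) return(verdict("excluded"))

  bip <- .edge_bipartitions(tree)
  comp <- function(s) sort(setdiff(bip$tips, s))

  # (a) query monophyly
  qedge <- which(vapply(bip$clades, function(s)
    identical(s, qset) || identical(comp(s), qset), logical(1)))
  if (length(qset) == 1) {
    msup <- 1
  } else {
    if (!length(qedge)) return(verdict("unresolved"))
    msup <- max(c(bip$support[qedge], 0), na.rm = TRUE)
    if (msup < min_support)
      return(verdict("unresolved", support = msup))
  }

  # node at which the query clade attaches to the rest of the tree, and
  # topological node distances from it (for the outward-walk order)
  e0 <- bip$edge[qedge[1], ]
  q_att <- if (identical(bip$clades[[qedge[1]]], qset)) e0[1] else e0[2]
  gtree <- igraph::graph_from_edgelist(apply(bip$full_edge, 2, as.character),
                                       directed = FALSE)
  ndist <- igraph::distances(gtree, v = as.character(q_att))[1, ]

  # enclosing clades: bipartition sides containing every query leaf
  sides <- list(); side_sup <- numeric(0); side_dist <- numeric(0)
  for (i in seq_along(bip$clades)) {
    s <- bip$clades[[i]]
    enclosing <- if (all(qset %in% s)) s
                 else if (all(qset %in% comp(s))) comp(s) else NULL
    if (is.null(enclosing)) next
    sides[[length(sides) + 1L]] <- enclosing
    side_sup <- c(side_sup, bip$support[i])
    side_dist <- c(side_dist,
                   min(ndist[as.character(bip$edge[i, ])]))
  }
  side_sup[is.na(side_sup)] <- 0

  # (b) criterion 1: nesting within a donor phylum.  The defining edge must
  # not be incident to the query's attachment node (side_dist >= 1):
  # otherwise the query is basal/sister to the clade, not nested inside it.
  k_nonq <- vapply(sides, function(s) length(setdiff(s, qset)), integer(1))
  cand <- which(k_nonq >= nest_min_nonquery & side_dist >= 1)
  if (length(cand)) {
    sz <- lengths(sides)[cand]
    key <- vapply(sides[cand], paste, character(1), collapse = "\r")
    best <- cand[order(sz, k_nonq[cand], side_dist[cand], key)][1]
    nq <- setdiff(sides[[best]], qset)
    frac_bact <- mean(dom[nq] == "Bacteria")
    bact_nq <- nq[dom[nq] == "Bacteria"]
    if (length(bact_nq)) {
      tabp <- sort(table(phy[bact_nq]), decreasing = TRUE)
      top_phy <- names(tabp)[1]
      frac_top <- tabp[[1]] / length(nq)
    } else {
      top_phy <- NA_character_; frac_top <- 0
    }
    if (frac_bact >= nest_bacterial_purity &&
        frac_top >= nest_phylum_purity &&
        side_sup[best] >= min_support) {
      return(verdict("hgt", "nested_in_phylum", "Bacteria", top_phy,
                     side_sup[best]))
    }
  }

  # (c) criterion 2: query isolated among many bacteria
  bact <- nonq[dom[nonq] == "Bacteria"]
  other_arch <- nonq[dom[nonq] == "Archaea"]
  if (length(bact) >= min_bacterial_leaves &&
      length(unique(phy[bact][!is.na(phy[bact])])) >= min_bacterial_phyla) {
    # enclosing clades of the query that contain no other archaeon and are
    # bacterial-majority: every path to another archaeal leaf must cross
    # all of them, so >= 2 such supported clades bury the query among
    # bacteria
    cnt <- 0L
    for (i in seq_along(sides)) {
      nq <- setdiff(sides[[i]], qset)
      if (!length(nq)) next
      if (any(dom[nq] == "Archaea")) next
      if (side_sup[i] >= min_support && mean(dom[nq] == "Bacteria") > 0.5)
        cnt <- cnt + 1L
    }
    isolated <- length(other_arch) == 0 || cnt >= 2
    if (isolated)
      return(verdict("hgt", "isolated_among_bacteria", "Bacteria",
                     NA_character_, msup))
  }

  # (d) intermixed domains with no supported structure at all
  any_supported <- any(bip$support >= min_support, na.rm = TRUE)
  if (!any_supported && length(bact) && length(other_arch))
    return(verdict("excluded", support = msup))

  verdict("native", support = msup)
}

#' Time an HGT verdict from the cluster's pangenome class
#'
#' Transfers into the lineage-specific core happened at the base of the
#' lineage (`early`); transfers into the shell happened after its
#' diversification (`late`).  An archaeal-core cluster with an HGT verdict
#' is a conflict: flagged, timing stays `n/a`.
#'
#' @param verdicts verdict data.frame from [call_hgt()] rows.
#' @param classes named character vector: cluster id -> class.
#' @return `verdicts` with `timing` filled and a logical `conflict` column.
#' @export
time_transfer <- function(verdicts, classes) {
  cls <- classes[verdicts$cluster_id]
  is_hgt <- verdicts$status == "hgt"
  verdicts$timing <- ifelse(is_hgt & cls == "lineage_core", "early",
                     ifelse(is_hgt & cls == "shell", "late", "n/a"))
  verdicts$conflict <- is_hgt & cls == "archaeal_core"
  verdicts
}

#' Donor breakdown of HGT verdicts per timing class
#'
#' @param verdicts timed verdict data.frame.
#' @return named list per timing class (`early`, `late`) with `domains` and
#'   `phyla` fraction vectors (phylum `unassigned` collects calls without a
#'   phylum-level donor); each fraction vector sums to 1.  Empty timing
#'   classes are omitted.
#' @export
donor_spectrum <- function(verdicts) {
  hgt <- verdicts[verdicts$status == "hgt", , drop = FALSE]
  out <- list()
  for (tm in c("early", "late")) {
    v <- hgt[hgt$timing == tm, , drop = FALSE]
    if (!nrow(v)) next
    domains <- table(v$donor_domain) / nrow(v)
    ph <- ifelse(is.na(v$donor_phylum), "unassigned", v$donor_phylum)
    phyla <- table(ph) / nrow(v)
    out[[tm]] <- list(n = nrow(v),
                      domains = setNames(as.numeric(domains), names(domains)),
                      phyla = setNames(as.numeric(phyla), names(phyla)))
  }
  out
}

#' Write / read verdict tables
#' @param verdicts verdict data.frame.
#' @param file path.
#' @export
write_verdicts <- function(verdicts, file) {
  write.table(verdicts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_verdicts
#' @export
read_verdicts <- function(file) read.delim(file, stringsAsFactors = FALSE)
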