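# Compositional signatures: k-mer z-score profiles (tetra/penta), PCA
# embedding, and quality-threshold clustering of per-fosmid taxon profiles.

#' k-mer z-score profile of a nucleotide sequence
#'
#' Computes the standardized deviation of each k-mer count from its
#' maximal-order Markov expectation.  Counts are taken over both strands
#' (the sequence and its reverse complement, counted separately and
#' summed), so profiles are strand-symmetric by construction.  For a word
#' \eqn{w = n_1..n_k}, with \eqn{N()} denoting substring counts of the
#' (k-1)-mer prefix/suffix and the (k-2)-mer core,
#' \deqn{E = N(pref) N(suf) / N(core)}
#' \deqn{V = E (N(core)-N(pref)) (N(core)-N(suf)) / N(core)^2}
#' \deqn{z = (obs - E) / \sqrt{V}}
#' Words whose core is unobserved or whose variance is non-positive get
#' z = 0 and are flagged.
#'
#' @param sequence nucleotide string (A/C/G/T/N) or `DNAString`.
#' @param k word size, 4 (tetranucleotides, default) or 5; any k >= 2 works.
#' @param id record id carried into the result.
#' @return object of class `tetra_profile`: list with `id`, `k`, `z`
#'   (named numeric vector, length 4^k) and `undefined` (logical flag
#'   vector marking words with undefined variance).
#' @export
kmer_zscores <- function(sequence, k = 4, id = "seq") {
  if (k < 2) stop("k must be >= 2")
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < k + 2) stop("sequence shorter than k + 2")
  dna <- Biostrings::DNAString(sequence)
  rc <- Biostrings::reverseComplement(dna)
  count_w <- function(width) {
    Biostrings::oligonucleotideFrequency(dna, width = width) +
      Biostrings::oligonucleotideFrequency(rc, width = width)
  }
  nk <- count_w(k)
  nk1 <- count_w(k - 1)
  words <- names(nk)
  pref <- substr(words, 1, k - 1)
  suf <- substr(words, 2, k)
  Np <- unname(nk1[pref]); Ns <- unname(nk1[suf])
  if (k == 2) {
    # the (k-2)-mer core is the empty word; its count is the number of
    # single-base windows on the two strands
    Nc <- rep(2 * nchar(sequence), length(words))
  } else {
    nk2 <- count_w(k - 2)
    Nc <- unname(nk2[substr(words, 2, k - 1)])
  }
  E <- ifelse(Nc > 0, Np * Ns / Nc, 0)
  V <- ifelse(Nc > 0, E * (Nc - Np) * (Nc - Ns) / Nc^2, 0)
  undefined <- !(Nc > 0) | !(V > 0)
  z <- numeric(length(words))
  ok <- !undefined
  z[ok] <- (nk[ok] - E[ok]) / sqrt(V[ok])
  names(z) <- words
  structure(list(id = id, k = k, z = z, undefined = setNames(undefined, words)),
            class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  cat(sprintf("k-mer z-score profile '%s' (k = %d, %d words, %d undefined)\n",
              x$id, x$k, length(x$z), sum(x$undefined)))
  invisible(x)
}

#' Principal component embedding of profile rows
#'
#' Thin wrapper around covariance (or correlation) PCA with a fixed sign
#' convention: each component is flipped so that its largest-magnitude
#' loading is positive, making embeddings reproducible.
#'
#' @param x numeric matrix, one profile per row.
#' @param n_components number of components to return (default all).
#' @param scale. logical; `TRUE` for correlation PCA (default covariance).
#' @return list with `coordinates` (rows x components), `loadings`,
#'   `explained` (variance fractions, non-increasing), `center`, `scale`
#'   and `constant` (flag: input had zero total variance).
#' @export
pca_embed <- function(x, n_components = NULL, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  keep_sd <- apply(x, 2, sd)
  constant <- all(keep_sd == 0)
  if (constant) {
    nc <- min(n_components %||% 1, nrow(x) - 1)
    return(list(coordinates = matrix(0, nrow(x), nc,
                                     dimnames = list(rownames(x), NULL)),
                loadings = matrix(0, ncol(x), nc),
                explained = rep(0, nc), center = colMeans(x),
                scale = FALSE, constant = TRUE))
  }
  if (scale.) x_fit <- x[, keep_sd > 0, drop = FALSE] else x_fit <- x
  p <- prcomp(x_fit, center = TRUE, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  rot <- sweep(p$rotation, 2, flip, `*`)
  sco <- sweep(p$x, 2, flip, `*`)
  expl <- p$sdev^2 / sum(p$sdev^2)
  nc <- min(n_components %||% ncol(sco), ncol(sco))
  list(coordinates = sco[, seq_len(nc), drop = FALSE],
       loadings = rot[, seq_len(nc), drop = FALSE],
       explained = expl[seq_len(nc)],
       center = p$center, scale = if (scale.) p$scale else FALSE,
       constant = FALSE)
}

#' Quality-threshold clustering
#'
#' Greedy quality-threshold (QT) partitioning: repeatedly extract the
#' largest subset of profiles whose maximum pairwise distance does not
#' exceed `diameter` (a maximum clique of the threshold graph), then
#' recurse on the remainder.  Ties between equally large candidates are
#' broken by the lower cluster diameter, then by the lexicographically
#' smallest sorted member-id vector.  Singletons are allowed.
#'
#' @param x numeric matrix of profiles (rows = items, rownames = ids) or a
#'   `dist` object.
#' @param diameter maximum allowed within-cluster pairwise distance (> 0).
#'   The default of 30 is calibrated for percentage-vector taxon profiles.
#' @return list of character vectors of member ids (a partition of the
#'   input), largest cluster first.
#' @export
qt_cluster <- function(x, diameter = 30) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else {
    x <- as.matrix(x)
    if (!nrow(x)) return(list())
    d <- as.matrix(dist(x))
  }
  n <- nrow(d)
  if (!n) return(list())
  ids <- rownames(d) %||% as.character(seq_len(n))
  rownames(d) <- colnames(d) <- ids
  remaining <- ids
  out <- list()
  while (length(remaining)) {
    dr <- d[remaining, remaining, drop = FALSE]
    adj <- dr <= diameter
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::largest_cliques(g)
    cands <- lapply(cl, function(v) sort(remaining[as.integer(v)]))
    if (!length(cands)) cands <- list(remaining[1])
    diam <- vapply(cands, function(m) {
      if (length(m) == 1) 0 else max(dr[m, m])
    }, numeric(1))
    keylex <- vapply(cands, function(m) paste(m, collapse = "\r"), character(1))
    ord <- order(diam, keylex)
    best <- cands[[ord[1]]]
    out[[length(out) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  out
}

#' Per-fosmid taxon profile matrix
#'
#' Builds the fixed-category percentage matrix used for taxonomic binning:
#' for each fosmid, the percentage of its genes whose best-hit taxonomy
#' falls into each broad category.
#'
#' @param gene_tax data.frame with columns `fosmid` and `category` (one
#'   row per annotated gene; genes without assignment may be absent, so
#'   percentages can sum to less than 100 per domain level).
#' @param categories category vocabulary (columns of the result).
#' @return numeric matrix, fosmids x categories, in percent.
#' @export
taxon_profiles <- function(gene_tax,
                           categories = c("Archaea", "Bacteria", "Eucarya",
                                          "viruses", "Crenarchaeota",
                                          "Euryarchaeota", "Thaumarchaeota",
                                          "Nanoarchaeota", "Korarchaeota",
                                          "unclassified archaea")) {
  fos <- sort(unique(gene_tax$fosmid))
  m <- matrix(0, length(fos), length(categories),
              dimnames = list(fos, categories))
  tot <- table(gene_tax$fosmid)
  tab <- table(gene_tax$fosmid, factor(gene_tax$category, levels = categories))
  m[rownames(tab), ] <- 100 * sweep(unclass(tab), 1,
                                    as.numeric(tot[rownames(tab)]), `/`)
  m
}
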