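# Independent oracles: deliberately naive re-derivations of the quantities
# the package computes, used to cross-check the implementations.

# six-frame ORF scanner: walks every position of both strands explicitly
oracle_find_orfs <- function(sequence, min_aa) {
  sequence <- toupper(sequence)
  gc11 <- Biostrings::getGeneticCode("11")
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  L <- nchar(sequence)
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (f in 0:2) {
      pos <- f + 1
      seg_start <- pos
      while (pos + 2 <= nchar(s)) {
        cod <- substr(s, pos, pos + 2)
        if (cod %in% stops) {
          # scan segment [seg_start, pos) for first start codon
          p <- seg_start
          first_start <- NA
          while (p < pos) {
            if (substr(s, p, p + 2) %in% starts) { first_start <- p; break }
            p <- p + 3
          }
          if (!is.na(first_start)) {
            aa_len <- (pos - first_start) / 3
            if (aa_len >= min_aa) {
              tr <- character(0)
              for (q in seq(first_start, pos - 3, by = 3)) {
                c3 <- substr(s, q, q + 2)
                a <- gc11[c3]
                tr <- c(tr, if (is.na(a)) "X" else unname(a))
              }
              s0 <- first_start - 1; e0 <- pos + 2
              if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
              out[[length(out) + 1]] <- data.frame(
                start = s0, end = e0, strand = strand,
                translation = paste(tr, collapse = ""),
                stringsAsFactors = FALSE)
            }
          }
          seg_start <- pos + 3
        }
        pos <- pos + 3
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), translation = character()))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# direct-enumeration k-mer z-scores: counts every substring occurrence on
# the two strands by explicit position loops
oracle_kmer_z <- function(sequence, k) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(sequence), "")[[1]]
  strands <- list(chars, rev(unname(comp[chars])))
  # direct enumeration: every substring of every width, tabulated
  counts <- list()
  for (w in seq(max(k - 2, 1), k)) {
    subs <- character(0)
    for (s in strands) {
      L <- length(s)
      if (L >= w)
        subs <- c(subs, vapply(seq_len(L - w + 1), function(i)
          paste(s[i:(i + w - 1)], collapse = ""), character(1)))
    }
    counts[[as.character(w)]] <- table(subs)
  }
  count <- function(word) {
    w <- nchar(word)
    if (w == 0) return(2 * length(chars))
    x <- counts[[as.character(w)]][word]
    if (is.na(x)) 0 else unname(x)
  }
  bases <- c("A", "C", "G", "T")
  words <- apply(expand.grid(rep(list(bases), k))[, k:1, drop = FALSE], 1,
                 paste, collapse = "")
  z <- setNames(numeric(length(words)), words)
  for (w in words) {
    obs <- count(w)
    Np <- count(substr(w, 1, k - 1))
    Ns <- count(substr(w, 2, k))
    Nc <- count(substr(w, 2, k - 1))
    if (Nc > 0) {
      E <- Np * Ns / Nc
      V <- E * (Nc - Np) * (Nc - Ns) / Nc^2
      if (V > 0) z[w] <- (obs - E) / sqrt(V)
    }
  }
  z
}

# brute-force QT clustering: enumerate every subset (n <= 12) with diameter
# within the bound, pick largest / lowest diameter / smallest ids, recurse
oracle_qt <- function(x, diameter) {
  d <- as.matrix(dist(x))
  ids <- rownames(x)
  rownames(d) <- colnames(d) <- ids
  pick <- function(remaining) {
    n <- length(remaining)
    best <- NULL; best_key <- NULL
    for (mask in seq_len(2^n - 1)) {
      mem <- remaining[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
      dm <- if (length(mem) == 1) 0 else max(d[mem, mem])
      if (dm > diameter) next
      key <- list(-length(mem), dm, paste(sort(mem), collapse = "\r"))
      if (is.null(best) ||
          key[[1]] < best_key[[1]] ||
          (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
          (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
           key[[3]] < best_key[[3]])) {
        best <- sort(mem); best_key <- key
      }
    }
    best
  }
  remaining <- ids
  out <- list()
  while (length(remaining)) {
    cl <- pick(remaining)
    out[[length(out) + 1]] <- cl
    remaining <- setdiff(remaining, cl)
  }
  out
}

# exhaustive bipartition HGT oracle: extracts every bipartition by deleting
# tree edges in an igraph copy, then applies the verdict rules literally
oracle_call_hgt <- function(tree, tax, min_support = 0.8,
                            min_bacterial_phyla = 3,
                            min_bacterial_leaves = 10,
                            nest_min_nonquery = 5,
                            nest_bacterial_purity = 0.9,
                            nest_phylum_purity = 0.8) {
  tru <- tree
  n <- length(tru$tip.label)
  sup <- suppressWarnings(as.numeric(tru$node.label))
  sup[is.na(sup)] <- 0
  if (any(sup > 1)) sup <- sup / 100
  length(sup) <- tru$Nnode
  sup[is.na(sup)] <- 0
  dom <- setNames(tax$domain, tax$leaf)
  phy <- setNames(tax$phylum, tax$leaf)
  queries <- sort(intersect(tru$tip.label, tax$leaf[tax$is_query]))
  nonq <- setdiff(tru$tip.label, queries)
  if (!length(queries)) stop("no query leaves")
  if (length(nonq) < 4) return("excluded")

  alltips <- sort(tru$tip.label)
  comp_of <- function(s) sort(setdiff(alltips, s))

  el <- apply(tru$edge, 2, as.character)
  raw_splits <- list(); raw_sup <- numeric(0); raw_key <- character(0)
  for (e in seq_len(nrow(el))) {
    g2 <- igraph::graph_from_edgelist(el[-e, , drop = FALSE], directed = FALSE)
    miss <- setdiff(as.vector(el), igraph::V(g2)$name)
    if (length(miss)) g2 <- igraph::add_vertices(g2, length(miss), name = miss)
    comp <- igraph::components(g2)$membership
    side_nodes <- names(comp)[comp == comp[[el[e, 2]]]]
    tips <- as.integer(side_nodes)[as.integer(side_nodes) <= n]
    s <- sort(tru$tip.label[tips])
    raw_splits[[e]] <- s
    child <- as.integer(el[e, 2])
    raw_sup[e] <- if (child > n &&
                      min(length(s), n - length(s)) > 1) sup[child - n] else NA
    canon <- if (alltips[1] %in% s) comp_of(s) else s
    raw_key[e] <- paste(canon, collapse = "\r")
  }
  keep <- which(!duplicated(raw_key))
  splits <- raw_splits[keep]
  ssup <- vapply(raw_key[keep], function(kk) {
    x <- raw_sup[raw_key == kk]
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }, numeric(1))

  qedge <- which(vapply(splits, function(s)
    identical(s, queries) || identical(comp_of(s), queries), logical(1)))
  if (length(queries) == 1) {
    msup <- 1
  } else {
    if (!length(qedge)) return("unresolved")
    msup <- max(c(ssup[qedge], 0), na.rm = TRUE)
    if (msup < min_support) return("unresolved")
  }

  e0 <- tru$edge[keep[qedge[1]], ]
  q_att <- if (identical(splits[[qedge[1]]], queries)) e0[1] else e0[2]
  gfull <- igraph::graph_from_edgelist(el, directed = FALSE)
  ndist <- igraph::distances(gfull, v = as.character(q_att))[1, ]

  sides <- list(); side_sup <- numeric(0); side_dist <- numeric(0)
  for (e in seq_along(splits)) {
    s <- splits[[e]]
    enc <- if (all(queries %in% s)) s
           else if (all(queries %in% comp_of(s))) comp_of(s) else NULL
    if (is.null(enc)) next
    sides[[length(sides) + 1]] <- enc
    side_sup <- c(side_sup, ssup[e])
    side_dist <- c(side_dist, min(ndist[el[keep[e], ]]))
  }
  side_sup[is.na(side_sup)] <- 0

  k_nonq <- vapply(sides, function(s) length(setdiff(s, queries)), integer(1))
  cand <- which(k_nonq >= nest_min_nonquery & side_dist >= 1)
  if (length(cand)) {
    sz <- lengths(sides)[cand]
    key <- vapply(sides[cand], paste, character(1), collapse = "\r")
    best <- cand[order(sz, k_nonq[cand], side_dist[cand], key)][1]
    nq <- setdiff(sides[[best]], queries)
    frac_bact <- mean(dom[nq] == "Bacteria")
    bnq <- nq[dom[nq] == "Bacteria"]
    frac_top <- if (length(bnq))
      max(table(phy[bnq])) / length(nq) else 0
    if (frac_bact >= nest_bacterial_purity && frac_top >= nest_phylum_purity &&
        side_sup[best] >= min_support)
      return("hgt")
  }

  bact <- nonq[dom[nonq] == "Bacteria"]
  other_arch <- nonq[dom[nonq] == "Archaea"]
  if (length(bact) >= min_bacterial_leaves &&
      length(unique(phy[bact][!is.na(phy[bact])])) >= min_bacterial_phyla) {
    cnt <- 0
    for (i in seq_along(sides)) {
      nq <- setdiff(sides[[i]], queries)
      if (!length(nq) || any(dom[nq] == "Archaea")) next
      if (side_sup[i] >= min_support && mean(dom[nq] == "Bacteria") > 0.5)
        cnt <- cnt + 1
    }
    if (length(other_arch) == 0 || cnt >= 2) return("hgt")
  }

  if (!any(ssup >= min_support, na.rm = TRUE) &&
      length(bact) && length(other_arch))
    return("excluded")
  "native"
}

# random supported tree plus taxonomy for property tests
random_hgt_case <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_leaves))
  # unrooted labeling: one support label per split, as bootstrap would give
  tr$node.label <- as.character(sample(c(0, 0.5, 0.85, 0.95, 1),
                                       tr$Nnode, replace = TRUE))
  n_q <- sample.int(max(1, n_leaves - 4), 1)
  is_q <- c(rep(TRUE, n_q), rep(FALSE, n_leaves - n_q))[sample.int(n_leaves)]
  dom <- ifelse(is_q, "Archaea",
                sample(c("Bacteria", "Bacteria", "Bacteria", "Archaea",
                         "Eucarya"), n_leaves, replace = TRUE))
  phylum <- ifelse(dom == "Bacteria",
                   sample(c("Proteobacteria", "Firmicutes", "Actinobacteria"),
                          n_leaves, replace = TRUE),
                   ifelse(is_q, "query", NA))
  list(tree = tr,
       tax = taxonomy_map(tr$tip.label, dom, phylum, is_query = is_q))
}

# adjusted Rand index between two labelings of the same items
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  expct <- si * sj / ch2(sum(tab))
  (sij - expct) / ((si + sj) / 2 - expct)
}

# small shared community for cross-module tests (built once per run)
tiny_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- community_config(n_genomes = c(thaum = 5, gii_iii = 4),
                              n_families = 40, n_marker_families = 5,
                              n_ribosomal_families = 4, seed = 7)
      fo <- simulate_species_forest(cfg)
      lib <- emit_fosmid_library(cfg, fo)
      cache <<- list(cfg = cfg, forest = fo, lib = lib)
    }
    cache
  }
})
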