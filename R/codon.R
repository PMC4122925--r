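# Codon usage tables, the codon adaptation index (CAI) against a
# highly-expressed reference set, and codon-usage PCA across gene classes.
#
# CAI follows the Sharp-Li conventions: relative adaptiveness
# w(codon) = f(codon) / max f over its synonym family, computed from the
# reference set with unseen codons smoothed to 0.5 counts; a gene's CAI is
# the geometric mean of w over its codons, excluding Met, Trp and stops
# (amino acids without synonymous choice carry no information).

.codon_universe <- function() {
  gc <- Biostrings::getGeneticCode("11")
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
}

.split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Codon usage table from a reference gene set
#'
#' Counts codons over all reference CDSs (stop codons excluded), smooths
#' zero-count codons to 0.5 before computing synonymous frequencies and
#' relative adaptiveness.  Genes with premature internal stop codons are
#' skipped with a warning.
#'
#' @param cds character vector of in-frame nucleotide CDSs (lengths
#'   divisible by 3; trailing stop codons allowed and ignored).
#' @return object of class `codon_usage`: data.frame with `codon`, `aa`,
#'   `count`, `frequency` (within synonym family, summing to 1 per amino
#'   acid) and `w` (relative adaptiveness, max 1 per family).
#' @export
usage_table <- function(cds) {
  uni <- .codon_universe()
  counts <- setNames(numeric(nrow(uni)), uni$codon)
  skipped <- 0L
  for (g in cds) {
    cods <- .split_codons(g)
    aa <- uni$aa[match(cods, uni$codon)]
    # trailing stop is fine; internal stops disqualify the gene
    if (length(cods) > 1 && any(aa[-length(aa)] == "*", na.rm = TRUE)) {
      skipped <- skipped + 1L
      next
    }
    cods <- cods[!is.na(aa) & aa != "*"]
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.numeric(t)
  }
  if (skipped) warning(skipped, " gene(s) with internal stops skipped")
  keep <- uni$aa != "*"
  tab <- uni[keep, , drop = FALSE]
  tab$count <- counts[tab$codon]
  smoothed <- ifelse(tab$count == 0, 0.5, tab$count)
  tab$frequency <- stats::ave(smoothed, tab$aa, FUN = function(x) x / sum(x))
  tab$w <- stats::ave(smoothed, tab$aa, FUN = function(x) x / max(x))
  rownames(tab) <- NULL
  class(tab) <- c("codon_usage", "data.frame")
  tab
}

#' Codon adaptation index of one gene
#'
#' Geometric mean of relative adaptiveness over the gene's codons,
#' excluding Met (ATG), Trp (TGG) and stop codons.
#'
#' @param cds in-frame nucleotide CDS.
#' @param table a `codon_usage` reference table from [usage_table()].
#' @param gene_id id recorded in the result.
#' @return one-row data.frame: `gene_id`, `cai` (in (0,1], or `NA` when no
#'   countable codon exists), `n_codons` used, `flagged`.
#' @export
cai <- function(cds, table, gene_id = "gene") {
  cods <- .split_codons(cds)
  uni <- .codon_universe()
  aa <- uni$aa[match(cods, uni$codon)]
  use <- !is.na(aa) & !(aa %in% c("*", "M", "W"))
  cods <- cods[use]
  if (!length(cods))
    return(data.frame(gene_id = gene_id, cai = NA_real_, n_codons = 0L,
                      flagged = TRUE, stringsAsFactors = FALSE))
  w <- table$w[match(cods, table$codon)]
  data.frame(gene_id = gene_id, cai = exp(mean(log(w))),
             n_codons = length(cods), flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Per-gene synonymous codon frequency vectors
#'
#' 59-dimensional vectors (61 sense codons minus ATG and TGG): for each
#' codon, its frequency among the gene's codons for the same amino acid
#' (0 when the amino acid is absent from the gene).
#'
#' @param cds named character vector of in-frame CDSs.
#' @return numeric matrix, genes x 59 codons.  Genes using a single codon
#'   overall are flagged via the `degenerate` attribute.
#' @export
codon_frequency_matrix <- function(cds) {
  uni <- .codon_universe()
  keep <- uni$aa != "*" & !(uni$codon %in% c("ATG", "TGG"))
  cod59 <- uni$codon[keep]
  aa59 <- uni$aa[keep]
  m <- matrix(0, length(cds), length(cod59),
              dimnames = list(names(cds), cod59))
  degenerate <- logical(length(cds))
  for (i in seq_along(cds)) {
    cods <- .split_codons(cds[[i]])
    cods <- cods[cods %in% cod59]
    if (length(unique(cods)) <= 1) degenerate[i] <- TRUE
    cnt <- setNames(numeric(length(cod59)), cod59)
    t <- table(cods)
    cnt[names(t)] <- as.numeric(t)
    aatot <- tapply(cnt, aa59, sum)[aa59]
    m[i, ] <- ifelse(aatot > 0, cnt / aatot, 0)
  }
  attr(m, "degenerate") <- degenerate
  m
}

#' PCA of codon usage across genes
#'
#' Embeds per-gene synonymous-frequency vectors with [pca_embed()]; group
#' labels (lineage, origin class) are carried through for plotting.
#'
#' @param cds named character vector of in-frame CDSs (>= 2 genes).
#' @param groups optional factor/character of group labels per gene.
#' @param n_components number of components (default 2).
#' @return the [pca_embed()] result with an added `groups` element.
#' @export
usage_pca <- function(cds, groups = NULL, n_components = 2) {
  m <- codon_frequency_matrix(cds)
  emb <- pca_embed(m, n_components = n_components)
  emb$groups <- groups
  emb$degenerate <- attr(m, "degenerate")
  emb
}
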