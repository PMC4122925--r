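# Gene finding, gene validation, and the pipeline's on-disk formats.
#
# Coordinates are 0-based half-open on the forward strand everywhere in
# memory and in the feature-table TSV; the optional GFF3 writer converts to
# 1-based inclusive.  CDS coordinates include the stop codon, so a complete
# gene satisfies length(translation) == (end - start)/3 - 1.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# translation table 11 (bacterial/archaeal/plant-plastid); identical residue
# assignments to the standard code
.codon_table <- function() {
  gc <- Biostrings::getGeneticCode("11")
  gc[gc == "*"] <- "*"
  gc
}

.translate_codons <- function(codons) {
  gc <- .codon_table()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  aa
}

.check_nucleotides <- function(sequence) {
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters other than A, C, G, T, N")
}

.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Find candidate coding sequences on both strands
#'
#' Scans all six reading frames for maximal stop-to-stop segments and, within
#' each segment that is terminated by a stop codon, takes the first
#' downstream start codon (ATG/GTG/TTG) as the CDS start.  Translation uses
#' the bacterial/archaeal code (translation table 11); codons containing N
#' are translated as X.  Candidates shorter than `min_aa` amino acids
#' (stop excluded) are discarded.
#'
#' @param sequence nucleotide string over A,C,G,T,N (or a `DNAString`).
#' @param min_aa minimum translated length in amino acids (default 30).
#' @param id fosmid/record id recorded in the output.
#' @return data.frame with columns `gene_id`, `fosmid`, `start`, `end`
#'   (0-based half-open, forward strand, stop codon included), `strand`
#'   (`+`/`-`) and `translation`.
#' @export
find_orfs <- function(sequence, min_aa = 30, id = "seq") {
  if (min_aa < 1) stop("min_aa must be >= 1")
  sequence <- toupper(as.character(sequence))
  .check_nucleotides(sequence)
  L <- nchar(sequence)
  out <- list()
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 2) next
      starts_nt <- f + 3 * (seq_len(ncod) - 1) # 0-based codon starts
      codons <- substring(s, starts_nt + 1, starts_nt + 3)
      is_stop <- codons %in% STOP_CODONS
      stop_idx <- which(is_stop)
      if (!length(stop_idx)) next
      seg_begin <- c(1L, head(stop_idx, -1) + 1L) # first codon after prev stop
      for (j in seq_along(stop_idx)) {
        lo <- seg_begin[j]; hi <- stop_idx[j]
        if (hi <= lo) next
        cand <- which(codons[lo:(hi - 1)] %in% START_CODONS)
        if (!length(cand)) next
        i0 <- lo + cand[1] - 1L
        aa_len <- hi - i0
        if (aa_len < min_aa) next
        aa <- paste(.translate_codons(codons[i0:(hi - 1)]), collapse = "")
        s0 <- starts_nt[i0]; e0 <- starts_nt[hi] + 3L # stop included
        if (strand == "+") {
          out[[length(out) + 1L]] <<- data.frame(
            start = s0, end = e0, strand = "+", translation = aa,
            stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <<- data.frame(
            start = L - e0, end = L - s0, strand = "-", translation = aa,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (L >= 6) {
    scan_strand(sequence, "+")
    scan_strand(.revcomp(sequence), "-")
  }
  if (!length(out))
    return(data.frame(gene_id = character(), fosmid = character(),
                      start = integer(), end = integer(),
                      strand = character(), translation = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  res <- cbind(gene_id = sprintf("%s_orf%04d", id, seq_len(nrow(res))),
               fosmid = id, res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Validate candidate genes against a homology hit table
#'
#' Candidates with a database hit at e-value `<= evalue_gene` are accepted.
#' Candidates whose only evidence comes from motif/COG-style sources are
#' accepted at the laxer `evalue_motif`.  Small (< `min_orphan_aa` amino
#' acids) candidates without any hit are dropped; larger no-hit candidates
#' are retained as orphan genes.  Candidates overlapping structural-RNA
#' features are dropped.  With no hit table at all, every candidate passes
#' flagged as provisional.
#'
#' @param candidates data.frame as returned by [find_orfs()].
#' @param hit_table data.frame with columns `query`, `subject`, `e_value`
#'   and optionally `source` (`"motif"`/`"cog"` rows are treated as
#'   motif-level evidence); `NULL` for none.
#' @param evalue_gene inclusive e-value threshold for full gene validation.
#' @param evalue_motif inclusive e-value threshold for motif-only evidence.
#' @param rna_features optional data.frame (`fosmid`, `start`, `end`) of
#'   structural-RNA annotations (0-based half-open).
#' @param min_orphan_aa orphan candidates shorter than this are dropped.
#' @return the accepted subset of `candidates` with columns `status`
#'   (`validated`, `motif`, `orphan` or `provisional`) appended.
#' @export
validate_genes <- function(candidates, hit_table = NULL,
                           evalue_gene = 1e-10, evalue_motif = 1e-5,
                           rna_features = NULL, min_orphan_aa = 100) {
  if (!nrow(candidates)) return(cbind(candidates, status = character(0)))
  keep_rna <- rep(TRUE, nrow(candidates))
  if (!is.null(rna_features) && nrow(rna_features)) {
    for (i in seq_len(nrow(candidates))) {
      r <- rna_features[rna_features$fosmid == candidates$fosmid[i], , drop = FALSE]
      if (nrow(r) &&
          any(pmax(r$start, candidates$start[i]) < pmin(r$end, candidates$end[i])))
        keep_rna[i] <- FALSE
    }
  }
  if (is.null(hit_table)) {
    out <- candidates[keep_rna, , drop = FALSE]
    out$status <- "provisional"
    return(out)
  }
  if (!"source" %in% names(hit_table)) hit_table$source <- "db"
  motif_sources <- c("motif", "cog", "cdd")
  status <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    h <- hit_table[hit_table$query == candidates$gene_id[i], , drop = FALSE]
    aa_len <- nchar(candidates$translation[i])
    if (!nrow(h)) {
      status[i] <- if (aa_len < min_orphan_aa) "drop" else "orphan"
      next
    }
    full <- h[!(h$source %in% motif_sources), , drop = FALSE]
    if (nrow(full) && min(full$e_value) <= evalue_gene) {
      status[i] <- "validated"
    } else {
      mot <- h[h$source %in% motif_sources, , drop = FALSE]
      status[i] <- if (nrow(mot) && min(mot$e_value) <= evalue_motif)
        "motif" else if (aa_len < min_orphan_aa) "drop" else "orphan"
    }
  }
  keep <- keep_rna & status != "drop"
  out <- candidates[keep, , drop = FALSE]
  out$status <- status[keep]
  rownames(out) <- NULL
  out
}

#' Write a fosmid library (FASTA + feature table, optionally truth table)
#'
#' @param lib list with elements `fosmids` (named character vector or
#'   `DNAStringSet`), `features` (data.frame with 0-based half-open
#'   coordinates) and optionally `truth` (data.frame).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_fosmid_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- lib$fosmids
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, file.path(dir, "fosmids.fasta"), width = 80)
  write.table(lib$features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(lib$truth))
    write.table(lib$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a fosmid library written by [write_fosmid_library()]
#'
#' @param dir directory containing `fosmids.fasta` and `features.tsv`.
#' @return list with `fosmids` (named character vector), `features`, and
#'   `truth` if present.
#' @export
read_fosmid_library <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "fosmids.fasta"))
  fos <- setNames(as.character(seqs), names(seqs))
  feat <- read.delim(file.path(dir, "features.tsv"), stringsAsFactors = FALSE)
  truth <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) truth <- read.delim(tf, stringsAsFactors = FALSE)
  out <- list(fosmids = fos, features = feat)
  if (!is.null(truth)) out$truth <- truth
  out
}

#' Write features as GFF3 (1-based inclusive coordinates)
#'
#' @param features feature data.frame with 0-based half-open `start`/`end`.
#' @param file output path.
#' @export
write_gff3 <- function(features, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s;family_id=%s", features$gene_id,
                   features$family_id %||% rep(".", nrow(features)))
  lines <- sprintf("%s\tarchpan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   features$fosmid, features$start + 1L, features$end,
                   features$strand, attrs)
  writeLines(lines, con)
  invisible(file)
}

#' Read a tabular homology hit table
#'
#' Expects the de-facto tabular pairwise-search format: columns `query`,
#' `subject`, `percent_identity`, `align_length`, `e_value`, `bitscore`
#' (header optional; headerless files are assumed to be in that order).
#'
#' @param file path to a TSV file.
#' @return data.frame with the six standard columns.
#' @export
read_hit_table <- function(file) {
  first <- readLines(file, n = 1)
  cols <- c("query", "subject", "percent_identity", "align_length",
            "e_value", "bitscore")
  if (grepl("^query\t", first)) {
    read.delim(file, stringsAsFactors = FALSE)
  } else {
    setNames(read.delim(file, header = FALSE, stringsAsFactors = FALSE)[1:6], cols)
  }
}
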