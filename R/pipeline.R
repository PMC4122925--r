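# End-to-end orchestration: homology evidence -> ortholog clusters ->
# gene trees -> HGT verdicts -> class/timing -> pangenome summaries,
# synteny, composition and codon-usage statistics, with a reproducible
# report bundle.

#' Pipeline configuration
#'
#' Validated key/value settings for [run_pipeline()]; unknown keys are
#' rejected.
#'
#' @param seed master seed; every stochastic stage derives its seed here.
#' @param min_identity,min_coverage,max_evalue ortholog clustering
#'   thresholds (see [cluster_orthologs()]).
#' @param n_boot bootstrap replicates for tree inference.
#' @param min_support,min_bacterial_phyla,min_bacterial_leaves HGT-calling
#'   thresholds (see [call_hgt()]).
#' @param tetra_k k-mer size for composition profiles.
#' @param stages character vector of optional stage toggles; subset of
#'   `c("synteny", "tetra", "cai")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, min_identity = 30, min_coverage = 0.7,
                            max_evalue = 1e-5, n_boot = 100,
                            min_support = 0.8, min_bacterial_phyla = 3,
                            min_bacterial_leaves = 10, tetra_k = 4,
                            stages = c("synteny", "tetra", "cai")) {
  bad <- setdiff(stages, c("synteny", "tetra", "cai"))
  if (length(bad)) stop("unknown stage toggle(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), min_identity = min_identity,
                 min_coverage = min_coverage, max_evalue = max_evalue,
                 n_boot = n_boot, min_support = min_support,
                 min_bacterial_phyla = min_bacterial_phyla,
                 min_bacterial_leaves = min_bacterial_leaves,
                 tetra_k = tetra_k, stages = stages),
            class = "pipeline_config")
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full pangenome / HGT pipeline on a fosmid library
#'
#' Stages run in dependency order: all-vs-all homology -> ortholog
#' clustering -> per-cluster gene tree (neighbor joining + bootstrap) ->
#' HGT calling -> core/shell classification against the reference panel ->
#' transfer timing -> per-lineage pangenome summaries; then synteny
#' blocks, tetranucleotide profiles and CAI.  Record counts in and out of
#' every filter are logged so conservative exclusions stay auditable.
#'
#' @param lib a `fosmid_library` (see [emit_fosmid_library()]) or a list
#'   with the same elements assembled from real data.
#' @param config a [pipeline_config()].
#' @param verbose log stage progress via `message()`.
#' @return object of class `archpan_report`: list with `clusters`,
#'   `classes`, `verdicts`, `summaries` (per lineage), `donors`,
#'   `genome_equivalents`, `synteny`, `tetra`, `cai_results`, `config` and
#'   (when the library carries truth) `confusion` and `recovery`.
#' @export
run_pipeline <- function(lib, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  proteins <- lib$proteins
  if (!length(proteins)) stop("stage homology: library contains no genes")
  lineage_of_genome <- NULL

  .log_stage(verbose, "homology: %d proteins", length(proteins))
  self_hits <- build_hit_table(proteins)
  clusters <- cluster_orthologs(self_hits, nchar(proteins),
                                min_identity = config$min_identity,
                                min_coverage = config$min_coverage,
                                max_evalue = config$max_evalue)
  .log_stage(verbose, "clustering: %d clusters", length(clusters$clusters))

  # presence in reference genomes and database homolog counts
  ref_hits <- if (length(lib$ref_proteins))
    build_hit_table(proteins, lib$ref_proteins) else NULL
  db_hits <- if (length(lib$db_proteins))
    build_hit_table(proteins, lib$db_proteins) else NULL
  pass <- function(h, qlen, slen) {
    h[h$percent_identity >= config$min_identity &
      h$e_value <= config$max_evalue &
      h$align_length / pmin(qlen[h$query], slen[h$subject]) >=
        config$min_coverage, , drop = FALSE]
  }
  if (!is.null(ref_hits))
    ref_hits <- pass(ref_hits, nchar(proteins), nchar(lib$ref_proteins))
  if (!is.null(db_hits))
    db_hits <- pass(db_hits, nchar(proteins), nchar(lib$db_proteins))

  gene_lineage <- setNames(
    lib$fosmid_lineage[lib$features$fosmid[match(names(proteins),
                                                 lib$features$gene_id)]],
    names(proteins))

  ref_genome_of <- setNames(lib$ref_genes$ref_genome, lib$ref_genes$gene_id)
  cluster_ids <- names(clusters$clusters)
  classes <- setNames(character(length(cluster_ids)), cluster_ids)
  cluster_lineage <- setNames(character(length(cluster_ids)), cluster_ids)
  presence_list <- list()
  dbcount <- setNames(integer(length(cluster_ids)), cluster_ids)
  for (cid in cluster_ids) {
    members <- clusters$clusters[[cid]]
    lin <- names(sort(table(gene_lineage[members]), decreasing = TRUE))[1]
    cluster_lineage[cid] <- lin
    pres <- character(0)
    if (!is.null(ref_hits)) {
      hh <- ref_hits[ref_hits$query %in% members, , drop = FALSE]
      pres <- sort(unique(ref_genome_of[hh$subject]))
    }
    nhits <- 0L
    if (!is.null(db_hits))
      nhits <- length(unique(db_hits$subject[db_hits$query %in% members]))
    presence_list[[cid]] <- pres
    dbcount[cid] <- nhits
    classes[cid] <- classify_cluster(pres, lin, lib$ref_panel,
                                     n_members = length(members),
                                     db_hit_count = nhits)
  }
  .log_stage(verbose, "classification: %s",
             paste(names(table(classes)), table(classes),
                   sep = "=", collapse = " "))

  # per-cluster gene trees and HGT verdicts
  db_tax <- lib$db_tax
  verdict_rows <- list()
  excluded_small <- 0L
  i_cluster <- 0L
  for (cid in cluster_ids) {
    i_cluster <- i_cluster + 1L
    members <- clusters$clusters[[cid]]
    homologs <- if (!is.null(db_hits))
      unique(db_hits$subject[db_hits$query %in% members]) else character(0)
    aln <- c(proteins[members], lib$db_proteins[homologs])
    if (length(aln) < 4 || !length(homologs)) {
      excluded_small <- excluded_small + 1L
      verdict_rows[[cid]] <- data.frame(
        cluster_id = cid, status = "excluded", criterion = "none",
        donor_domain = NA_character_, donor_phylum = NA_character_,
        timing = "n/a", support_at_decision = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    tree <- infer_tree(aln, method = "nj",
                       seed = config$seed + i_cluster, n_boot = config$n_boot)
    tax <- rbind(
      taxonomy_map(members, "Archaea", cluster_lineage[cid], is_query = TRUE),
      db_tax[match(homologs, db_tax$leaf), ])
    verdict_rows[[cid]] <- call_hgt(
      tree, tax, min_support = config$min_support,
      min_bacterial_phyla = config$min_bacterial_phyla,
      min_bacterial_leaves = config$min_bacterial_leaves,
      cluster_id = cid)
  }
  verdicts <- do.call(rbind, verdict_rows)
  rownames(verdicts) <- NULL
  verdicts <- time_transfer(verdicts, classes)
  .log_stage(verbose,
             "hgt calling: %d hgt / %d native / %d unresolved / %d excluded",
             sum(verdicts$status == "hgt"), sum(verdicts$status == "native"),
             sum(verdicts$status == "unresolved"),
             sum(verdicts$status == "excluded"))

  # a cluster belongs to every lineage it has member genes in, so shared
  # (archaeal core) clusters appear in both lineages' summaries
  lineages <- names(lib$ref_panel)
  summaries <- lapply(setNames(lineages, lineages), function(l) {
    has_l <- vapply(clusters$clusters, function(m)
      any(gene_lineage[m] == l), logical(1))
    summarize_pangenome(classes[has_l], verdicts, lineage = l)
  })
  donors <- donor_spectrum(verdicts)

  # genome equivalents from single-copy marker annotations
  marker_fams <- unique(lib$features$family_id[
    grepl("single-copy marker", lib$features$annotation)])
  geq <- NULL
  if (length(marker_fams)) {
    fam_of_gene <- setNames(lib$features$family_id, lib$features$gene_id)
    geq <- estimate_genome_equivalents(fam_of_gene, marker_fams)
  }

  report <- list(clusters = clusters, classes = classes,
                 cluster_lineage = cluster_lineage,
                 presence = presence_list, db_hit_count = dbcount,
                 verdicts = verdicts, summaries = summaries, donors = donors,
                 genome_equivalents = geq, config = config)

  # gene-level origin classes for synteny
  if ("synteny" %in% config$stages) {
    vstat <- setNames(verdicts$status, verdicts$cluster_id)
    gene_class5 <- vapply(lib$features$gene_id, function(gid) {
      cid <- clusters$membership[gid]
      if (is.na(cid)) return("other")
      cls <- classes[cid]; hgt <- identical(unname(vstat[cid]), "hgt")
      if (cls == "archaeal_core") "archaeal_core"
      else if (cls == "lineage_core" && hgt) "early_hgt"
      else if (cls == "lineage_core") "lineage_core"
      else if (cls == "shell" && hgt) "late_hgt"
      else "other"
    }, character(1))
    blocks <- do.call(rbind, lapply(unique(lib$features$fosmid), function(f) {
      idx <- lib$features$fosmid == f
      ord <- order(lib$features$start[idx])
      b <- build_blocks(gene_class5[idx][ord], fosmid = f)
      b$group <- paste(lib$fosmid_lineage[[f]], b$class, sep = ":")
      b
    }))
    cm <- couple_matrix(blocks)
    report$synteny <- list(blocks = blocks, couple_matrix = cm,
                           mean_lengths = mean_block_length(blocks),
                           clustering = if (nrow(cm$matrix) >= 2)
                             cluster_couple_patterns(cm$matrix) else NULL)
  }

  if ("tetra" %in% config$stages) {
    profs <- lapply(names(lib$fosmids), function(f)
      kmer_zscores(lib$fosmids[[f]], k = config$tetra_k, id = f))
    zmat <- do.call(rbind, lapply(profs, `[[`, "z"))
    rownames(zmat) <- names(lib$fosmids)
    emb <- pca_embed(zmat, n_components = 2)
    report$tetra <- list(profiles = zmat, pca = emb,
                         lineage = lib$fosmid_lineage[rownames(zmat)])
  }

  if ("cai" %in% config$stages && length(lib$cds)) {
    ribo <- lib$features$gene_id[grepl("ribosomal protein",
                                       lib$features$annotation)]
    if (length(ribo) >= 3) {
      tabs <- usage_table(lib$cds[ribo])
      cai_rows <- do.call(rbind, lapply(names(lib$cds), function(g)
        cai(lib$cds[[g]], tabs, gene_id = g)))
      report$cai_results <- cai_rows
    }
  }

  # truth-based evaluation when available
  if (!is.null(lib$truth)) {
    fam_class <- unique(lib$truth[, c("family_id", "origin_class",
                                      "donor_phylum")])
    called5 <- setNames(rep("other", length(cluster_ids)), cluster_ids)
    truth5 <- called5
    vstat <- setNames(verdicts$status, verdicts$cluster_id)
    vtim <- setNames(verdicts$timing, verdicts$cluster_id)
    fam_of_gene <- setNames(lib$truth$family_id, lib$truth$gene_id)
    for (cid in cluster_ids) {
      members <- clusters$clusters[[cid]]
      tf <- names(sort(table(fam_of_gene[members]), decreasing = TRUE))[1]
      truth5[cid] <- fam_class$origin_class[fam_class$family_id == tf]
      cls <- classes[cid]; hgt <- identical(unname(vstat[cid]), "hgt")
      called5[cid] <-
        if (cls == "orphan") "orphan"
        else if (cls == "archaeal_core") "archaeal_core"
        else if (cls == "lineage_core" && hgt) "lineage_core_early_hgt"
        else if (cls == "lineage_core") "lineage_core_native"
        else if (hgt) "shell_late_hgt" else "shell_native"
    }
    report$confusion <- table(truth = truth5, called = called5)
    truth_hgt <- grepl("hgt", truth5)
    called_hgt <- grepl("hgt", called5)
    n_all <- length(cluster_ids)
    report$recovery <- list(
      planted_hgt_pct = 100 * sum(truth_hgt) / n_all,
      recovered_hgt_pct = 100 * sum(called_hgt) / n_all,
      sensitivity = if (sum(truth_hgt)) mean(called_hgt[truth_hgt]) else NA,
      false_positive_rate = if (sum(!truth_hgt))
        mean(called_hgt[!truth_hgt]) else NA,
      timing_accuracy = {
        both <- truth_hgt & called_hgt
        if (sum(both)) {
          tt <- ifelse(truth5[both] == "lineage_core_early_hgt",
                       "early", "late")
          mean(tt == vtim[names(truth5)[both]])
        } else NA
      })
  }
  class(report) <- "archpan_report"
  report
}

#' @export
print.archpan_report <- function(x, ...) {
  cat("archpan pipeline report\n")
  for (s in x$summaries) print(s)
  if (!is.null(x$recovery))
    cat(sprintf("recovery: planted %.1f%%, recovered %.1f%% HGT (sens %.2f, fpr %.3f)\n",
                x$recovery$planted_hgt_pct, x$recovery$recovered_hgt_pct,
                x$recovery$sensitivity, x$recovery$false_positive_rate))
  invisible(x)
}

#' Render a report bundle to TSV/JSON (and SVG figures)
#'
#' Writes a machine-readable JSON twin of every table, the tables as TSV,
#' and (when the stages ran) the tetra-PCA and donor-spectrum figures as
#' SVG, plus a manifest recording the configuration.
#'
#' @param report an `archpan_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.table(df, file.path(dir, name), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  w(report$verdicts, "verdicts.tsv")
  cls_df <- data.frame(cluster_id = names(report$classes),
                       class = unname(report$classes),
                       lineage = unname(report$cluster_lineage),
                       db_hit_count = unname(report$db_hit_count),
                       stringsAsFactors = FALSE)
  w(cls_df, "clusters.tsv")
  summaries <- lapply(report$summaries, function(s)
    c(as.list(s$counts), total_clusters = s$total_clusters,
      orphans = s$orphan_count, pct_hgt_total = s$pct_hgt_total,
      pct_hgt_early = s$pct_hgt_early, pct_hgt_late = s$pct_hgt_late))
  sm <- do.call(rbind, lapply(names(summaries), function(l)
    data.frame(lineage = l, summaries[[l]], stringsAsFactors = FALSE)))
  w(sm, "summary.tsv")
  json <- list(config = unclass(report$config), summary = summaries,
               donors = report$donors,
               genome_equivalents = report$genome_equivalents,
               recovery = report$recovery)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(report$synteny)) {
    w(report$synteny$blocks, "synteny_blocks.tsv")
    cmm <- report$synteny$couple_matrix$matrix
    w(data.frame(group = rownames(cmm), cmm, check.names = FALSE),
      "couple_matrix.tsv")
  }
  if (!is.null(report$tetra)) {
    co <- report$tetra$pca$coordinates
    w(data.frame(fosmid = rownames(co), co,
                 lineage = report$tetra$lineage, check.names = FALSE),
      "tetra_pca.tsv")
    grDevices::svg(file.path(dir, "tetra_pca.svg"), width = 6, height = 5)
    lin <- factor(report$tetra$lineage)
    plot(co[, 1], co[, 2], col = as.integer(lin), pch = 19,
         xlab = "PC1", ylab = "PC2",
         main = "Tetranucleotide z-score PCA")
    graphics::legend("topright", legend = levels(lin),
                     col = seq_along(levels(lin)), pch = 19)
    grDevices::dev.off()
  }
  if (length(report$donors)) {
    grDevices::svg(file.path(dir, "donor_spectrum.svg"), width = 6, height = 5)
    ph <- lapply(report$donors, `[[`, "phyla")
    all_ph <- sort(unique(unlist(lapply(ph, names))))
    mat <- sapply(ph, function(p) setNames(p[all_ph], all_ph))
    mat[is.na(mat)] <- 0
    rownames(mat) <- all_ph
    graphics::barplot(as.matrix(mat), beside = TRUE, legend.text = all_ph,
                      main = "Donor spectrum by timing", ylab = "fraction")
    grDevices::dev.off()
  }
  if (!is.null(report$cai_results)) w(report$cai_results, "cai.tsv")
  invisible(dir)
}
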