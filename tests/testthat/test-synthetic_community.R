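# Synthetic community generator: determinism, planted truth, GC control,
# tiling invariants

test_that("configuration is validated", {
  expect_error(community_config(n_genomes = c(a = 0, b = 3)), "at least one")
  expect_error(community_config(class_proportions = c(archaeal_core = 1)),
               "cover exactly")
  bad <- c(archaeal_core = 0.5, lineage_core_native = 0.5,
           lineage_core_early_hgt = 0.5, shell_native = 0,
           shell_late_hgt = 0, orphan = 0)
  expect_error(community_config(class_proportions = bad), "sum to 1")
  expect_error(community_config(lineage_gc = c(thaum = 1.2, gii_iii = 0.5)),
               "\\[0, 1\\]")
})

test_that("a fixed seed reproduces the forest and library byte-for-byte", {
  cfg <- community_config(n_genomes = c(thaum = 3, gii_iii = 3),
                          n_families = 20, n_marker_families = 3,
                          n_ribosomal_families = 2, seed = 99)
  f1 <- simulate_species_forest(cfg)
  f2 <- simulate_species_forest(cfg)
  nwk <- function(fo) vapply(Filter(function(x) !is.null(x$tree), fo$families),
                             function(x) ape::write.tree(x$tree), character(1))
  expect_identical(nwk(f1), nwk(f2))
  l1 <- emit_fosmid_library(cfg, f1)
  l2 <- emit_fosmid_library(cfg, f2)
  expect_identical(l1$fosmids, l2$fosmids)
  expect_identical(l1$features, l2$features)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fosmid_library(l1, d1); write_fosmid_library(l2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "fosmids.fasta"))),
                   unname(tools::md5sum(file.path(d2, "fosmids.fasta"))))
})

test_that("planted class proportions are recovered from the truth table", {
  cfg <- community_config(n_genomes = c(thaum = 4, gii_iii = 3),
                          n_families = 120, n_marker_families = 6,
                          n_ribosomal_families = 4, seed = 3)
  fo <- simulate_species_forest(cfg)
  cls <- vapply(fo$families, `[[`, character(1), "class")
  got <- table(factor(cls, levels = names(cfg$class_proportions))) / length(cls)
  # largest-remainder allocation: exact up to 1/n_families per class
  expect_true(all(abs(got - cfg$class_proportions) <= 1 / 120 + 1e-12))
})

test_that("zero HGT proportions produce no donor labels", {
  cp <- c(archaeal_core = 0.4, lineage_core_native = 0.3,
          lineage_core_early_hgt = 0, shell_native = 0.2,
          shell_late_hgt = 0, orphan = 0.1)
  cfg <- community_config(n_genomes = c(thaum = 3, gii_iii = 3),
                          class_proportions = cp, n_families = 20,
                          n_marker_families = 2, n_ribosomal_families = 2,
                          seed = 5)
  fo <- simulate_species_forest(cfg)
  expect_true(all(is.na(vapply(fo$families, `[[`, character(1),
                               "donor_phylum"))))
})

test_that("truth table genes map 1:1 onto feature-table rows", {
  com <- tiny_community()
  expect_setequal(com$lib$truth$gene_id, com$lib$features$gene_id)
  expect_equal(anyDuplicated(com$lib$features$gene_id), 0)
  expect_equal(anyDuplicated(com$lib$truth$gene_id), 0)
})

test_that("single-copy markers occur exactly once per genome", {
  com <- tiny_community()
  markers <- unique(com$lib$features$family_id[
    grepl("single-copy marker", com$lib$features$annotation)])
  expect_length(markers, com$cfg$n_marker_families)
  tr <- com$lib$truth
  for (m in markers) {
    g <- tr$genome[tr$family_id == m]
    expect_setequal(g, unique(tr$genome))
    expect_equal(anyDuplicated(g), 0)
  }
})

test_that("orphan families have size one and no homologs", {
  com <- tiny_community()
  orph <- Filter(function(f) f$class == "orphan", com$forest$families)
  expect_true(all(vapply(orph, function(f) nrow(f$members), integer(1)) == 1))
  expect_true(all(vapply(orph, function(f) is.null(f$tree), logical(1))))
  # early transfers sit in all (or all but one) genomes of their lineage;
  # late transfers in a strict subset
  lin_n <- com$cfg$n_genomes
  for (f in com$forest$families) {
    n <- nrow(f$members)
    if (f$class == "lineage_core_early_hgt")
      expect_gte(n, lin_n[[f$lineage]] - 1)
    if (f$class == "shell_late_hgt")
      expect_lt(n, lin_n[[f$lineage]])
  }
})

test_that("back-translation realizes the target GC over a megabase", {
  cfg <- community_config(n_genomes = c(a = 2, b = 2),
                          lineage_gc = c(a = 0.5, b = 0.5),
                          n_families = 520, n_marker_families = 2,
                          n_ribosomal_families = 2, seed = 21)
  fo <- simulate_species_forest(cfg)
  lib <- emit_fosmid_library(cfg, fo)
  s <- paste(lib$fosmids, collapse = "")
  expect_gte(nchar(s), 1e6)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.49); expect_lte(gc, 0.51)
})

test_that("feature coordinates stay inside fosmids and genes do not overlap", {
  com <- tiny_community()
  feat <- com$lib$features
  for (f in names(com$lib$fosmids)) {
    rows <- feat[feat$fosmid == f, ]
    rows <- rows[order(rows$start), ]
    expect_true(all(rows$end <= nchar(com$lib$fosmids[[f]])))
    expect_true(all(rows$start >= 0))
    if (nrow(rows) > 1)
      expect_true(all(head(rows$end, -1) <= tail(rows$start, -1)))
    # extracted CDS reproduces the recorded translation
    for (i in seq_len(nrow(rows))) {
      nt <- substr(com$lib$fosmids[[f]], rows$start[i] + 1, rows$end[i])
      if (rows$strand[i] == "-")
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(nt),
        genetic.code = Biostrings::getGeneticCode("11"),
        no.init.codon = TRUE))
      expect_equal(sub("\\*$", "", aa),
                   unname(com$lib$proteins[rows$gene_id[i]]))
    }
  }
})

test_that("fosmid length constraint is enforced", {
  cfg <- community_config(n_genomes = c(a = 2, b = 2), n_families = 20,
                          n_marker_families = 2, n_ribosomal_families = 2,
                          fosmid_length_mean = 500, seed = 1)
  fo <- simulate_species_forest(cfg)
  expect_error(emit_fosmid_library(cfg, fo), "too small")
})
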