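# Ortholog clustering, class assignment, summary arithmetic,
# genome equivalents, outgroup sharing

test_that("ortholog clustering follows single-linkage component semantics", {
  lens <- c(a = 100, b = 100, c = 100, d = 100)
  full <- data.frame(query = c("a", "b", "a"), subject = c("b", "c", "c"),
                     percent_identity = c(90, 90, 90), align_length = 100,
                     e_value = 1e-30, bitscore = 100)
  cl <- cluster_orthologs(full, lens)
  expect_length(cl$clusters, 2) # {a,b,c} and {d}
  expect_setequal(cl$clusters[["OG_a"]], c("a", "b", "c"))
  # chain a-b, b-c with a-c failing still gives one component
  chain <- full[1:2, ]
  cl2 <- cluster_orthologs(chain, lens)
  expect_setequal(cl2$clusters[["OG_a"]], c("a", "b", "c"))
  # empty hit table: every gene its own cluster
  cl3 <- cluster_orthologs(full[0, ], lens)
  expect_length(cl3$clusters, 4)
  # permutation invariance of input order
  cl4 <- cluster_orthologs(full[c(3, 1, 2), ], lens[c(4, 2, 1, 3)])
  expect_identical(cl4$clusters, cl$clusters)
  # thresholds: sub-threshold identity breaks the edge
  weak <- full; weak$percent_identity <- 20
  expect_length(cluster_orthologs(weak, lens)$clusters, 4)
})

test_that("recovered clusters match planted families (adjusted Rand >= 0.95)", {
  com <- tiny_community()
  lib <- com$lib
  hits <- build_hit_table(lib$proteins)
  cl <- cluster_orthologs(hits, nchar(lib$proteins))
  fam <- setNames(lib$truth$family_id, lib$truth$gene_id)
  genes <- names(cl$membership)
  expect_gte(adjusted_rand(fam[genes], cl$membership[genes]), 0.95)
})

test_that("cluster classification implements the presence rules", {
  panel <- list(thaum = c("ref_thaum_1", "ref_thaum_2", "ref_thaum_3"),
                gii_iii = "ref_gii_iii_1")
  allr <- unlist(panel)
  expect_equal(classify_cluster(allr, "thaum", panel), "archaeal_core")
  # all-but-one rule for the 3-genome panel
  expect_equal(classify_cluster(c("ref_thaum_1", "ref_thaum_2"),
                                "thaum", panel), "lineage_core")
  # the single-genome panel tolerates no absence
  expect_equal(classify_cluster(character(0), "gii_iii", panel,
                                n_members = 4, db_hit_count = 10), "shell")
  expect_equal(classify_cluster("ref_gii_iii_1", "gii_iii", panel),
               "lineage_core")
  # 1-3 database hits, absent from refs: shell
  expect_equal(classify_cluster(character(0), "thaum", panel,
                                n_members = 3, db_hit_count = 2), "shell")
  # no homologs at all: orphan
  expect_equal(classify_cluster(character(0), "thaum", panel,
                                n_members = 1, db_hit_count = 0), "orphan")
  expect_error(classify_cluster("nope", "thaum", panel), "unknown reference")
  expect_error(classify_cluster(allr, "x", panel), "unknown lineage")
})

test_that("pangenome summary reproduces the published percentage arithmetic", {
  thaum <- pangenome_summary(
    c(core = 629, lineage_core_native = 416, lineage_core_early_hgt = 290,
      shell_native = 452, shell_late_hgt = 311), orphans = 416)
  expect_equal(thaum$pct_hgt_total, 23.9)
  expect_equal(thaum$pct_hgt_early, 11.5)
  expect_equal(thaum$total_clusters, 2098)
  expect_equal(thaum$lineage_core_total, 706)
  expect_equal(thaum$shell_total, 763)

  gii <- pangenome_summary(
    c(core = 552, lineage_core_native = 288, lineage_core_early_hgt = 416,
      shell_native = 1256, shell_late_hgt = 1015), orphans = 1293)
  expect_equal(gii$pct_hgt_total, 29.7)
  expect_equal(gii$pct_hgt_early, 8.6)
  expect_equal(gii$pct_hgt_late, 21.1)
  expect_equal(gii$lineage_core_total, 704)
  expect_equal(gii$shell_total, 2271)

  # all-native pangenome has zero HGT
  z <- pangenome_summary(c(core = 10, lineage_core_native = 5,
                           lineage_core_early_hgt = 0, shell_native = 3,
                           shell_late_hgt = 0), orphans = 2)
  expect_equal(z$pct_hgt_total, 0)
  expect_error(pangenome_summary(c(core = 0, lineage_core_native = 0,
                                   lineage_core_early_hgt = 0,
                                   shell_native = 0, shell_late_hgt = 0), 0),
               "empty")
  # percentages are internally consistent at full precision
  expect_equal(gii$pct_full[["total"]],
               gii$pct_full[["early"]] + gii$pct_full[["late"]])
})

test_that("summarize_pangenome tallies classes and verdicts", {
  classes <- c(c1 = "archaeal_core", c2 = "lineage_core", c3 = "lineage_core",
               c4 = "shell", c5 = "shell", c6 = "orphan")
  verd <- data.frame(cluster_id = c("c2", "c5"), status = "hgt")
  s <- summarize_pangenome(classes, verd)
  expect_equal(unname(s$counts), c(1, 1, 1, 1, 1))
  expect_equal(s$orphan_count, 1)
  expect_equal(s$total_clusters, 5)
  expect_equal(s$pct_hgt_total, round(100 * 2 / 6, 1))
})

test_that("genome equivalents average single-copy marker counts", {
  fams <- setNames(rep(c("m1", "m2", "m3"), c(3, 4, 5)), paste0("g", 1:12))
  est <- estimate_genome_equivalents(fams, c("m1", "m2", "m3"))
  expect_equal(est$mean, 4)
  expect_equal(unname(est$per_marker), c(3, 4, 5))
  one <- estimate_genome_equivalents(setNames("m1", "g1"), "m1")
  expect_equal(one$mean, 1)
  expect_error(estimate_genome_equivalents(fams, c("zz")), "missing")
  # simulated community: markers recover the genome count
  com <- tiny_community()
  fam_of <- setNames(com$lib$truth$family_id, com$lib$truth$gene_id)
  markers <- unique(com$lib$features$family_id[
    grepl("single-copy marker", com$lib$features$annotation)])
  est2 <- estimate_genome_equivalents(fam_of, markers)
  expect_equal(est2$mean, sum(com$cfg$n_genomes), tolerance = 0.06)
})

test_that("outgroup sharing counts early transfers with tree support", {
  verd <- data.frame(cluster_id = c("A", "B", "C"), status = "hgt",
                     timing = c("early", "early", "late"))
  links <- data.frame(cluster_id = c("A", "C"), outgroup_gene = c("o1", "o2"))
  # homology-only: upper bound
  res <- shared_hgt_with_outgroup(verd, links)
  expect_equal(res$count, 1) # only A is early with a link
  expect_true(res$upper_bound)
  # with a tree where the outgroup groups with the query clade
  tr <- ape::read.tree(text = "(((q1,q2),o1),(b1,(b2,b3)));")
  tax <- taxonomy_map(c("q1", "q2", "o1", "b1", "b2", "b3"),
                      c("Archaea", "Archaea", "Archaea", rep("Bacteria", 3)),
                      c("q", "q", "outgroup", rep("Proteobacteria", 3)),
                      is_query = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  res2 <- shared_hgt_with_outgroup(verd, links, trees = list(A = tr),
                                   taxonomies = list(A = tax))
  expect_equal(res2$count, 1)
  expect_false(res2$upper_bound)
  # outgroup far from the query clade does not count
  tr2 <- ape::read.tree(text = "(((q1,q2),b1),(b2,(b3,o1)));")
  res3 <- shared_hgt_with_outgroup(verd, links, trees = list(A = tr2),
                                   taxonomies = list(A = tax))
  expect_equal(res3$count, 0)
  # empty outgroup set
  res4 <- shared_hgt_with_outgroup(verd, links[0, ])
  expect_equal(res4$count, 0)
})
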