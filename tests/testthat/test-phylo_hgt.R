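# Alignment trimming, tree inference, the HGT verdict rules, timing,
# donor spectra

test_that("gap trimming removes exactly the columns above the threshold", {
  rows <- c(rep("ACDEF", 7), "A-DEF", "A-D-F", "A-D-F")
  names(rows) <- paste0("s", 1:10)
  # column 2 has 3/10 gaps (> 0.2): removed; column 4 has 2/10 (= 0.2): kept
  out <- trim_alignment(rows, 0.2)
  expect_equal(unique(nchar(out)), 4)
  expect_equal(unname(out["s1"]), "ADEF")
  expect_equal(unname(out["s9"]), "AD-F")
  # gap-free alignment is untouched
  clean <- setNames(c("MKL", "MQL"), c("a", "b"))
  expect_identical(trim_alignment(clean), clean)
  expect_error(trim_alignment(setNames(c("---", "---"), c("a", "b")), 0.2),
               "all columns")
  expect_error(trim_alignment(c(a = "AC", b = "ACG")), "equal length")
})

test_that("NJ recovers the unique topology from additive distances", {
  # four clean sequences: ((a,b),(c,d)) with long internal branch
  set.seed(8)
  base <- sample(c("A", "R", "N", "D", "C", "E", "Q", "G"), 300, replace = TRUE)
  mut <- function(s, k) { i <- sample(seq_along(s), k); s[i] <- "W"; s }
  aln <- c(a = paste(base, collapse = ""),
           b = paste(mut(base, 10), collapse = ""),
           c = paste(mut(base, 150), collapse = ""),
           d = paste(c(mut(base, 150)[1:150], rep("Y", 150)), collapse = ""))
  tr <- infer_tree(aln, n_boot = 0)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_error(infer_tree(aln[1:3]), "fewer than four")
})

test_that("tree inference is deterministic under a fixed seed", {
  com <- tiny_community()
  f <- Filter(function(x) x$class == "lineage_core_early_hgt",
              com$forest$families)[[1]]
  aln <- f$proteins[f$tree$tip.label]
  t1 <- infer_tree(aln, seed = 5, n_boot = 30)
  t2 <- infer_tree(aln, seed = 5, n_boot = 30)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(t1$node.label, t2$node.label)
})

test_that("external Newick parsing round-trips supports", {
  tr <- infer_tree(method = "external",
                   newick = "((a:1,b:1)0.9:1,(c:1,d:1)0.8:1);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
})

test_that("constructed minimal trees get the expected verdicts", {
  # query pair nested inside a one-phylum bacterial clade (phylum members
  # on both sides of its attachment): hgt by nesting
  nest <- ape::read.tree(text = paste0(
    "(((fX1,fX2)1.0,((q1,q2)1.0,(fX3,(fX4,fX5)1.0)1.0)1.0)1.0,",
    "(a1,(a2,a3)1.0)1.0);"))
  tax <- taxonomy_map(
    c("q1", "q2", paste0("fX", 1:5), paste0("a", 1:3)),
    c(rep("Archaea", 2), rep("Bacteria", 5), rep("Archaea", 3)),
    c(rep("query", 2), rep("PhylumX", 5), rep(NA, 3)),
    is_query = c(TRUE, TRUE, rep(FALSE, 8)))
  v <- call_hgt(nest, tax, min_bacterial_leaves = 3,
                min_bacterial_phyla = 1)
  expect_equal(v$status, "hgt")
  expect_equal(v$criterion, "nested_in_phylum")
  expect_equal(v$donor_phylum, "PhylumX")

  # query sister to other archaea, bacteria outside: native
  nat <- ape::read.tree(text = paste0(
    "(((q1,q2)1.0,(a1,(a2,a3)1.0)1.0)1.0,",
    "((fX1,fX2)1.0,(fX3,(fX4,fX5)1.0)1.0)1.0);"))
  v2 <- call_hgt(nat, tax, min_bacterial_leaves = 3, min_bacterial_phyla = 1)
  expect_equal(v2$status, "native")

  # unsupported query clade: unresolved
  lowsup <- ape::read.tree(text = paste0(
    "(((fX1,fX2)1.0,((q1,q2)0.3,(fX3,(fX4,fX5)1.0)1.0)1.0)1.0,",
    "(a1,(a2,a3)1.0)1.0);"))
  expect_equal(call_hgt(lowsup, tax, min_bacterial_leaves = 3,
                        min_bacterial_phyla = 1)$status, "unresolved")

  # fewer than 4 informative non-query leaves: excluded
  small <- ape::read.tree(text = "((q1,q2)1.0,(fX1,(fX2,fX3)1.0)1.0);")
  expect_equal(call_hgt(small, tax, min_bacterial_leaves = 1,
                        min_bacterial_phyla = 1)$status, "excluded")

  expect_error(call_hgt(nest, taxonomy_map(tax$leaf, tax$domain, tax$phylum,
                                           is_query = FALSE)),
               "no query leaves")
})

test_that("call_hgt equals the exhaustive bipartition oracle on random trees", {
  ok <- 0
  for (i in 1:300) {
    case <- random_hgt_case(sample(5:8, 1), seed = 1000 + i)
    got <- call_hgt(case$tree, case$tax, min_bacterial_leaves = 3,
                    min_bacterial_phyla = 2, nest_min_nonquery = 3)$status
    want <- oracle_call_hgt(case$tree, case$tax, min_bacterial_leaves = 3,
                            min_bacterial_phyla = 2, nest_min_nonquery = 3)
    expect_identical(got, want)
    ok <- ok + 1
  }
  expect_equal(ok, 300)
})

test_that("verdicts are invariant to re-rooting and leaf permutation", {
  for (i in 1:40) {
    case <- random_hgt_case(8, seed = 5000 + i)
    base <- call_hgt(case$tree, case$tax, min_bacterial_leaves = 3,
                     min_bacterial_phyla = 2, nest_min_nonquery = 3)
    # re-root on a random tip, keeping edge-support association
    out <- sample(case$tree$tip.label, 1)
    rr <- ape::root(case$tree, outgroup = out, edgelabel = TRUE)
    v1 <- call_hgt(rr, case$tax, min_bacterial_leaves = 3,
                   min_bacterial_phyla = 2, nest_min_nonquery = 3)
    expect_identical(v1$status, base$status)
    expect_identical(v1$criterion, base$criterion)
    # permute leaf order in the Newick text
    perm <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
      case$tree, sample(case$tree$tip.label))))
    v2 <- call_hgt(perm, case$tax, min_bacterial_leaves = 3,
                   min_bacterial_phyla = 2, nest_min_nonquery = 3)
    expect_identical(v2$status, base$status)
  }
})

test_that("raising min_support never converts native to hgt", {
  for (i in 1:100) {
    case <- random_hgt_case(sample(6:8, 1), seed = 9000 + i)
    lo <- call_hgt(case$tree, case$tax, min_support = 0.6,
                   min_bacterial_leaves = 3, min_bacterial_phyla = 2,
                   nest_min_nonquery = 3)$status
    hi <- call_hgt(case$tree, case$tax, min_support = 0.9,
                   min_bacterial_leaves = 3, min_bacterial_phyla = 2,
                   nest_min_nonquery = 3)$status
    if (lo == "native") expect_true(hi != "hgt")
  }
})

test_that("transfer timing follows the cluster class", {
  verd <- data.frame(cluster_id = c("a", "b", "c", "d"),
                     status = c("hgt", "hgt", "native", "hgt"),
                     criterion = "nested_in_phylum",
                     donor_domain = "Bacteria", donor_phylum = "P",
                     timing = "n/a", support_at_decision = 1)
  classes <- c(a = "lineage_core", b = "shell", c = "shell",
               d = "archaeal_core")
  out <- time_transfer(verd, classes)
  expect_equal(out$timing, c("early", "late", "n/a", "n/a"))
  expect_equal(out$conflict, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("donor spectrum fractions sum to one per timing class", {
  verd <- data.frame(
    cluster_id = paste0("c", 1:6), status = "hgt",
    criterion = "nested_in_phylum", donor_domain = "Bacteria",
    donor_phylum = c("P", "P", "A", NA, "P", NA),
    timing = c("early", "early", "early", "early", "late", "late"))
  sp <- donor_spectrum(verd)
  expect_equal(sum(sp$early$phyla), 1)
  expect_equal(sum(sp$late$phyla), 1)
  expect_equal(sp$early$phyla[["P"]], 0.5)
  expect_equal(sp$early$phyla[["unassigned"]], 0.25)
  # single-phylum case: 100%
  one <- donor_spectrum(verd[verd$donor_phylum %in% "P" &
                             verd$timing == "early", ])
  expect_equal(one$early$phyla[["P"]], 1)
  # empty set: no entries, no division by zero
  expect_length(donor_spectrum(verd[0, ]), 0)
})

test_that("planted family trees are recovered and called correctly", {
  com <- tiny_community()
  fams <- Filter(function(f) !is.null(f$tree), com$forest$families)
  recovered <- 0; correct <- 0; n <- 0
  for (f in fams) {
    aln <- f$proteins[f$tree$tip.label]
    tr <- infer_tree(aln, seed = 17, n_boot = 50)
    n <- n + 1
    qs <- f$panel_tax$leaf[f$panel_tax$is_query]
    if (length(qs) < 2 || ape::is.monophyletic(tr, qs))
      recovered <- recovered + 1
    v <- call_hgt(tr, f$panel_tax, cluster_id = f$id)
    truth_hgt <- grepl("hgt", f$class)
    if ((v$status == "hgt") == truth_hgt) correct <- correct + 1
  }
  expect_gte(recovered / n, 0.9)
  expect_gte(correct / n, 0.9)
})
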