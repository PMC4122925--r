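# Synthetic fosmid community with planted truth.
#
# Two archaeal lineages with distinct GC content, mosaic ~36-kb fosmids
# mixing five gene origin classes (archaeal core, lineage-specific core
# native / early HGT, shell native / late HGT) plus orphans, single-copy
# marker families and ribosomal-protein reference families.  Gene families
# carry simulated gene trees whose topology encodes the planted signal:
# native families branch with the archaeal homologs, transferred families
# nest inside the chosen bacterial donor phylum's clade.  Protein sequences
# evolve along those trees under a 20-letter Jukes-Cantor-like model, and
# nucleotide fosmids are produced by back-translation with a
# lineage-specific, GC-calibrated codon bias.

ORIGIN_CLASSES <- c("archaeal_core", "lineage_core_native",
                    "lineage_core_early_hgt", "shell_native",
                    "shell_late_hgt", "orphan")

#' Configuration for the synthetic fosmid community
#'
#' Defaults emulate the study conditions of the two deep-Mediterranean
#' archaeal pangenomes: two lineages with GC 47.13% and 54.82%, roughly 15
#' and 9 genome equivalents, ~36.2-kb fosmids, origin-class proportions
#' matching the published Thaumarchaeota cluster-count distribution, and
#' 40 single-copy marker families.
#'
#' @param n_genomes named count of genomes per lineage.
#' @param lineage_gc named GC fraction per lineage, in \[0,1\].
#' @param class_proportions named fractions over the six origin classes,
#'   summing to 1.
#' @param donor_phyla named sampling weights over bacterial donor phyla.
#' @param fosmid_length_mean mean fosmid insert length in bases.
#' @param genes_per_genome genes per genome; used to derive the family
#'   count when `n_families` is `NULL`.
#' @param n_families number of gene families (overrides derivation).
#' @param n_marker_families single-copy marker families (carved from the
#'   archaeal-core allocation).
#' @param n_ribosomal_families ribosomal-protein reference families for
#'   CAI (also archaeal core).
#' @param strain_divergence within-lineage crown depth of the query clade,
#'   in substitutions/site; the study gives no figure, so it is exposed as
#'   a parameter rather than fixed.
#' @param protein_length_range amino-acid length range for family proteins.
#' @param n_per_phylum reference homolog leaves per bacterial phylum.
#' @param n_other_archaea distant-archaea homolog leaves per family.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return validated list of class `community_config`.
#' @export
community_config <- function(n_genomes = c(thaum = 15, gii_iii = 9),
                             lineage_gc = c(thaum = 0.4713, gii_iii = 0.5482),
                             class_proportions = c(
                               archaeal_core = 629,
                               lineage_core_native = 416,
                               lineage_core_early_hgt = 290,
                               shell_native = 452,
                               shell_late_hgt = 311,
                               orphan = 416) / 2514,
                             donor_phyla = c(Proteobacteria = 0.4,
                                             Actinobacteria = 0.3,
                                             Firmicutes = 0.2,
                                             Cyanobacteria = 0.1),
                             fosmid_length_mean = 36178,
                             genes_per_genome = 1400,
                             n_families = NULL,
                             n_marker_families = 40,
                             n_ribosomal_families = 20,
                             strain_divergence = 0.05,
                             protein_length_range = c(150, 450),
                             n_per_phylum = 6,
                             n_other_archaea = 6,
                             seed = 1) {
  if (any(n_genomes < 1)) stop("need at least one genome per lineage")
  if (length(n_genomes) != 2 || is.null(names(n_genomes)))
    stop("n_genomes must be a named vector of two lineages")
  if (!setequal(names(class_proportions), ORIGIN_CLASSES))
    stop("class_proportions must cover exactly: ",
         paste(ORIGIN_CLASSES, collapse = ", "))
  class_proportions <- class_proportions[ORIGIN_CLASSES]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0) || any(lineage_gc < 0 | lineage_gc > 1))
    stop("all fractions must lie in [0, 1]")
  if (any(donor_phyla < 0) || sum(donor_phyla) <= 0)
    stop("donor_phyla weights must be non-negative and not all zero")
  donor_phyla <- donor_phyla / sum(donor_phyla)
  structure(list(n_genomes = n_genomes, lineage_gc = lineage_gc,
                 class_proportions = class_proportions,
                 donor_phyla = donor_phyla,
                 fosmid_length_mean = fosmid_length_mean,
                 genes_per_genome = genes_per_genome,
                 n_families = n_families,
                 n_marker_families = n_marker_families,
                 n_ribosomal_families = n_ribosomal_families,
                 strain_divergence = strain_divergence,
                 protein_length_range = protein_length_range,
                 n_per_phylum = n_per_phylum,
                 n_other_archaea = n_other_archaea,
                 seed = as.integer(seed)),
            class = "community_config")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# evolve a root protein down `tree`; per branch of length t each site is
# redrawn uniformly from the 20-letter alphabet with probability 1-exp(-t)
.evolve_protein <- function(tree, root_seq) {
  n <- length(tree$tip.label)
  seqs <- vector("list", n + tree$Nnode)
  root_node <- n + 1L
  seqs[[root_node]] <- root_seq
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    t <- pre$edge.length[e]
    s <- seqs[[p]]
    hit <- runif(length(s)) < (1 - exp(-t))
    if (any(hit)) s[hit] <- sample(AA20, sum(hit), replace = TRUE)
    seqs[[ch]] <- s
  }
  out <- lapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""))
  setNames(unlist(out), tree$tip.label)
}

# clades are built as Newick fragments (no trailing ";") so single-leaf
# clades and nesting compose uniformly

# random rooted clade over `labels` with crown depth `depth`
.random_clade <- function(labels, depth) {
  n <- length(labels)
  if (n == 1) return(labels)
  tr <- ape::rcoal(n, tip.label = sample(labels))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * depth
  sub(";$", "", ape::write.tree(tr))
}

# join Newick fragments under a new node with the given stem lengths
.join_clades <- function(clades, stems) {
  paste0("(", paste0(unlist(clades), ":", stems, collapse = ","), ")")
}

.as_tree <- function(fragment) ape::read.tree(text = paste0(fragment, ";"))

# largest-remainder allocation of n items to the given proportions
.allocate <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(prop))
}

#' Simulate the family forest: gene trees and reference protein sequences
#'
#' Allocates origin classes across families (largest-remainder allocation,
#' so planted proportions are exact up to integer rounding), assigns
#' lineages, donors and member genomes, builds one gene tree per family
#' with the planted topology, and evolves protein sequences along it.
#' Native families place the query clade with the distant-archaea
#' homologs; transferred families nest it inside the donor phylum's clade.
#'
#' @param config a [community_config()].
#' @return object of class `community_forest`: list of family records plus
#'   the reference panel taxonomy.  Each family carries `id`, `class`,
#'   `lineage`, `donor_phylum`, `members` (gene id / genome table),
#'   `ref_presence`, `tree` (`phylo`, query genes + homolog panel),
#'   `proteins` (named amino-acid sequences for every leaf and reference
#'   gene), `panel_tax` and `annotation`.
#' @export
simulate_species_forest <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  lineages <- names(config$n_genomes)
  genomes <- unlist(lapply(lineages, function(l)
    sprintf("%s%02d", l, seq_len(config$n_genomes[[l]]))), use.names = FALSE)
  genome_lineage <- setNames(rep(lineages, config$n_genomes), genomes)
  ref_panel <- setNames(lapply(lineages, function(l) {
    k <- if (config$n_genomes[[l]] >= max(config$n_genomes)) 3 else 1
    sprintf("ref_%s_%d", l, seq_len(k))
  }), lineages)

  n_fam <- config$n_families
  if (is.null(n_fam)) {
    cp <- config$class_proportions
    G <- sum(config$n_genomes)
    e_genes <- cp[["archaeal_core"]] * G +
      (cp[["lineage_core_native"]] + cp[["lineage_core_early_hgt"]]) *
        mean(config$n_genomes) +
      (cp[["shell_native"]] + cp[["shell_late_hgt"]]) *
        mean(pmax(config$n_genomes / 3, 1)) +
      cp[["orphan"]]
    n_fam <- max(1L, round(config$genes_per_genome * G / e_genes))
  }
  alloc <- .allocate(n_fam, config$class_proportions)
  if (alloc[["archaeal_core"]] <
      config$n_marker_families + config$n_ribosomal_families)
    stop("archaeal_core allocation too small to hold marker and ribosomal ",
         "families; increase n_families or lower those counts")
  classes <- sample(rep(ORIGIN_CLASSES, alloc))

  phyla <- names(config$donor_phyla)
  # donors allocated by largest remainder too, so planted donor weights are
  # exact up to integer rounding
  n_hgt <- sum(grepl("hgt", classes))
  donor_pool <- if (n_hgt)
    sample(rep(phyla, .allocate(n_hgt, config$donor_phyla))) else character(0)
  donor_next <- 0L
  panel_bact <- unlist(lapply(phyla, function(p)
    sprintf("bact_%s_%d", p, seq_len(config$n_per_phylum))), use.names = FALSE)
  other_arch_phy <- rep(c("Crenarchaeota", "Euryarchaeota_distant"),
                        length.out = config$n_other_archaea)

  marker_left <- config$n_marker_families
  ribo_left <- config$n_ribosomal_families
  families <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    fid <- sprintf("F%04d", i)
    cls <- classes[i]
    lineage <- if (cls == "archaeal_core") NA_character_ else
      sample(lineages, 1, prob = config$n_genomes)
    donor <- if (grepl("hgt", cls)) {
      donor_next <- donor_next + 1L
      donor_pool[donor_next]
    } else NA_character_
    # member genomes
    member_genomes <- switch(cls,
      archaeal_core = genomes,
      lineage_core_native = ,
      lineage_core_early_hgt = {
        g <- genomes[genome_lineage == lineage]
        if (length(g) > 2 && runif(1) < 0.15) g <- sample(g, length(g) - 1)
        g
      },
      shell_native = ,
      shell_late_hgt = {
        g <- genomes[genome_lineage == lineage]
        sample(g, sample.int(max(1L, floor(length(g) / 2)), 1))
      },
      orphan = sample(genomes[genome_lineage == lineage], 1))
    gene_ids <- sprintf("%s_%s", member_genomes, fid)
    L <- sample(seq(config$protein_length_range[1],
                    config$protein_length_range[2]), 1)

    is_marker <- FALSE; is_ribo <- FALSE
    if (cls == "archaeal_core" && marker_left > 0) {
      is_marker <- TRUE; marker_left <- marker_left - 1
    } else if (cls == "archaeal_core" && ribo_left > 0) {
      is_ribo <- TRUE; ribo_left <- ribo_left - 1
    }
    annotation <- if (is_marker) {
      sprintf("single-copy marker protein %s", fid)
    } else if (is_ribo) {
      sprintf("ribosomal protein L%d", i %% 36 + 1)
    } else sprintf("hypothetical protein family %s", fid)

    # reference-genome presence
    ref_presence <- switch(cls,
      archaeal_core = unlist(ref_panel, use.names = FALSE),
      lineage_core_native = ,
      lineage_core_early_hgt = {
        r <- ref_panel[[lineage]]
        if (length(r) >= 3 && runif(1) < 0.15) r <- sample(r, length(r) - 1)
        r
      },
      character(0))

    if (cls == "orphan") {
      prot <- paste(sample(AA20, L, replace = TRUE), collapse = "")
      families[[i]] <- list(id = fid, class = cls, lineage = lineage,
                            donor_phylum = donor, is_marker = FALSE,
                            is_ribosomal = FALSE, annotation = annotation,
                            members = data.frame(gene_id = gene_ids,
                                                 genome = member_genomes,
                                                 stringsAsFactors = FALSE),
                            ref_presence = character(0), tree = NULL,
                            proteins = setNames(prot, gene_ids),
                            panel_tax = NULL)
      next
    }

    ref_gene_ids <- if (length(ref_presence))
      sprintf("%s_%s", ref_presence, fid) else character(0)
    # query clade: fosmid genes plus reference-genome copies
    query_clade <- if (cls == "archaeal_core") {
      subclades <- lapply(lineages, function(l) {
        labs <- c(gene_ids[genome_lineage[member_genomes] == l],
                  ref_gene_ids[grepl(paste0("^ref_", l), ref_gene_ids)])
        .random_clade(labs, config$strain_divergence)
      })
      .join_clades(subclades, rep(0.1, length(subclades)))
    } else {
      .random_clade(c(gene_ids, ref_gene_ids), config$strain_divergence)
    }

    arch_labs <- sprintf("arch_%s_%d", fid, seq_len(config$n_other_archaea))
    arch_clade <- .random_clade(arch_labs, 0.15)
    phylum_clades <- lapply(phyla, function(p) {
      labs <- sprintf("bact_%s_%s_%d", p, fid, seq_len(config$n_per_phylum))
      .random_clade(labs, 0.12)
    })
    names(phylum_clades) <- phyla

    if (grepl("hgt", cls)) {
      # nest the query clade inside the donor phylum: split the donor clade
      # in two and make the query sister to one half
      labs <- sprintf("bact_%s_%s_%d", donor, fid,
                      seq_len(config$n_per_phylum))
      h <- ceiling(length(labs) / 2)
      half1 <- .random_clade(labs[seq_len(h)], 0.08)
      half2 <- .random_clade(labs[-seq_len(h)], 0.08)
      inner <- .join_clades(list(query_clade, half2), c(0.18, 0.05))
      phylum_clades[[donor]] <- .join_clades(list(half1, inner), c(0.05, 0.05))
      bact <- .join_clades(phylum_clades, rep(0.2, length(phylum_clades)))
      tree <- .as_tree(.join_clades(list(bact, arch_clade), c(0.1, 0.25)))
    } else {
      bact <- .join_clades(phylum_clades, rep(0.2, length(phylum_clades)))
      archside <- .join_clades(list(query_clade, arch_clade), c(0.2, 0.12))
      tree <- .as_tree(.join_clades(list(archside, bact), c(0.12, 0.12)))
    }

    root_seq <- sample(AA20, L, replace = TRUE)
    proteins <- .evolve_protein(tree, root_seq)

    leaf <- tree$tip.label
    is_bact <- grepl("^bact_", leaf)
    is_arch_out <- grepl("^arch_", leaf)
    is_ref <- grepl("^ref_", leaf)
    phylum <- rep(NA_character_, length(leaf))
    phylum[is_bact] <- sub("^bact_([^_]+)_.*$", "\\1", leaf[is_bact])
    phylum[is_arch_out] <- other_arch_phy[
      as.integer(sub(".*_(\\d+)$", "\\1", leaf[is_arch_out]))]
    qphylum <- if (cls == "archaeal_core") "query" else lineage
    phylum[!is_bact & !is_arch_out] <- qphylum
    domain <- ifelse(is_bact, "Bacteria", "Archaea")
    panel_tax <- taxonomy_map(leaf, domain, phylum,
                              is_query = !is_bact & !is_arch_out & !is_ref)

    # reference copies are panel context for presence calls, not tree leaves
    gene_tree <- if (length(ref_gene_ids))
      ape::drop.tip(tree, ref_gene_ids) else tree

    families[[i]] <- list(id = fid, class = cls, lineage = lineage,
                          donor_phylum = donor, is_marker = is_marker,
                          is_ribosomal = is_ribo, annotation = annotation,
                          members = data.frame(gene_id = gene_ids,
                                               genome = member_genomes,
                                               stringsAsFactors = FALSE),
                          ref_presence = ref_presence, tree = gene_tree,
                          proteins = proteins,
                          panel_tax = panel_tax[!panel_tax$leaf %in% ref_gene_ids, ])
  }
  structure(list(families = families, genomes = genomes,
                 genome_lineage = genome_lineage, ref_panel = ref_panel,
                 config = config), class = "community_forest")
}

#' @export
print.community_forest <- function(x, ...) {
  cls <- vapply(x$families, `[[`, character(1), "class")
  cat(sprintf("community forest: %d families, %d genomes (%s)\n",
              length(x$families), length(x$genomes),
              paste(names(x$config$n_genomes), collapse = " + ")))
  print(table(cls))
  invisible(x)
}

# codon table biased so coding sequences hit a target GC fraction; the
# single knob is a shared log-odds on G+C content of the codon
.gc_codon_weights <- function(target_gc, aa_freq) {
  uni <- .codon_universe()
  uni <- uni[uni$aa != "*", ]
  gc_count <- vapply(strsplit(uni$codon, ""), function(x)
    sum(x %in% c("G", "C")), numeric(1))
  exp_gc <- function(beta) {
    w <- exp(beta * gc_count)
    num <- 0; den <- 0
    for (a in names(aa_freq)) {
      idx <- uni$aa == a
      p <- w[idx] / sum(w[idx])
      num <- num + aa_freq[[a]] * sum(p * gc_count[idx])
      den <- den + aa_freq[[a]] * 3
    }
    num / den
  }
  beta <- tryCatch(stats::uniroot(function(b) exp_gc(b) - target_gc,
                                  c(-8, 8))$root,
                   error = function(e) if (exp_gc(0) < target_gc) 8 else -8)
  w <- exp(beta * gc_count)
  split(data.frame(codon = uni$codon, w = w, stringsAsFactors = FALSE), uni$aa)
}

.back_translate <- function(protein, weights) {
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    tab <- weights[[a]]
    if (is.null(tab)) return("NNN")
    sample(tab$codon, 1, prob = tab$w)
  }, character(1), USE.NAMES = FALSE)
  paste(cods, collapse = "")
}

.random_spacer <- function(len, gc) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Emit the fosmid library: FASTA, feature table and truth table
#'
#' Lays each genome's genes out in random order and strand with
#' GC-matched intergenic spacers, back-translates proteins with the
#' lineage's GC-calibrated codon table (stop codon appended), and cuts the
#' genome into fosmid inserts whose lengths are drawn around
#' `fosmid_length_mean` (sd 5% of the mean) with boundaries snapped to
#' intergenic midpoints, so every gene lands on exactly one fosmid.
#'
#' @param config the [community_config()] used for the forest.
#' @param forest a [simulate_species_forest()] result.
#' @return list of class `fosmid_library` with `fosmids` (named nucleotide
#'   strings), `features` (0-based half-open coordinates), `truth`,
#'   `proteins` (fosmid gene translations), `cds` (nucleotide CDSs),
#'   `fosmid_lineage`, `ref_genes`/`ref_proteins` (reference inventories),
#'   `db_proteins`/`db_tax` (homolog panel) and `annotations`.
#' @export
emit_fosmid_library <- function(config, forest) {
  stopifnot(inherits(forest, "community_forest"))
  set.seed(config$seed + 1L)
  max_len_nt <- 3 * (config$protein_length_range[2] + 1)
  if (config$fosmid_length_mean < max_len_nt + 40)
    stop("fosmid_length_mean too small to hold the largest gene")

  fams <- forest$families
  lineages <- names(config$n_genomes)
  # per-genome gene lists
  genome_genes <- setNames(vector("list", length(forest$genomes)),
                           forest$genomes)
  for (f in fams) {
    for (j in seq_len(nrow(f$members))) {
      g <- f$members$genome[j]
      genome_genes[[g]] <- c(genome_genes[[g]],
                             setNames(f$id, f$members$gene_id[j]))
    }
  }
  fam_by_id <- setNames(fams, vapply(fams, `[[`, character(1), "id"))

  # codon weights per lineage from that lineage's amino-acid composition
  weights <- list()
  for (l in lineages) {
    prot <- unlist(lapply(fams, function(f) {
      idx <- forest$genome_lineage[f$members$genome] == l
      unname(f$proteins[f$members$gene_id[idx]])
    }), use.names = FALSE)
    aa <- table(strsplit(paste(prot, collapse = ""), "")[[1]])
    weights[[l]] <- .gc_codon_weights(config$lineage_gc[[l]],
                                      as.list(aa / sum(aa)))
  }

  fosmids <- character(0); features <- list(); truth <- list()
  cds_all <- character(0)
  fosmid_lineage <- character(0)
  stops <- c("TAA", "TGA", "TAG")
  for (g in forest$genomes) {
    l <- forest$genome_lineage[[g]]
    ids <- names(genome_genes[[g]])
    ord <- sample(seq_along(ids))
    ids <- ids[ord]
    fam_ids <- unname(genome_genes[[g]])[ord]
    # build gene nucleotide sequences
    nts <- character(length(ids))
    for (j in seq_along(ids)) {
      prot <- fam_by_id[[fam_ids[j]]]$proteins[[ids[j]]]
      nts[j] <- paste0(.back_translate(prot, weights[[l]]),
                       sample(stops, 1))
    }
    cds_all[ids] <- nts
    # tile into fosmids with intergenic spacers
    target <- max(rnorm(1, config$fosmid_length_mean,
                        0.05 * config$fosmid_length_mean), max_len_nt + 40)
    fos_seq <- ""; fos_feat <- list(); fos_n <- 0L
    flush_fosmid <- function() {
      if (!nchar(fos_seq)) return()
      fos_n <<- fos_n + 1L
      fid <- sprintf("%s_fos%02d", g, fos_n)
      fosmids[[fid]] <<- fos_seq
      fosmid_lineage[[fid]] <<- l
      for (ft in fos_feat) {
        ft$fosmid <- fid
        features[[length(features) + 1L]] <<- ft
      }
      fos_seq <<- ""; fos_feat <<- list()
      target <<- max(rnorm(1, config$fosmid_length_mean,
                           0.05 * config$fosmid_length_mean),
                     max_len_nt + 40)
    }
    for (j in seq_along(ids)) {
      spacer <- .random_spacer(sample(30:150, 1), config$lineage_gc[[l]])
      strand <- sample(c("+", "-"), 1)
      gene_nt <- if (strand == "+") nts[j] else .revcomp(nts[j])
      start <- nchar(fos_seq) + nchar(spacer)
      fos_seq <- paste0(fos_seq, spacer, gene_nt)
      fos_feat[[length(fos_feat) + 1L]] <- data.frame(
        fosmid = NA_character_, start = start,
        end = start + nchar(gene_nt), strand = strand,
        gene_id = ids[j], family_id = fam_ids[j],
        annotation = fam_by_id[[fam_ids[j]]]$annotation,
        stringsAsFactors = FALSE)
      if (nchar(fos_seq) >= target) {
        fos_seq <- paste0(fos_seq, .random_spacer(sample(30:150, 1),
                                                  config$lineage_gc[[l]]))
        flush_fosmid()
      }
    }
    if (nchar(fos_seq)) {
      fos_seq <- paste0(fos_seq, .random_spacer(sample(30:150, 1),
                                                config$lineage_gc[[l]]))
      flush_fosmid()
    }
  }
  features <- do.call(rbind, features)
  rownames(features) <- NULL

  truth <- do.call(rbind, lapply(fams, function(f) {
    data.frame(gene_id = f$members$gene_id, family_id = f$id,
               origin_class = f$class,
               donor_domain = ifelse(grepl("hgt", f$class), "Bacteria",
                                     NA_character_),
               donor_phylum = f$donor_phylum %||% NA_character_,
               genome = f$members$genome,
               lineage = forest$genome_lineage[f$members$genome],
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  proteins <- unlist(lapply(fams, function(f)
    f$proteins[f$members$gene_id]))
  # reference inventories and homolog panel
  ref_rows <- list(); ref_proteins <- character(0)
  db_proteins <- character(0); db_tax <- list()
  for (f in fams) {
    if (length(f$ref_presence)) {
      rid <- sprintf("%s_%s", f$ref_presence, f$id)
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        ref_genome = f$ref_presence, gene_id = rid, family_id = f$id,
        stringsAsFactors = FALSE)
      ref_proteins[rid] <- unname(f$proteins[rid])
    }
    if (!is.null(f$panel_tax)) {
      panel <- f$panel_tax[!f$panel_tax$is_query, , drop = FALSE]
      db_proteins[panel$leaf] <- unname(f$proteins[panel$leaf])
      db_tax[[length(db_tax) + 1L]] <- panel
    }
  }
  annotations <- setNames(
    rep(vapply(fams, `[[`, character(1), "annotation"),
        vapply(fams, function(f) nrow(f$members), integer(1))),
    unlist(lapply(fams, function(f) f$members$gene_id), use.names = FALSE))

  structure(list(
    fosmids = unlist(fosmids), features = features, truth = truth,
    proteins = proteins, cds = cds_all,
    fosmid_lineage = unlist(fosmid_lineage),
    ref_genes = do.call(rbind, ref_rows), ref_proteins = ref_proteins,
    db_proteins = db_proteins, db_tax = do.call(rbind, db_tax),
    ref_panel = forest$ref_panel, annotations = annotations,
    config = config), class = "fosmid_library")
}

#' @export
print.fosmid_library <- function(x, ...) {
  cat(sprintf("fosmid library: %d fosmids, %d genes, %.1f kb total\n",
              length(x$fosmids), nrow(x$features),
              sum(nchar(x$fosmids)) / 1000))
  invisible(x)
}
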