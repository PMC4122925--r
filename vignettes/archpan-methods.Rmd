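---
title: "Methods: pangenome construction and interdomain HGT inference for uncultured marine archaea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome construction and interdomain HGT inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archpan)
```

## The problem

Deep-sea planktonic archaea — marine Thaumarchaeota and the uncultured
Group II/III Euryarchaeota — are known almost entirely from environmental
sequence. Fosmid-sized genome fragments (~36 kb) give access to physically
linked gene neighbourhoods, which makes two questions tractable at once:
what does the *pangenome* of such a lineage look like (which gene families
are core to all archaea, specific to the lineage, or accessory "shell"
genes), and how much of it arrived by horizontal gene transfer (HGT) from
bacteria — and when. A transfer that landed at the base of a lineage is
inherited by all of its members and therefore shows up in the
lineage-specific core ("early" HGT); a transfer after diversification is
present only in a subset of strains and lands in the shell ("late" HGT).

`archpan` implements that analysis as a tested pipeline: ortholog
clustering from homology evidence, presence-based classification against
reference genome panels, gene-tree-based HGT calling with donor
attribution and early/late timing, and the supporting statistics
(tetranucleotide z-score binning, quality-threshold clustering of taxon
profiles, synteny-block bounding couples, codon usage and the codon
adaptation index, genome equivalents from single-copy markers). A
synthetic fosmid community with planted truth exercises every stage.

## Pangenome classes and summary arithmetic

Ortholog (OG) clusters are connected components of the gene homology
graph: an edge joins two genes when a pairwise hit passes all three
thresholds — percent identity, e-value, and coverage defined as
`align_length / min(query_length, subject_length)`. Defaults are 30%
identity, 1e-5, and 0.70 coverage; single-linkage components are the
standard, deliberately inclusive choice, and all three knobs are exposed.

Classification against the reference panels follows presence rules:

* **archaeal core** — present in every genome of every reference lineage
  panel (universal genes included);
* **lineage-specific core** — present in at least `n_refs - allow_missing`
  genomes of the cluster's own lineage. `allow_missing` defaults to 1 for
  a three-genome panel (accommodating a single lineage-specific loss) and
  0 for a single composite reference genome;
* **orphan** — a single gene with no homolog anywhere;
* **shell** — everything else, including families with only 1–3 database
  homologs and families whose homologs all lie outside Archaea.

Derived HGT percentages use one denominator: total OG clusters *plus*
orphan genes. Early and late percentages share that denominator, so
`total = early + late` holds exactly at full precision; report-layer
values are rounded half-up to one decimal only at output. With this
arithmetic the five class counts, the lineage-core and shell totals, and
the three percentages are mutually consistent by construction — the late
fraction is always the total minus the early fraction up to rounding, and
the package reports that value rather than adjusting any class count.

```{r table-arith}
pangenome_summary(
  c(core = 629, lineage_core_native = 416, lineage_core_early_hgt = 290,
    shell_native = 452, shell_late_hgt = 311), orphans = 416,
  lineage = "Thaumarchaeota")
```

## Reading HGT from gene trees

Tree inspection is the step most analyses leave manual. `call_hgt()`
commits to one explicit, deterministic operationalization, applied to
unrooted bipartitions so that verdicts cannot depend on the arbitrary
rooting or leaf order of the input Newick:

1. **Exclusion of thin trees.** Fewer than 4 informative non-query leaves:
   `excluded` (too little signal to read).
2. **Query monophyly.** Some bipartition must split exactly the query
   leaves from the rest, with support at least `min_support` (default
   0.8). Non-monophyletic or unsupported queries are `unresolved`.
3. **Nesting** (`nested_in_phylum`). The smallest enclosing clade of the
   query with at least 5 non-query leaves must be ≥ 90% bacterial and
   ≥ 80% one bacterial phylum, with a supported defining edge. Only
   clades the query branches *strictly inside of* qualify: the defining
   edge may not touch the query's attachment node, because a query merely
   sister to a phylum clade is not nested in it. Size ties resolve to
   fewer non-query leaves, then to the clade closest to the query (the
   outward-walk order), then lexicographically.
4. **Isolation** (`isolated_among_bacteria`). With at least
   `min_bacterial_leaves` (10) bacterial leaves from at least
   `min_bacterial_phyla` (3) phyla in the tree, the query is called
   transferred when no other archaeon is present, or when it lies beneath
   at least two supported, archaea-free, bacterial-majority enclosing
   clades — every path from the query to another archaeal leaf then
   crosses bacterial context twice. The donor stays at domain level
   unless nesting also identifies a phylum.
5. Trees mixing archaeal and bacterial leaves with no supported internal
   edge at all are `excluded`; everything else is `native`.

The purity thresholds (90%/80%) rather than strict donor-phylum monophyly
absorb limited HGT among the bacterial reference leaves themselves. The
thresholds 0.8 / 3 / 10 / 5 are declared operational choices for language
like "reasonable support" and "many bacterial phyla"; all are exposed as
configuration. Two properties are enforced by tests: the caller agrees
with an exhaustive bipartition-enumeration oracle on thousands of random
small trees, and raising `min_support` never converts `native` into
`hgt` (conservativeness is monotone).

Support handling has two deliberate conventions. In a rooted binary tree
the two root edges describe the same split; their labels are merged with
`max` when they disagree. Splits cutting off a single leaf carry no
support (they are trivially true), so they never count as "supported
structure".

Timing then follows from the pangenome class: an HGT cluster in the
lineage-specific core is `early`, in the shell `late`; an archaeal-core
cluster with an HGT verdict is flagged as a conflict and left untimed.

### Tree inference

The topology-reading rule, not tree inference, is the contribution here,
so the default engine is deliberately simple and dependency-free:
Poisson-corrected protein distances (`d = -log(1 - p)`, observed
difference capped at 0.95 to keep the correction finite, pairwise
deletion of gap sites) under BIONJ, with bipartition supports from 100
bootstrap replicates. Externally computed Newick trees are accepted
wherever a tree is consumed. Alignment columns with a gap fraction
strictly above 0.20 are removed first (a column at exactly 0.20 stays).

## Composition profiles and binning

Tetranucleotide (and pentanucleotide) z-scores follow the maximal-order
Markov expectation: for a word `w = n1..nk`,
`E = N(prefix) N(suffix) / N(core)` and
`V = E (N(core)-N(prefix)) (N(core)-N(suffix)) / N(core)^2`, with
`z = (obs - E) / sqrt(V)`. Counts are taken over the sequence and its
reverse complement (summed, no junction words), so profiles are
strand-symmetric — fosmid insert orientation is arbitrary. Words with an
unobserved core or non-positive variance get `z = 0` and a flag. The PCA
wrapper uses covariance by default (correlation optional) and fixes each
component's sign so the largest-magnitude loading is positive, making
embeddings reproducible.

Quality-threshold clustering of per-fosmid taxon profiles extracts, at
each step, the largest subset whose pairwise distances all stay within
the diameter bound (a maximum clique of the threshold graph, found with
`igraph`), breaking ties by lower diameter and then by smallest member
ids. The metric is Euclidean on percentage vectors with a default
diameter of 30 percentage points; both are configuration, since the
method name alone fixes neither.

## Synteny blocks and bounding couples

Blocks are maximal runs of contiguous genes with the same origin class
(five classes: archaeal core, lineage-specific core, early HGT, late HGT,
other), i.e. run-length encoding of the per-fosmid class string, measured
in genes — the unit the statistic is defined in. Each *interior* block
contributes the unordered pair of its flanking classes to one of
k(k+1)/2 = 15 bounding-couple categories; terminal blocks have at most
one flank and are excluded from the matrix but tallied separately so the
totals remain auditable (counting them would require inventing an edge
convention). A per-gene weighting is available as a flag. Flank-pattern
rows are normalized to fractions and clustered by average linkage on
Euclidean distances, rows pre-sorted by label for deterministic ties.

## Codon usage and CAI

The usage table counts codons over a reference set of highly expressed
genes (ribosomal proteins in the pipeline), smooths unseen codons to 0.5
counts, and derives relative adaptiveness `w = f / max(f)` within each
synonym family. CAI is the geometric mean of `w` over a gene's codons,
excluding Met, Trp and stops (amino acids without synonymous choice carry
no information); a gene built entirely from modal codons scores exactly
1. The 0.5-count smoothing is a declared convention, stated so results
are bit-reproducible. Codon-usage PCA embeds per-gene 59-dimensional
synonymous-frequency vectors through the same PCA wrapper.

## The synthetic community

The generator's defaults are the study conditions the pipeline is meant
to operate under: two archaeal lineages with GC 47.13% and 54.82%,
roughly 15 and 9 genome equivalents, mean fosmid insert length 36,178 bp
(sd 5% of the mean), 40 single-copy marker families, and an origin-class
mix matching a deep-sea thaumarchaeal pangenome's cluster-count
distribution. Within-lineage strain divergence has no published figure
and is exposed as a parameter (default 0.05 substitutions/site crown
depth).

Design choices, made once:

* **Exact allocation.** Origin classes and donor phyla are allocated by
  largest-remainder rounding rather than i.i.d. sampling, so planted
  proportions are exact up to integer rounding and parameter-recovery
  comparisons measure the pipeline, not multinomial noise.
* **Sequence evolution** is per-site substitution on the 20-letter
  alphabet (each site redrawn uniformly with probability `1 - exp(-t)`
  per branch of length `t`): topology recovery, not realism, is what the
  downstream tests need. Branch lengths are set so neighbor joining
  recovers the planted topology in well over 90% of families at default
  divergence.
* **Planted topology.** Native families place the query clade with the
  distant-archaea homologs and the bacterial phyla outside; transferred
  families split the donor phylum clade in two and make the query sister
  to one half, so the query is strictly nested. Early transfers are
  present in all (or all but one) genomes of their lineage *and* in its
  reference genomes; late transfers sit in a strict subset of genomes and
  are absent from references — which is exactly what makes timing
  recoverable from presence rules.
* **Back-translation** realizes each lineage's GC target through a single
  log-odds knob on codon G+C content, calibrated by root finding against
  the lineage's amino-acid composition; intergenic spacers are drawn at
  the same GC. This is the simplest mechanism that separates the lineages
  in tetranucleotide and codon-usage space.
* **Orphans** are lone random sequences with no family partners; marker
  and ribosomal families are carved from the archaeal-core allocation and
  occur exactly once per genome.
* Fosmids tile each genome completely with boundaries snapped to
  intergenic midpoints, so every gene lands on exactly one fosmid and the
  truth table is a bijection onto the feature table.

What the generator does *not* emulate: indels (alignments are gap-free,
so trimming is exercised on constructed fixtures), sequencing error,
chimeric inserts, paralogy, rate heterogeneity across sites, and
composition-driven tree artifacts. Passing the end-to-end tests therefore
shows the pipeline's logic is correct under clean signal of realistic
strength; it does not certify performance on noisy real alignments, where
the conservative `unresolved`/`excluded` routes are expected to absorb
much more of the input.

Homology evidence for simulated proteins is ungapped identity between
equal-length pairs (family members share their ancestral length), mapped
to a monotone surrogate e-value; unrelated equal-length proteins score
near the random-identity floor, far below any threshold in use.

## Problem sizes and determinism

The test suite runs the full pipeline on a 40-family, 9-genome community
for integration checks and on a 200-family community (25% planted
transfers, four donor phyla at weights 0.4/0.3/0.2/0.1) for parameter
recovery; `scripts/acceptance.R` re-runs the latter from scratch. Those
sizes keep a complete run in minutes on one CPU while leaving binomial
noise at n = 200 well inside the ±5-point recovery band. Every stochastic
stage (simulation, bootstrap) derives from an explicit integer seed, and
a fixed seed reproduces FASTA, feature tables and verdicts byte for byte.

## Known limitations

* The nesting/isolation rule set is one faithful formalization of what is
  usually a manual reading of trees; its thresholds are declared, not
  fitted, and per-gene agreement with any particular manual analysis is
  not claimed.
* Single-linkage clustering can chain families through promiscuous
  domains on real data; the identity/coverage thresholds are the only
  guard, as paralog splitting and synteny-aware orthology are out of
  scope.
* `shared_hgt_with_outgroup()` without trees is an upper bound by
  construction and is flagged as such.
* Genome-equivalent estimates assume markers are genuinely single-copy in
  the sampled taxa.
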