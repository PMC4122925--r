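# archpan

Pangenome construction and interdomain horizontal gene transfer (HGT)
inference for uncultured marine archaea, built around fosmid-sized genome
fragments.

Deep-sea planktonic Thaumarchaeota and Group II/III Euryarchaeota are
known almost entirely from environmental sequencing. Fosmid libraries
(~36-kb cloned inserts) preserve gene neighbourhoods, which lets one
build a *pangenome* for each lineage — the union of its ortholog (OG)
clusters — and ask how much of it was imported from bacteria, and when.
`archpan` provides that analysis as a tested R pipeline:

* **Gene finding and validation** — six-frame ORF scanning (translation
  table 11) with hit-table-based validation (genes at e ≤ 1e-10, motif
  evidence at e ≤ 1e-5, small no-hit candidates dropped).
* **Ortholog clustering** — single-linkage components of the homology
  graph at identity/coverage/e-value thresholds.
* **Pangenome classes** — archaeal core (present in all reference
  lineages), lineage-specific core (all — or all but one — own-lineage
  references), shell, orphan.
* **HGT calling from gene trees** — on unrooted bipartitions, a cluster
  is transferred when its query clade either *nests* inside a bacterial
  phylum's clade (smallest enclosing clade ≥ 90% bacterial, ≥ 80% one
  phylum, supported) or is *isolated among bacteria* away from all other
  archaea; poorly resolved trees are conservatively `unresolved` or
  `excluded`. Transfers into the lineage-specific core are **early**
  (at the base of the lineage); transfers into the shell are **late**.
* **Summary arithmetic** — HGT percentages over total clusters plus
  orphans, e.g. counts (629, 416, 290, 452, 311; 416 orphans) give
  23.9% total and 11.5% early HGT.
* **Supporting statistics** — tetranucleotide z-score profiles with PCA
  for lineage binning, quality-threshold clustering of taxon profiles,
  synteny blocks with the 15 bounding-couple categories, codon usage /
  CAI against ribosomal-protein references, and genome equivalents from
  single-copy markers.
* **A synthetic fosmid community** with planted origin classes, donors
  and GC regimes, so the whole pipeline is testable end to end without
  any downloads.

See `vignettes/archpan-methods.Rmd` for the model, every threshold and
its default, and the design decisions.

## Worked example

Simulate a small two-lineage community and run the pipeline:

```r
library(archpan)

cfg <- community_config(n_genomes = c(thaum = 5, gii_iii = 4),
                        n_families = 40, n_marker_families = 5,
                        n_ribosomal_families = 4, seed = 7)
forest <- simulate_species_forest(cfg)
lib    <- emit_fosmid_library(cfg, forest)
lib
#> fosmid library: 9 fosmids, 159 genes, 167.2 kb total

report <- run_pipeline(lib, pipeline_config(seed = 11, n_boot = 50))
report
#> archpan pipeline report
#> Pangenome summary (thaum)
#>   core                     10
#>   lineage_core_native      3
#>   lineage_core_early_hgt   2
#>   shell_native             3
#>   shell_late_hgt           2
#>   total_clusters           20
#>   orphans                  3
#>   HGT: total 17.4%  early 8.7%  late 8.7%
#> Pangenome summary (gii_iii)
#>   core                     10
#>   lineage_core_native      4
#>   lineage_core_early_hgt   2
#>   shell_native             4
#>   shell_late_hgt           3
#>   total_clusters           23
#>   orphans                  4
#>   HGT: total 18.5%  early 7.4%  late 11.1%
#> recovery: planted 22.5%, recovered 22.5% HGT (sens 1.00, fpr 0.000)
```

Each lineage's summary is the five-class count matrix with the derived
HGT percentages (denominator: clusters + orphans). Because the library
is synthetic, the report also carries a truth-vs-called confusion table;
here all 20 planted origin classes per lineage were recovered exactly
(sensitivity 1.00 at zero false positives). `render_report(report, dir)`
writes every table as TSV with a JSON twin, plus tetra-PCA and
donor-spectrum SVG figures.

Summary arithmetic can also be used standalone on a printed count matrix:

```r
pangenome_summary(
  c(core = 629, lineage_core_native = 416, lineage_core_early_hgt = 290,
    shell_native = 452, shell_late_hgt = 311), orphans = 416)
#>   ...
#>   HGT: total 23.9%  early 11.5%  late 12.4%
```

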