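# apespectra

Compartmentalized mutation-spectrum analysis of multi-species
polymorphism panels.

Germline mutation rates are shaped by two kinds of forces:
*trans*-acting modifiers (for example DNA-repair variants) that shift
the mutation spectrum genome-wide, and *cis*-acting features of the
local genomic environment — replication timing, chromatin state, repeat
context — that shift it only in particular regions. `apespectra`
implements an analysis that separates the two by comparing triplet
mutation spectra **between genomic compartments within species** and
**between species within compartments**, using segregating variation
from a multi-genus panel in place of directly observed mutations.

The package provides, end to end:

- **Mutation class catalog** — the 96 strand-collapsed triplet
  substitution classes (32 central-A/C contexts × 3 derived alleles) and
  the 24,576-class 7-mer refinement, with a fixed canonical order used
  by every spectrum (`mutation_classes()`, `classify_mutation()`).
- **Polarization and filtering** — cross-genus parsimony polarization of
  biallelic sites, followed by a fixed filter cascade: N-context,
  recurrent derived allele, singletons (or doubleton-only mode), derived
  allele frequency ≥ 0.5, and an exact one-sided Hardy–Weinberg
  excess-heterozygosity test (`filter_sites()`,
  `hwe_excess_het_test()`).
- **Compartments** — BED-backed interval sets with algebra, k-mer
  content counting, replication-timing quartile construction, and a
  length-preserving bootstrap that places ERV-like segment multisets
  uniformly inside a background compartment (`compartment_content()`,
  `bootstrap_ervlike()`).
- **Spectra** — species-level (one count per segregating site),
  individual full-mode (heterozygote 1, homozygote 2), and randomized
  haplotype-thinned spectra in which each site is credited to exactly
  one carrier haplotype (`species_spectrum()`, `individual_spectrum()`,
  `randomized_spectrum()`).
- **Content normalization** — rescaling of class counts by reference
  compartment context content, content-matched count downscaling for
  two-compartment tests, and a 7-mer content correction that asks what a
  compartment's triplet spectrum would be if its extended sequence
  composition matched a target (`rescale_rates()`,
  `downscale_counts()`, `sevenmer_correct()`).
- **Comparative statistics** — PCA with deterministic sign conventions,
  multiplicative-update NMF signature extraction, cosine-distance
  signature clustering, within/between-group spectrum distances,
  log-odds heatmaps, a multinomial likelihood test assigning de novo
  mutation (DNM) sets to species with the fold-range ≥ 20 (α = 0.05)
  convention, and a bootstrap enrichment test for single classes
  (`run_pca()`, `run_nmf()`, `dnm_fit_test()`,
  `bootstrap_enrichment_test()`).
- **Synthetic panels** — a generator that plants known trans-acting
  signature mixtures, compartment-specific cis multipliers, a 1/k site
  frequency spectrum with optional gBGC tilt, excess-heterozygosity
  contamination and shared ancestral variants, and records the full
  ground truth (`simulate_panel()`).
- **Pipeline** — one call that runs simulate (or load) → filter →
  spectra → normalize → PCA/NMF/distances/heatmaps and writes every
  artifact plus an md5 manifest (`run_pipeline()`).

## Worked example

Simulate a two-genus panel in which chimp-like and gorilla-like lineages
draw from different trans-acting signature mixtures, and an ERV-like
compartment carries a planted 2× cis multiplier on `ACG>G`; then
polarize, filter, build spectra and recover the cis effect.

```r
library(apespectra)

# Three trans-acting signatures over disjoint class blocks
cls <- mutation_classes(3)
base <- setNames(rep(0.002, 96), cls)
blockify <- function(block) {
  v <- base; v[block] <- v[block] + (1 - sum(base)) / length(block)
  v / sum(v)
}
sigs <- rbind(cpg = blockify(cls[grepl("CG>T$", cls)]),
              a2g = blockify(cls[grepl("^.A.>G$", cls)]),
              c2t = blockify(cls[grepl("^.C.>T$", cls) & !grepl("CG>T$", cls)]))
colnames(sigs) <- cls

cfg <- simulation_config(
  seed = 11, sequence_length = 5e5, n_chromosomes = 1,
  genera = list(Pan = list(troglodytes = 6), Gorilla = list(gorilla = 6)),
  lineage_dosages = list(troglodytes = c(0.7, 0.2, 0.1),
                         gorilla = c(0.1, 0.2, 0.7)),
  true_signatures = sigs,
  compartments = list(
    list(name = "ncnr", fraction = 0.6),
    list(name = "erv", fraction = 0.4, cis = c("ACG>G" = 2))),
  n_snvs_per_lineage = 8000, shared_ancestral_fraction = 0.05)
sim <- simulate_panel(cfg)

# polarize by cross-genus parsimony and run the site filter cascade
flt <- filter_sites(sim$calls, sim$panel, sim$reference)
flt$tally
#>                DAF>=0.5 multi-genus-segregating               singleton
#>                    4295                     375                    5304
nrow(flt$kept)
#> [1] 6826

# per-individual randomized spectra in the reference compartment
ncnr <- sites_in_compartment(flt, sim$compartments$ncnr)
spectra <- randomized_spectrum(ncnr, seed = 11)
spectra[1:2, c("ACA>G", "ACG>T", "TAT>G")]
#>                            ACA>G ACG>T TAT>G
#> troglodytes_troglodytes_01     2    54     4
#> troglodytes_troglodytes_02     1    46     4

# content-normalized rates and the ERV-vs-NCNR log-odds of the planted class
content <- lapply(sim$compartments, function(cp)
  compartment_content(sim$reference, cp, 3))
erv_counts <- colSums(randomized_spectrum(
  sites_in_compartment(flt, sim$compartments$erv), seed = 11))
ncnr_counts <- colSums(spectra)
lo <- log_odds_heatmap(
  rescale_rates(erv_counts, content$erv, content$ncnr),
  rescale_rates(ncnr_counts, content$ncnr, content$ncnr))
round(lo["ACG>G"], 3)   # planted log 2 = 0.693
#> ACG>G
#>  0.86
```

At this demonstration size (8,000 SNVs per lineage) the recovered
log-odds of 0.86 carries visible sampling noise around the planted
log 2 ≈ 0.693; at the package's standard study size (100,000 SNVs) the
estimate lands within ±0.15 of the truth and outside a 100-replicate
placement-bootstrap null (see the acceptance run below). For
significance testing of such an enrichment, `bootstrap_ervlike()` +
`bootstrap_enrichment_test()` build the null by re-placing the
compartment's segment lengths uniformly inside a background
compartment.

The methods vignette (`vignettes/compartment-spectra.Rmd`) walks
through the model, the filter cascade, every normalization formula and
the package's statistical conventions.

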