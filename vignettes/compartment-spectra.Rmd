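---
title: "Compartmentalized mutation-spectrum analysis: methods and conventions"
author: "apespectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized mutation-spectrum analysis: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `apespectra`, the
exact definition of every filter and normalization formula, the
conventions the package adopts where several reasonable choices exist,
and the design of the synthetic-panel generator used for validation.
Nothing here is required to *use* the package — see the README for
that — but everything a reviewer might ask "what exactly does this
compute?" about is answered here.

## 1. The scientific question

A germline mutation spectrum — the distribution of mutation counts
across sequence-context classes — can differ between species for two
distinct reasons:

- **trans-acting** differences: variants in replication or repair
  machinery that change mutation probabilities everywhere in the
  genome at once;
- **cis-acting** differences: properties of the local genomic
  environment (replication timing, chromatin, repeat content,
  base composition) that modulate rates region by region.

The analysis implemented here disentangles the two with a
two-way contrast on a multi-genus polymorphism panel:

1. **Between species, within a compartment**: differences that persist
   after conditioning on the genomic environment are candidates for
   trans-acting evolution.
2. **Between compartments, within a species**: differences that persist
   after correcting for sequence-content composition are candidates for
   cis effects of that compartment.

Segregating variants stand in for mutations. This is the standard
proxy when direct de novo mutation (DNM) calls are unavailable at
scale, and it is the reason the filtering stage below is aggressive:
every filter targets a way in which polymorphism misrepresents the
mutation process (mispolarization, selection and biased gene
conversion at high frequencies, genotyping artefacts, recurrent
mutation).

## 2. Mutation classes

All spectra are indexed by **strand-collapsed context classes**. For
width 3 there are 32 contexts — the central base is constrained to A or
C; a mutation whose ancestral central base is G or T is reverse
complemented first — and each context pairs with the 3 possible derived
central bases, giving 96 classes labelled like `"ACG>T"`. For width 7
the same construction gives 8,192 contexts and 24,576 classes; each
triplet class has exactly 256 7-mer children (4 choices at each of the
4 extra flanking positions). Class order is fixed and lexicographic
(`mutation_classes()`), so spectra from different code paths are always
positionally comparable.

`classify_mutation(context, derived)` is total on contexts without N:
the identity `classify_mutation(ctx, d) ==
classify_mutation(revcomp(ctx), complement(d))` holds for every input,
and every class is reached from exactly two (context, derived) pairs —
one per strand. Contexts containing N are not classified; sites whose
window overhangs a chromosome end get the missing positions N-padded
(only the overhanging positions — the known bases are kept) and are
then removed by the N filter.

Contexts are always taken from the **ancestral** state: the reference
base at the focal position is replaced by the inferred ancestral allele
before extracting the window, since the reference genome may carry the
derived allele.

## 3. Polarization and the filter cascade

`filter_sites()` consumes a genotype-call table, a sample panel
(individual → species → genus) and the reference sequence, and applies
the following stages **in order**; each removed site is labelled with
the first reason that applies, so the tally decomposes the losses
unambiguously.

1. **Biallelic, callable sites.** Sites with more than two observed
   alleles are dropped, as are sites whose missingness exceeds
   `max_missing` (default 0).
2. **Parsimony polarization.** A site is polarized when it is
   segregating in exactly one genus and every called genotype in all
   other genera is homozygous for one of its two alleles; that allele
   is ancestral. Sites segregating in two or more genera, monomorphic
   sites, fixed inter-genus differences, and sites where outgroup
   genera disagree are removed. This is deliberately conservative: it
   trades sites for polarization accuracy, because mispolarization
   converts classes into their reverse pairs and mimics spectrum
   differences.
3. **N context.** Sites whose ancestral context window (at the widest
   width that will be used downstream) contains any N.
4. **Recurrent derived alleles.** The same derived allele at the same
   position in more than one genus is evidence of recurrent mutation or
   alignment error; such sites are removed. This is the
   operationalization chosen for "recurrent": cross-genus recurrence is
   detectable without phasing, within-genus recurrence is not.
5. **Singletons** (default) or, in `doubleton` mode, everything except
   doubletons. Singletons are enriched for genotyping error; the
   doubleton mode gives a frequency class with minimal influence from
   selection.
6. **Derived allele frequency.** Sites with DAF ≥ 0.5 are removed,
   *inclusive* at the boundary: at DAF exactly 0.5 the parsimony
   assignment is least reliable and biased gene conversion strongest,
   so ties are excluded. DAF is computed over called haplotypes in the
   segregating genus.
7. **Excess heterozygosity.** The one-sided exact Levene–Haldane test
   (`hwe_excess_het_test()`): conditional on the minor-allele count
   `nA` among `2N` called haplotypes, the probability of the observed
   or more heterozygotes under random union of gametes. Sites with
   P < 0.05 are removed. Monomorphic sites return P = 1 by convention
   (no evidence of excess). The implementation works on log
   factorials; the test suite verifies it against full subset
   enumeration for every table with 2N ≤ 20 (agreement to < 1e-12).

Only the *excess* side is tested because excess heterozygosity is the
signature of paralogous collapse and cross-sample contamination;
heterozygote deficits (population structure, inbreeding) do not
systematically distort spectra.

## 4. Spectrum modes

Given the filtered sites, three counting modes are provided:

- `species_spectrum()`: each segregating site contributes **1** to its
  class for the species, regardless of frequency. This is the
  site-level spectrum used for species-to-species comparisons and as
  the reference distribution in the DNM test.
- `individual_spectrum()` (full mode): per individual, heterozygous
  sites contribute 1 and homozygous-derived sites contribute 2 —
  i.e. the count of derived alleles carried.
- `randomized_spectrum()`: each site is credited to exactly **one**
  uniformly chosen carrier haplotype; the chosen individual gets 1.
  Summed over individuals this reproduces the pooled site spectrum
  *exactly* (conservation is an identity, not an expectation), while
  breaking the frequency-weighting that makes full-mode individual
  spectra dominated by common variants. A carrier with `c` derived
  copies at a site with `k` derived copies total is chosen with
  probability `c/k`. The draw is vectorized: per site, cumulative
  copy counts define the inverse-CDF cells and one uniform deviate
  selects the carrier.

All three return matrices/vectors in canonical class order.
`spectrum_frequencies()` normalizes rows to 1; `subsample_individuals()`
supports equalizing sample sizes across species.

## 5. Content normalization

Compartments differ in sequence composition, so raw class counts
confound mutation rate with opportunity. Three corrections are
implemented; all take **context content** vectors from
`compartment_content()`, which counts every (strand-collapsed) context
window fully inside the compartment's intervals, excluding windows
containing N. Abutting intervals are merged before counting, so a
compartment's content depends only on its base set, not its interval
representation.

1. **Rescaled rates** (`rescale_rates`). For class *i* with context
   *c(i)* in compartment *C* and reference compartment *R*:
   `R_i = m_i × t_R(c(i)) / t_C(c(i))`, then `r_i = R_i / Σ R`. With
   equal content this reduces to raw frequencies (an identity the
   tests pin down). Zero content for a class with nonzero counts is an
   error, not an NA.
2. **Downscaled counts** (`downscale_counts`). For a two-compartment
   comparison at matched opportunity, per context the side with the
   larger content is scaled down by the content ratio (≤ 1); the other
   side is untouched. The operation is symmetric under swapping the
   arguments and never inflates counts.
3. **7-mer correction** (`sevenmer_correct`). The triplet spectrum a
   compartment *would* show if its extended (7-mer) composition matched
   a target: each 7-mer class count is reweighted by the target/source
   ratio of its 7-mer context content, then children are aggregated to
   their 3-mer parents. If the true mutation process depends only on
   the triplet, this provably recovers the target-composition triplet
   spectrum — the generator-based test confirms the residual mean
   log-odds on a strongly GC-skewed compartment is ≈ 0.003.

## 6. Comparative statistics

- **PCA** (`run_pca`): `stats::prcomp` on row-normalized spectra,
  centered, with zero-variance columns dropped and a deterministic sign
  convention (each loading vector's largest-magnitude entry is made
  positive) so results are bit-reproducible across platforms.
  `group_silhouette()` wraps `cluster::silhouette` on Euclidean
  distance in the leading PCs.
- **NMF** (`run_nmf`): multiplicative Frobenius updates (Lee–Seung)
  with multiple random restarts (the objective is verifiably
  non-increasing per iteration); signature rows are normalized to sum
  to 1. NMF is written in-package because no NMF implementation is
  available in the dependency stack; at the ranks used here
  (k ≤ 5, 96 columns) the simple updates converge in well under a
  second. `cluster_signatures()` does average-linkage hierarchical
  clustering on cosine distance for comparing signature sets across
  runs or compartments.
- **Distances** (`pairwise_distance_distributions`): all pairwise
  cosine distances between individual spectra, labelled
  within/between species.
- **Log-odds heatmaps** (`log_odds_heatmap`): `log(p_i / q_i)` per
  class between two rate vectors, natural log, with classes at zero in
  either vector masked as NA rather than ±Inf.
- **DNM assignment** (`dnm_fit_test`): for a DNM class-count vector
  *m* and per-species spectra with frequencies `p_{i,s}`, the
  log-likelihood of species *s* is `Σ_i m_i log p_{i,s}` (zero
  frequencies floored by a pseudo-count to keep likelihoods finite
  when the DNM set hits an unobserved class). The **fold range** is
  `exp(max_s LL − min_s LL)`; the set is significantly assigned when
  fold range ≥ 20, the likelihood-ratio convention corresponding to
  α = 0.05 (1/α = 20). With thousands of DNMs the likelihood gap is
  thousands of nats and `exp()` overflows double precision, so the
  decision is made on the **log scale** (`log_fold_range ≥ log 20`)
  and both `fold_range` (possibly `Inf`) and `log_fold_range` are
  returned.
- **Cis enrichment** (`bootstrap_ervlike` +
  `bootstrap_enrichment_test`): the null for "class *x* is enriched in
  compartment *T* relative to background *B*" re-places *T*'s exact
  multiset of segment lengths uniformly at random inside *B*
  (per chromosome, length-preserving, N-containing placements
  rejected, overlaps among placed segments allowed), recomputes the
  content-normalized log-odds of *x* for each of the (default 100)
  replicates, and reports whether the observed value falls outside the
  null range. With 100 replicates "outside the range" is an
  approximately P < 0.02 two-sided statement; the replicate count is a
  compute choice, not a tuned parameter.

## 7. The synthetic-panel generator

`simulate_panel()` exists so that every pipeline claim can be tested
against known truth. Its defaults are the package's **standard study
conditions** and were fixed before any validation was run:

- reference: 3 Mb over 2 chromosomes, i.i.d. base draws (uniform by
  default, per-compartment `base_freqs` optional, N runs optional);
- panel: 2 genera × 2 species × 9 diploids;
- trans model: each species draws mutation classes from its own convex
  mixture (dosage) of 3 shared signatures; mixtures differ by species;
- cis model: per-compartment multiplicative factors on chosen classes
  (standard: 2× on `ACG>G` in an ERV-like compartment), applied before
  renormalization;
- frequencies: derived-copy count `k` drawn ∝ 1/k over `1..2N_species`
  (scoped to the segregating species' haplotypes — the panel-wide SFS
  is not 1/k and is not claimed to be), placed as exactly `k` copies on
  random haplotypes; optional gBGC tilt multiplies strong→weak odds;
- contamination: a fraction of sites packed as excess heterozygotes
  (hets = 2·min(k, N) − k), and a fraction of "shared ancestral"
  variants segregating in both genera (which polarization must and
  does remove);
- truth record: every site's true class, compartment, lineage and
  copy count, plus each species' expected spectrum.

The generator is intentionally *not* a coalescent: there is no linkage,
no demography, and recombination is irrelevant because every analysis
here is site-wise. What it does reproduce faithfully are the features
the methods must be robust to — compositional differences between
compartments (the normalization target), shared and misleading
variation (the filtering target), and known planted effects (the
recovery target).

Numbers such as 100,000 SNVs per standard run, 40,000 per lineage for
the near-identical-spectra panel, and 100 bootstrap replicates were
chosen a priori from power calculations (documented in the project
notes) so that true effects are comfortably detectable and null
effects comfortably not — they are study-design choices, not values
fitted to outcomes.

## 8. Conventions and resolved ambiguities

Choices the package makes where a specification could be read several
ways, collected for reference:

- All logarithms are natural (base *e*); "log-odds of 2×" is ln 2.
- DAF filtering is inclusive at 0.5 (ties removed).
- The recurrent-mutation filter means *cross-genus* recurrence of the
  same derived allele.
- The 1/k frequency law is scoped to the segregating species'
  haplotype count, not the whole panel.
- HWE testing is one-sided (excess heterozygosity only), exact, with
  monomorphic sites assigned P = 1.
- Chromosome-edge contexts are partially N-padded (known flanking
  bases retained) and then excluded by the N filter.
- Fold-range significance is evaluated on the log scale to avoid
  overflow; the reported threshold remains 20.
- RNG: all stochastic functions take explicit `seed` arguments and use
  R's default Mersenne-Twister generator; every artifact written by
  `run_pipeline()` is byte-reproducible given the seed, and the output
  manifest records md5 checksums.

## 9. End-to-end pipeline

`run_pipeline()` chains all of the above: simulate (or read
FASTA/VCF/BED/panel inputs from disk) → filter → per-individual
randomized spectra in a chosen compartment → content-normalized rates →
PCA, NMF, distance distributions and log-odds heatmaps → write every
table as TSV (spectra carry a JSON sidecar with mode and seed), plus a
`manifest.json` of md5 checksums. The in-memory return value and the
on-disk artifacts are identical, and a rerun with the same seed
reproduces every byte.
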