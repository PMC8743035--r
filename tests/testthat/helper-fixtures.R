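# Fixtures are generated in code; expensive ones are memoized for the run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Three trans-acting signatures on largely disjoint class blocks, with a
# shared CpG C>G component so that every lineage carries ACG>G mutations.
true_signature_set <- function() {
  cls <- mutation_classes(3)
  cpg_g <- cls[grepl("CG>G$", cls)]
  base <- setNames(rep(0.002, 96), cls)
  base[cpg_g] <- base[cpg_g] + 0.018
  blockify <- function(block) {
    v <- base
    v[block] <- v[block] + (1 - sum(base)) / length(block)
    v / sum(v)
  }
  sigs <- rbind(
    cpg_transition = blockify(cls[grepl("CG>T$", cls)]),
    a_to_g = blockify(cls[grepl("^.A.>G$", cls)]),
    c_to_t_noncpg = blockify(cls[grepl("^.C.>T$", cls) &
                                   !grepl("CG>T$", cls)]))
  colnames(sigs) <- cls
  sigs
}

late_cis_multipliers <- function() {
  cls <- mutation_classes(3)
  c(setNames(rep(1.6, 16), cls[grepl("^.C.>A$", cls)]),
    setNames(rep(1.4, 16), cls[grepl("^.A.>T$", cls)]))
}

# Standard study conditions: 2 genera x 2 species, 9 diploids per species,
# 1e5 lineage-specific SNVs over a 3 Mb reference.
standard_config <- function(seed = 20210513) {
  simulation_config(
    seed = seed,
    sequence_length = 3e6,
    n_chromosomes = 2,
    genera = list(Alpha = list(A1 = 9, A2 = 9),
                  Beta = list(B1 = 9, B2 = 9)),
    lineage_dosages = list(A1 = c(0.75, 0.15, 0.10),
                           A2 = c(0.55, 0.25, 0.20),
                           B1 = c(0.15, 0.70, 0.15),
                           B2 = c(0.10, 0.20, 0.70)),
    true_signatures = true_signature_set(),
    compartments = list(
      list(name = "ncnr", fraction = 0.40),
      list(name = "early", fraction = 0.15),
      list(name = "late", fraction = 0.15, cis = late_cis_multipliers()),
      list(name = "hetero", fraction = 0.20),
      list(name = "erv", fraction = 0.10, cis = c("ACG>G" = 2))),
    n_snvs_per_lineage = 25000,
    shared_ancestral_fraction = 0.05,
    excess_het_fraction = 0.02)
}

standard_sim <- function() memo("standard_sim", {
  simulate_panel(standard_config())
})

standard_filtered <- function() memo("standard_filtered", {
  sim <- standard_sim()
  filter_sites(sim$calls, sim$panel, sim$reference)
})

standard_contents <- function() memo("standard_contents", {
  sim <- standard_sim()
  lapply(sim$compartments, function(cp)
    compartment_content(sim$reference, cp, 3))
})

# per-individual randomized count spectra in the reference compartment
standard_ncnr_randomized <- function() memo("standard_ncnr_randomized", {
  sim <- standard_sim()
  sub <- sites_in_compartment(standard_filtered(),
                              sim$compartments$ncnr)
  randomized_spectrum(sub, seed = 11)
})

# small 2-genus / 2-species panel for fast unit tests
small_sim <- function() memo("small_sim", {
  simulate_panel(simulation_config(
    seed = 7, sequence_length = 4e5, n_chromosomes = 1,
    genera = list(Alpha = list(A1 = 5), Beta = list(B1 = 5)),
    lineage_dosages = list(A1 = c(0.8, 0.1, 0.1), B1 = c(0.1, 0.1, 0.8)),
    true_signatures = true_signature_set(),
    compartments = list(list(name = "ncnr", fraction = 0.6),
                        list(name = "other", fraction = 0.4)),
    n_snvs_per_lineage = 3000,
    shared_ancestral_fraction = 0.05,
    excess_het_fraction = 0.05))
})

small_filtered <- function() memo("small_filtered", {
  sim <- small_sim()
  filter_sites(sim$calls, sim$panel, sim$reference)
})

# two equally sized compartments whose base compositions differ; the
# mutation process is 3-mer-only, so any 7-mer structure in the observed
# spectra is compositional and must vanish under the 7-mer correction
gcskew_sim <- function() memo("gcskew_sim", {
  simulate_panel(simulation_config(
    seed = 907, sequence_length = 3e6, n_chromosomes = 2,
    genera = list(Alpha = list(A1 = 9), Beta = list(B1 = 9)),
    lineage_dosages = list(A1 = c(0.6, 0.2, 0.2), B1 = c(0.2, 0.2, 0.6)),
    true_signatures = true_signature_set(),
    compartments = list(
      list(name = "ncnr", fraction = 0.5),
      list(name = "gcrich", fraction = 0.5,
           base_freqs = c(0.20, 0.30, 0.30, 0.20))),
    n_snvs_per_lineage = 50000))
})

# three lineages drawing from one common signature mixture: their
# spectra differ only by sampling noise, the paper's "underpowered DNM
# assignment" regime
dnm_mini_sim <- function() memo("dnm_mini_sim", {
  common <- c(0.4, 0.3, 0.3)
  simulate_panel(simulation_config(
    seed = 4177, sequence_length = 2e6, n_chromosomes = 2,
    genera = list(Alpha = list(A1 = 6, A2 = 6), Beta = list(B1 = 6)),
    lineage_dosages = list(A1 = common, A2 = common, B1 = common),
    true_signatures = true_signature_set(),
    compartments = list(list(name = "ncnr", fraction = 1)),
    n_snvs_per_lineage = 40000))
})

# class counts over ALL lineage-specific simulated SNVs (no filtering),
# per compartment, at the requested context order
truth_compartment_counts <- function(sim, comp_name, order = 3) {
  st <- sim$calls$sites
  truth <- sim$truth$snvs
  own <- truth$lineage != "shared" & truth$compartment == comp_name
  pseudo <- data.frame(chrom = truth$chrom[own], pos = truth$pos[own],
                       verdict = "kept", stringsAsFactors = FALSE)
  m <- match(paste(pseudo$chrom, pseudo$pos),
             paste(st$chrom, st$pos))
  pseudo$ancestral <- st$ref[m]
  derived <- st$alt[m]
  ctx <- apespectra:::context_at(sim$reference, pseudo, order)
  ok <- !grepl("N", ctx, fixed = TRUE)
  apespectra:::count_classes(classify_mutation(ctx[ok], derived[ok]),
                             order)
}

# hand-built call set: one row per scenario, genotypes given per sample
manual_calls <- function(geno, ref = "A", alt = "G") {
  n <- nrow(geno)
  list(sites = data.frame(chrom = rep("chr1", n), pos = seq_len(n) * 10L,
                          ref = rep(ref, length.out = n),
                          alt = rep(alt, length.out = n),
                          multiallelic = FALSE, stringsAsFactors = FALSE),
       geno = geno, samples = colnames(geno))
}

manual_panel <- function(samples, genus) {
  data.frame(sample = samples, subspecies = genus, species = genus,
             genus = genus, stringsAsFactors = FALSE)
}

# Brute-force Levene-Haldane oracle: enumerate every way of placing nA
# copies of allele A onto the 2N haplotype slots (slots (1,2), (3,4), ...
# pair into individuals) and count heterozygotes per placement. combn
# emits sorted slot subsets, so equal pair ids are always adjacent.
hwe_het_counts <- function(N, nA) {
  if (nA == 0L || nA == 2L * N) return(0L)
  sets <- utils::combn(2L * N, nA)
  pair <- (sets + 1L) %/% 2L
  homs <- if (nA < 2L) 0L else
    colSums(pair[-1L, , drop = FALSE] == pair[-nA, , drop = FALSE])
  as.integer(nA - 2L * homs)
}

hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  hets <- hwe_het_counts(N, 2L * n_AA + n_Aa)
  mean(hets >= n_Aa)
}

# per-base membership oracle for interval algebra on [1, L]
interval_membership <- function(gr, L) {
  v <- logical(L)
  for (i in seq_along(gr))
    v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  v
}

random_compartment <- function(name, L, n_range = 3:8) {
  n <- sample(n_range, 1)
  s <- sort(sample(0:(L - 50L), n))
  e <- pmin(s + sample(10:120, n, replace = TRUE), L)
  compartment(name, rep("chr1", n), s, e)
}
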