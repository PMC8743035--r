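test_that("the configuration validator rejects inconsistent inputs", {
  sigs <- true_signature_set()
  base <- list(seed = 1, sequence_length = 1e5, n_chromosomes = 1,
               genera = list(G1 = list(s1 = 3), G2 = list(s2 = 3)),
               lineage_dosages = list(s1 = c(1, 0, 0), s2 = c(0, 1, 0)),
               true_signatures = sigs,
               compartments = list(list(name = "a", fraction = 0.5)),
               n_snvs_per_lineage = 500)
  expect_s3_class(do.call(simulation_config, base), "simulation_config")
  bad <- function(...) {
    dots <- list(...)
    args <- base
    for (nm in names(dots)) args[[nm]] <- dots[[nm]]
    expect_error(do.call(simulation_config, args))
  }
  bad(sequence_length = 5000)
  bad(true_signatures = sigs * 2)            # rows no longer sum to 1
  bad(true_signatures = sigs[, c(2:96, 1)])  # class order broken
  bad(lineage_dosages = list(s1 = c(1, 0, 0)))
  bad(lineage_dosages = list(s1 = c(1, 0), s2 = c(0, 1)))
  bad(compartments = list(list(name = "a", fraction = 0.7),
                          list(name = "b", fraction = 0.7)))
  bad(compartments = list(list(name = "a", fraction = 0.5),
                          list(name = "a", fraction = 0.3)))
  bad(sfs_model = "constant")
  # remainder of the genome becomes an explicit background compartment
  cfg <- do.call(simulation_config, base)
  expect_setequal(vapply(cfg$compartments, `[[`, character(1), "name"),
                  c("a", "background"))
})

test_that("the generator is deterministic in its seed and sensitive to it", {
  cfg <- simulation_config(
    seed = 31, sequence_length = 2e5, n_chromosomes = 1,
    genera = list(Alpha = list(A1 = 4), Beta = list(B1 = 4)),
    lineage_dosages = list(A1 = c(0.8, 0.1, 0.1), B1 = c(0.1, 0.1, 0.8)),
    true_signatures = true_signature_set(),
    compartments = list(list(name = "ncnr", fraction = 0.5)),
    n_snvs_per_lineage = 800, shared_ancestral_fraction = 0.05)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$calls$sites, b$calls$sites)
  expect_identical(a$calls$geno, b$calls$geno)
  cfg2 <- cfg
  cfg2$seed <- 32
  c2 <- simulate_panel(cfg2)
  expect_false(identical(a$calls$sites$pos, c2$calls$sites$pos))
})

test_that("the panel enumerates the taxonomy with stable sample ids", {
  sim <- standard_sim()
  p <- sim$panel
  expect_equal(nrow(p), 36)
  expect_setequal(unique(p$genus), c("Alpha", "Beta"))
  expect_equal(as.vector(table(p$species)[c("A1", "A2", "B1", "B2")]),
               rep(9L, 4))
  expect_identical(p$sample[p$species == "A1"][1], "A1_A1_01")
  expect_false(anyDuplicated(p$sample) > 0)
})

test_that("simulated site counts and positions honour the configuration", {
  sim <- standard_sim()
  st <- sim$calls$sites
  # 4 lineages x 25k + 5% shared
  expect_equal(nrow(st), 4 * 25000 + round(0.05 * 25000 * 4))
  expect_false(anyDuplicated(paste(st$chrom, st$pos)) > 0)
  expect_true(all(st$ref != st$alt))
  expect_true(all(st$ref %in% c("A", "C", "G", "T")))
  expect_true(all(st$alt %in% c("A", "C", "G", "T")))
  # the REF column matches the reference sequence at every site
  for (chr in unique(st$chrom)) {
    sel <- st$chrom == chr
    seqc <- as.character(sim$reference[[chr]])
    expect_identical(substring(seqc, st$pos[sel], st$pos[sel]),
                     st$ref[sel])
  }
  # compartments tile the genome disjointly
  all_comp <- do.call(c, unname(lapply(sim$compartments, function(g) {
    GenomicRanges::mcols(g) <- NULL
    g
  })))
  expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(all_comp))),
               compartment_length(all_comp))
})

test_that("ground truth classes agree with reference-orientation classification", {
  sim <- small_sim()
  truth <- sim$truth$snvs
  own <- truth$lineage != "shared"
  st <- sim$calls$sites
  key_truth <- paste(truth$chrom, truth$pos)
  key_calls <- paste(st$chrom, st$pos)
  m <- match(key_truth[own], key_calls)
  ctx <- apespectra:::context_at(
    sim$reference,
    data.frame(chrom = st$chrom[m], pos = st$pos[m], verdict = "kept",
               ancestral = st$ref[m], stringsAsFactors = FALSE),
    3L)
  expect_identical(classify_mutation(ctx, st$alt[m]), truth$class[own])
})

test_that("derived counts follow the 1/k site frequency spectrum", {
  sim <- standard_sim()
  own <- sim$truth$snvs[sim$truth$snvs$lineage == "A1", ]
  tab <- table(factor(own$k, levels = 1:17))
  expected <- (1 / 1:17) / sum(1 / 1:17) * nrow(own)
  chi <- sum((as.numeric(tab) - expected)^2 / expected)
  # 16 df; 99.9% quantile ~ 39. Loose bound, catches gross SFS distortion
  expect_lt(chi, qchisq(0.999, df = 16))
  # never monomorphic within the species
  expect_true(all(own$k >= 1 & own$k <= 17))
})

test_that("genotype assignment places exactly k derived haplotypes", {
  sim <- small_sim()
  truth <- sim$truth$snvs
  own <- which(truth$lineage != "shared")
  st <- sim$calls$sites
  m <- match(paste(truth$chrom, truth$pos)[own], paste(st$chrom, st$pos))
  for (sp in c("A1", "B1")) {
    rows <- m[truth$lineage[own] == sp]
    cols <- sim$panel$sample[sim$panel$species == sp]
    other <- setdiff(sim$panel$sample, cols)
    g <- sim$calls$geno[rows, cols, drop = FALSE]
    expect_equal(unname(rowSums(g)),
                 truth$k[own][truth$lineage[own] == sp])
    # lineage-specific: no derived copies outside the focal species
    expect_true(all(sim$calls$geno[rows, other] == 0L))
  }
})

test_that("excess-het packing yields the maximum heterozygote count", {
  set.seed(1)
  # heterozygotes = 2*min(k,n) - k for k <= 2n, the packing maximum
  for (k in 1:10) {
    copies <- apespectra:::pack_excess_het(k, 5)
    expect_equal(sum(copies == 1), 2 * min(k, 5) - k)
    expect_equal(sum(copies), k)
  }
})

test_that("per-lineage class draws track the dosage-mixture expectation", {
  sim <- standard_sim()
  truth <- sim$truth$snvs
  for (sp in c("A1", "B1")) {
    own <- truth[truth$lineage == sp, ]
    obs <- table(factor(own$class, levels = mutation_classes(3)))
    p <- sim$truth$expected_spectra[[sp]]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    obs_f <- as.numeric(obs) / sum(obs)
    # total variation distance small at n = 25k
    expect_lt(sum(abs(obs_f - p)) / 2, 0.03)
  }
  # dosage differences show up where they should: A1 is CpG-transition
  # heavy, B1 is A>G heavy
  a1 <- sim$truth$expected_spectra$A1
  b1 <- sim$truth$expected_spectra$B1
  cpg <- grepl("CG>T$", names(a1))
  a2g <- grepl("^.A.>G$", names(a1))
  expect_gt(sum(a1[cpg]), sum(b1[cpg]))
  expect_gt(sum(b1[a2g]), sum(a1[a2g]))
})

test_that("cis multipliers enrich the targeted class in the right compartment", {
  sim <- standard_sim()
  truth <- sim$truth$snvs[sim$truth$snvs$lineage != "shared", ]
  frac <- function(comp) {
    sub <- truth[truth$compartment == comp, ]
    mean(sub$class == "ACG>G")
  }
  # erv has a 2x multiplier on ACG>G; ncnr does not
  expect_gt(frac("erv"), 1.5 * frac("ncnr"))
})

test_that("a simulation written to disk reloads into the same analysis inputs", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  apespectra:::write_simulation(sim, dir)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(ref) <- sub("\\s.*$", "", names(ref))
  expect_identical(as.character(ref), as.character(sim$reference))
  calls <- read_vcf_calls(file.path(dir, "panel.vcf"))
  expect_identical(unname(calls$geno), unname(sim$calls$geno))
  panel <- read_panel(file.path(dir, "panel.tsv"))
  expect_identical(panel$sample, sim$panel$sample)
  ncnr <- read_bed(file.path(dir, "ncnr.bed"))
  expect_identical(GenomicRanges::start(ncnr),
                   GenomicRanges::start(sim$compartments$ncnr))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, sim$truth$seed)
  expect_equal(truth$snvs$pos, sim$truth$snvs$pos)
})
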