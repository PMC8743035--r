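# Manual genotype scenarios: two genera (X: 3 diploids, Y: 3 diploids),
# REF = allele A, ALT = allele B. Each row is one polarization scenario.
two_genus_setup <- function() {
  samples <- c(paste0("X", 1:3), paste0("Y", 1:3))
  panel <- rbind(manual_panel(paste0("X", 1:3), "X"),
                 manual_panel(paste0("Y", 1:3), "Y"))
  list(samples = samples, panel = panel)
}

test_that("parsimony keeps one-genus-segregating sites, ancestral from the other genus", {
  s <- two_genus_setup()
  geno <- rbind(
    seg_in_X_anc_ref   = c(0L, 1L, 0L, 0L, 0L, 0L),
    seg_in_X_anc_alt   = c(2L, 1L, 2L, 2L, 2L, 2L),
    seg_in_both        = c(0L, 1L, 0L, 0L, 1L, 0L),
    monomorphic_ref    = c(0L, 0L, 0L, 0L, 0L, 0L),
    fixed_diff         = c(2L, 2L, 2L, 0L, 0L, 0L))
  colnames(geno) <- s$samples
  pol <- polarize_by_parsimony(manual_calls(geno), s$panel)
  st <- pol$sites
  expect_identical(st$verdict, c("kept", "kept", "excluded", "excluded",
                                 "excluded"))
  expect_identical(st$reason[3:5], c("multi-genus-segregating",
                                     "monomorphic",
                                     "multiple-fixed-alleles"))
  # site 1: Y fixed REF -> ancestral REF(A), derived ALT(G), k = 1
  expect_identical(st$ancestral[1], "A")
  expect_identical(st$derived[1], "G")
  expect_identical(st$k[1], 1L)
  expect_identical(st$n_hap[1], 6L)
  # site 2: Y fixed ALT -> ancestral ALT(G), derived REF(A), k = 6 - 5 = 1
  expect_identical(st$ancestral[2], "G")
  expect_identical(st$derived[2], "A")
  expect_identical(st$k[2], 1L)
  # derived copies are flipped into derived orientation for site 2
  expect_identical(unname(pol$derived_copies[2, ]), c(0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("multi-allelic and missing sites are excluded before polarization", {
  s <- two_genus_setup()
  geno <- rbind(a = c(0L, 1L, 0L, 0L, 0L, 0L),
                b = c(0L, 1L, NA, 0L, 0L, 0L),
                c = c(0L, 1L, 1L, NA, NA, NA))
  colnames(geno) <- s$samples
  calls <- manual_calls(geno)
  calls$sites$multiallelic[1] <- TRUE
  pol <- polarize_by_parsimony(calls, s$panel, max_missing = 0)
  expect_identical(pol$sites$reason,
                   c(">2-alleles-in-genus", "missingness", "missingness"))
  # a lenient haplotype-missingness threshold readmits the single-NA site
  pol2 <- polarize_by_parsimony(calls, s$panel, max_missing = 0.2)
  expect_identical(pol2$sites$verdict[2], "kept")
  expect_identical(pol2$sites$n_hap[2], 4L)  # within-genus haplotypes only
  # a whole genus unobserved can never be rescued by the threshold
  expect_identical(pol2$sites$reason[3], "missingness")
})

test_that("with three genera, discordant fixed outgroups block polarization", {
  samples <- c("X1", "X2", "Y1", "Z1")
  panel <- rbind(manual_panel(c("X1", "X2"), "X"),
                 manual_panel("Y1", "Y"), manual_panel("Z1", "Z"))
  geno <- rbind(discordant = c(0L, 1L, 0L, 2L),
                concordant = c(0L, 1L, 0L, 0L))
  colnames(geno) <- samples
  pol <- polarize_by_parsimony(manual_calls(geno), panel)
  expect_identical(pol$sites$reason[1], "multiple-fixed-alleles")
  expect_identical(pol$sites$verdict[2], "kept")
})

test_that("the filter cascade applies its stages in the documented order", {
  # k=1 (singleton) and DAF>=0.5 both apply to row 2 -> singleton wins;
  # rows ordered: N-context, singleton, DAF, HWE-excess, kept
  sites <- data.frame(
    chrom = "chr1", pos = 1:5, verdict = "kept", reason = NA_character_,
    ancestral = "A", derived = "G", genus = "X",
    k = c(3L, 1L, 5L, 4L, 3L),
    n_hap = c(10L, 2L, 10L, 10L, 10L),
    n_het = c(1L, 1L, 5L, 4L, 3L),
    n_hom_der = c(1L, 0L, 0L, 0L, 0L),
    derived_elsewhere = FALSE,
    context3 = c("ANA", "ACA", "ACA", "ACA", "ACA"),
    context7 = "AAAAAAA", stringsAsFactors = FALSE)
  out <- apply_site_filters(sites)
  expect_identical(out$reason[1:3], c("N-context", "singleton", "DAF>=0.5"))
  # row 4: 4 hets / 5 diploids at k=4 has exact P(>=4 hets) < 0.05?
  p4 <- hwe_excess_het_test(1L, 4L, 0L)
  expect_identical(out$verdict[4], if (p4 < 0.05) "excluded" else "kept")
  expect_identical(out$verdict[5], "kept")
  expect_equal(out$hwe_p[5], hwe_excess_het_test(2L, 3L, 0L))
})

test_that("the DAF cut is inclusive at exactly one half", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:2, verdict = "kept", reason = NA_character_,
    ancestral = "A", derived = "G", genus = "X",
    k = c(5L, 4L), n_hap = 10L, n_het = c(1L, 2L), n_hom_der = c(2L, 1L),
    derived_elsewhere = FALSE, context3 = "ACA", context7 = "AAACAAA",
    stringsAsFactors = FALSE)
  out <- apply_site_filters(sites)
  expect_identical(out$reason[1], "DAF>=0.5")
  expect_identical(out$verdict[2], "kept")
})

test_that("doubleton mode keeps exactly the k = 2 sites", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:3, verdict = "kept", reason = NA_character_,
    ancestral = "A", derived = "G", genus = "X",
    k = c(1L, 2L, 3L), n_hap = 12L, n_het = c(1L, 2L, 3L), n_hom_der = 0L,
    derived_elsewhere = FALSE, context3 = "ACA", context7 = "AAACAAA",
    stringsAsFactors = FALSE)
  out <- apply_site_filters(sites, doubletons_only = TRUE)
  expect_identical(out$verdict, c("excluded", "kept", "excluded"))
})

test_that("the recurrent filter removes derived alleles seen in another genus", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:2, verdict = "kept", reason = NA_character_,
    ancestral = "A", derived = "G", genus = "X",
    k = 3L, n_hap = 12L, n_het = 3L, n_hom_der = 0L,
    derived_elsewhere = c(TRUE, FALSE), context3 = "ACA",
    context7 = "AAACAAA", stringsAsFactors = FALSE)
  out <- apply_site_filters(sites)
  expect_identical(out$reason[1], "recurrent")
  expect_identical(out$verdict[2], "kept")
})

test_that("excess-het p-values match spot-checked Levene-Haldane values", {
  # N=2, nA=2: tables (AA,aa) and (Aa,Aa); P(h=2) = 2/3 under the
  # conditional null, so observing 2 hets gives p = 2/3 and 0 hets p = 1
  expect_equal(hwe_excess_het_test(0L, 2L, 0L), 2 / 3)
  expect_equal(hwe_excess_het_test(1L, 0L, 1L), 1)
  # monomorphic convention
  expect_equal(hwe_excess_het_test(5L, 0L, 0L), 1)
  expect_equal(hwe_excess_het_test(0L, 0L, 5L), 1)
  # symmetric in allele labels
  expect_equal(hwe_excess_het_test(3L, 4L, 1L), hwe_excess_het_test(1L, 4L, 3L))
  expect_true(all(hwe_excess_het_test(0:5, 5L, 5:0) >= 0))
  expect_error(hwe_excess_het_test(-1L, 1L, 1L), "negative")
})

test_that("chromosome-edge sites get N-padded contexts and are filtered", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  s <- two_genus_setup()
  geno <- rbind(edge = c(0L, 1L, 0L, 0L, 0L, 0L),
                mid = c(0L, 1L, 1L, 0L, 0L, 0L))
  colnames(geno) <- s$samples
  calls <- manual_calls(geno)
  calls$sites$pos <- c(1L, 5L)
  calls$sites$ref <- c("A", "A")
  calls$sites$alt <- c("G", "G")
  pol <- add_contexts(polarize_by_parsimony(calls, s$panel), ref)
  expect_identical(pol$sites$context3, c("NAC", "TAC"))
  expect_identical(pol$sites$context7, c("NNNACGT", "CGTACGT"))
  out <- apply_site_filters(pol$sites)
  expect_identical(out$reason[1], "N-context")
})

test_that("the ancestral allele replaces the reference base in the context", {
  # reference carries the derived allele at the site (ancestral is ALT)
  ref <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAAAAA"))
  s <- two_genus_setup()
  geno <- rbind(x = c(2L, 1L, 2L, 2L, 2L, 2L))
  colnames(geno) <- s$samples
  calls <- manual_calls(geno, ref = "A", alt = "G")
  calls$sites$pos <- 5L
  pol <- add_contexts(polarize_by_parsimony(calls, s$panel), ref)
  expect_identical(pol$sites$ancestral, "G")
  expect_identical(pol$sites$context3, "AGA")
})

test_that("frequency stratification partitions kept sites exactly", {
  flt <- small_filtered()
  bins <- frequency_stratified_subset(flt$kept, c(0, 0.1, 0.25, 0.5))
  expect_equal(sum(vapply(bins, nrow, integer(1))), nrow(flt$kept))
  daf <- flt$kept$k / flt$kept$n_hap
  expect_true(all(daf[order(daf)] ==
                    sort(unlist(lapply(bins, function(b) b$k / b$n_hap)))))
  preds <- frequency_stratified_subset(
    flt$kept, list(doubleton = function(k, n) k == 2,
                   rest = function(k, n) TRUE))
  expect_true(all(preds$doubleton$k == 2L))
  expect_equal(nrow(preds$doubleton) + nrow(preds$rest), nrow(flt$kept))
  expect_error(frequency_stratified_subset(flt$kept, c(0, 0.01)),
               "outside")
})

test_that("VCF round trip preserves the simulated call set byte for byte", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_vcf(sim$calls, sim$reference, file.path(dir, "p.vcf"))
  back <- read_vcf_calls(file.path(dir, "p.vcf"))
  expect_identical(back$samples, sim$calls$samples)
  expect_equal(back$sites$pos, sim$calls$sites$pos)
  expect_identical(back$sites$ref, sim$calls$sites$ref)
  expect_identical(back$sites$alt, sim$calls$sites$alt)
  expect_identical(unname(back$geno), unname(sim$calls$geno))
})
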