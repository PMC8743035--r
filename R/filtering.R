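#' Read a sample panel table
#'
#' Tab-separated table with columns `sample`, `subspecies`, `species`,
#' `genus` mapping every sample in the variant panel to its taxonomy.
#'
#' @param path file path.
#' @return data frame with the four panel columns.
#' @export
read_panel <- function(path) {
  panel <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  need <- c("sample", "subspecies", "species", "genus")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(panel$sample))
    stop("duplicated sample ids in panel")
  if (any(!nzchar(panel$genus)))
    stop("every sample needs a genus")
  invisible(panel)
}

#' Read genotype calls from a VCF
#'
#' Reads a VCF v4.2 with GT fields into the call-set structure used by the
#' polarization and filtering functions: a site table plus a matrix of
#' alternate-allele counts per sample (`NA` for missing genotypes). Sites
#' with more than one ALT allele are retained in the table but flagged, so
#' the filter cascade can dispose of them as multi-allelic.
#'
#' @param path VCF file path.
#' @return list with `sites` (data frame: chrom, pos, ref, alt,
#'   multiallelic), `geno` (sites x samples integer matrix of ALT counts)
#'   and `samples`.
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  # allele dosage of the first ALT; "." or NA -> missing
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | a2 == "."
  geno <- (a1 == "1") + (a2 == "1")
  geno[miss] <- NA_integer_
  mode(geno) <- "integer"
  alt <- fix[, "ALT"]
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = alt,
                      multiallelic = grepl(",", alt, fixed = TRUE),
                      stringsAsFactors = FALSE)
  rownames(geno) <- NULL
  list(sites = sites, geno = geno, samples = colnames(gt))
}

#' Polarize biallelic sites by cross-genus parsimony
#'
#' A biallelic site segregating within exactly one genus is polarized to
#' the allele fixed in all other genera, which becomes the ancestral
#' allele. Sites segregating in multiple genera, sites whose non-focal
#' genera are fixed for different alleles, and sites with more than two
#' alleles are excluded. Sites with missing genotypes beyond the
#' configured haplotype-missingness threshold are excluded as well.
#'
#' @param calls call set from [read_vcf_calls()] or [simulate_panel()].
#' @param panel panel data frame (sample, subspecies, species, genus).
#' @param max_missing maximum tolerated fraction of missing haplotypes per
#'   site (0 for ape-style panels; 0.2 mirrors the human/mouse-style rule).
#' @return list with `sites`, a data frame holding one row per input site
#'   (chrom, pos, verdict, reason, and for kept sites ancestral, derived,
#'   genus, k, n_hap, n_het, n_hom_der, derived_elsewhere), and
#'   `derived_copies`, a sites x samples matrix of derived-allele dosages
#'   for kept sites (NA rows elsewhere).
#' @export
polarize_by_parsimony <- function(calls, panel, max_missing = 0) {
  validate_panel(panel)
  if (!all(panel$sample %in% calls$samples))
    stop("panel samples missing from call set: ",
         paste(setdiff(panel$sample, calls$samples), collapse = ", "))
  geno <- calls$geno[, panel$sample, drop = FALSE]
  genera <- sort(unique(panel$genus))
  if (length(genera) < 2)
    stop("parsimony polarization requires at least two genera")
  ns <- nrow(calls$sites)
  ng <- length(genera)

  cntB <- matrix(0L, ns, ng, dimnames = list(NULL, genera))
  nonmiss <- matrix(0L, ns, ng, dimnames = list(NULL, genera))
  n_samp <- integer(ng)
  for (j in seq_along(genera)) {
    idx <- which(panel$genus == genera[j])
    n_samp[j] <- length(idx)
    sub <- geno[, idx, drop = FALSE]
    cntB[, j] <- rowSums(sub, na.rm = TRUE)
    nonmiss[, j] <- rowSums(!is.na(sub))
  }
  presentB <- cntB > 0L
  presentA <- cntB < 2L * nonmiss
  seg <- presentA & presentB
  seg_count <- rowSums(seg)
  observed <- nonmiss > 0L
  fixedA <- observed & !seg & presentA
  fixedB <- observed & !seg & presentB
  miss_frac <- 1 - rowSums(nonmiss) / sum(n_samp)

  verdict <- rep("kept", ns)
  reason <- rep(NA_character_, ns)
  excl <- function(cond, why) {
    hit <- cond & verdict == "kept"
    verdict[hit] <<- "excluded"
    reason[hit] <<- why
  }
  excl(calls$sites$multiallelic, ">2-alleles-in-genus")
  excl(rowSums(observed) < ng | miss_frac > max_missing, "missingness")
  excl(seg_count >= 2, "multi-genus-segregating")
  excl(seg_count == 0 & rowSums(fixedA) > 0 & rowSums(fixedB) > 0,
       "multiple-fixed-alleles")
  excl(seg_count == 0, "monomorphic")
  # one segregating genus: the others must be fixed for one shared allele
  focal <- max.col(seg, ties.method = "first")
  oth_fixedA <- rowSums(fixedA)   # focal genus is segregating, not fixed
  oth_fixedB <- rowSums(fixedB)
  excl(oth_fixedA > 0 & oth_fixedB > 0, "multiple-fixed-alleles")

  kept <- verdict == "kept"
  anc_is_B <- kept & oth_fixedB > 0
  focal_genus <- ifelse(kept, genera[focal], NA_character_)
  kB <- as.integer(cntB[cbind(seq_len(ns), focal)])
  n_hap <- 2L * as.integer(nonmiss[cbind(seq_len(ns), focal)])
  k <- ifelse(anc_is_B, n_hap - kB, kB)

  alleleA <- calls$sites$ref
  alleleB <- calls$sites$alt
  ancestral <- ifelse(anc_is_B, alleleB, alleleA)
  derived <- ifelse(anc_is_B, alleleA, alleleB)
  ancestral[!kept] <- NA_character_
  derived[!kept] <- NA_character_
  k[!kept] <- NA_integer_
  n_hap[!kept] <- NA_integer_

  derived_copies <- geno
  if (any(anc_is_B)) {
    flip <- which(anc_is_B)
    derived_copies[flip, ] <- 2L - geno[flip, , drop = FALSE]
  }
  derived_copies[!kept, ] <- NA_integer_

  # genotype table within the focal genus, derived-allele orientation
  n_het <- n_hom_der <- rep(NA_integer_, ns)
  for (j in seq_along(genera)) {
    rows <- which(kept & focal == j)
    if (!length(rows)) next
    idx <- which(panel$genus == genera[j])
    sub <- derived_copies[rows, idx, drop = FALSE]
    n_het[rows] <- as.integer(rowSums(sub == 1L, na.rm = TRUE))
    n_hom_der[rows] <- as.integer(rowSums(sub == 2L, na.rm = TRUE))
  }
  derived_elsewhere <- rep(FALSE, ns)
  for (j in seq_along(genera)) {
    rows <- kept & focal != j & observed[, j]
    der_b <- !anc_is_B   # derived allele is B unless ancestral is B
    derived_elsewhere[rows] <- derived_elsewhere[rows] |
      ifelse(der_b[rows], presentB[rows, j], presentA[rows, j])
  }

  sites <- data.frame(chrom = calls$sites$chrom, pos = calls$sites$pos,
                      verdict = verdict, reason = reason,
                      ancestral = ancestral, derived = derived,
                      genus = focal_genus, k = k, n_hap = n_hap,
                      n_het = n_het, n_hom_der = n_hom_der,
                      derived_elsewhere = derived_elsewhere,
                      stringsAsFactors = FALSE)
  list(sites = sites, derived_copies = derived_copies,
       samples = panel$sample)
}

#' Exact one-sided test for heterozygote excess
#'
#' Conditional on the observed allele counts, computes the exact
#' probability of observing at least as many heterozygotes as seen, under
#' the Hardy-Weinberg null in which the alleles are randomly paired into
#' diploid genotypes (the Levene-Haldane distribution). Monomorphic sites
#' return 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycle).
#' @return vector of one-sided p-values in `[0, 1]`.
#' @export
hwe_excess_het_test <- function(n_AA, n_Aa, n_aa) {
  n <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), n)
  n_Aa <- rep_len(as.integer(n_Aa), n)
  n_aa <- rep_len(as.integer(n_aa), n)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE))
    stop("negative genotype counts")
  vapply(seq_len(n), function(i) {
    hwe_excess_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_excess_one <- function(n_AA, n_Aa, n_aa) {
  if (anyNA(c(n_AA, n_Aa, n_aa))) return(NA_real_)
  N <- n_AA + n_Aa + n_aa
  if (N < 1) stop("empty genotype table")
  nA <- 2L * n_AA + n_Aa
  if (nA == 0L || nA == 2L * N) return(1)
  hs <- seq.int(nA %% 2L, min(nA, 2L * N - nA), by = 2L)
  logp <- lfactorial(N) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((2L * N - nA - hs) / 2) + hs * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hs >= n_Aa])
}

#' Apply the per-site filter cascade to polarized sites
#'
#' Applies, in order: N-context, recurrent mutation, singleton (or
#' doubleton-only), derived allele frequency >= 0.5, and Hardy-Weinberg
#' excess-heterozygosity filters. Each excluded site gets exactly one
#' reason, the first filter it fails. Sites already excluded upstream pass
#' through unchanged.
#'
#' @param sites polarized site table from [polarize_by_parsimony()] with
#'   context columns attached (see [add_contexts()]).
#' @param doubletons_only if TRUE, keep only sites with derived count
#'   exactly 2.
#' @param order context width whose N-filter applies (3 uses the +/-1 bp
#'   flank, 7 the +/-3 bp flank).
#' @param hwe_alpha significance level of the excess-heterozygosity test.
#' @return the site table with updated `verdict` and `reason` columns and a
#'   `hwe_p` column.
#' @export
apply_site_filters <- function(sites, doubletons_only = FALSE, order = 3,
                               hwe_alpha = 0.05) {
  order <- match_order(order)
  ctx_col <- if (order == 3L) "context3" else "context7"
  if (!ctx_col %in% names(sites))
    stop("sites lack ", ctx_col, "; run add_contexts() first")
  live <- sites$verdict == "kept"
  fail <- function(cond, why) {
    hit <- live & !is.na(cond) & cond
    sites$verdict[hit] <<- "excluded"
    sites$reason[hit] <<- why
    live[hit] <<- FALSE
  }
  fail(grepl("N", sites[[ctx_col]], fixed = TRUE), "N-context")
  fail(sites$derived_elsewhere, "recurrent")
  if (doubletons_only) {
    fail(sites$k != 2L, "singleton")
  } else {
    fail(sites$k < 2L, "singleton")
  }
  fail(sites$k / sites$n_hap >= 0.5, "DAF>=0.5")
  hwe_p <- rep(NA_real_, nrow(sites))
  idx <- which(live)
  if (length(idx)) {
    n_focal <- sites$n_hap[idx] / 2L
    n_het <- sites$n_het[idx]
    n_hom <- sites$n_hom_der[idx]
    hwe_p[idx] <- hwe_excess_het_test(n_focal - n_het - n_hom, n_het, n_hom)
  }
  sites$hwe_p <- hwe_p
  fail(hwe_p < hwe_alpha, "HWE-excess-het")
  sites
}

#' Attach ancestral-context strings to polarized sites
#'
#' Looks up the reference flanks around each kept site and substitutes the
#' inferred ancestral allele at the center. Positions too close to a
#' chromosome end get N-padded contexts (and will then fail the N filter).
#'
#' @param polarized output of [polarize_by_parsimony()].
#' @param reference `DNAStringSet` of chromosome sequences.
#' @return `polarized` with `context3` and `context7` columns added to its
#'   site table.
#' @export
add_contexts <- function(polarized, reference) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  sites <- polarized$sites
  sites$context3 <- context_at(reference, sites, 3L)
  sites$context7 <- context_at(reference, sites, 7L)
  polarized$sites <- sites
  polarized
}

context_at <- function(reference, sites, order) {
  flank <- (order - 1L) / 2L
  out <- rep(NA_character_, nrow(sites))
  kept <- which(sites$verdict == "kept")
  pad <- strrep("N", flank)
  for (chr in unique(sites$chrom[kept])) {
    rows <- kept[sites$chrom[kept] == chr]
    # N-pad both ends so chromosome-edge contexts keep their known bases
    seqc <- paste0(pad, as.character(reference[[chr]]), pad)
    pos <- sites$pos[rows] + flank
    raw <- substring(seqc, pos - flank, pos + flank)
    # center carries the ancestral allele
    substr(raw, flank + 1L, flank + 1L) <- sites$ancestral[rows]
    out[rows] <- raw
  }
  out
}

#' Run the full polarization + filter cascade
#'
#' Convenience wrapper: polarize by parsimony, attach contexts, apply the
#' site filters, and return kept sites together with the full disposition
#' table and the derived-allele dosage matrix for the kept sites.
#'
#' @inheritParams polarize_by_parsimony
#' @inheritParams apply_site_filters
#' @param reference `DNAStringSet` of chromosome sequences.
#' @return list with `kept` (site table of kept sites), `disposition`
#'   (full site table), `derived_copies` (kept sites x samples matrix),
#'   `samples`, and `tally` (a table of exclusion reasons).
#' @export
filter_sites <- function(calls, panel, reference, max_missing = 0,
                         doubletons_only = FALSE, order = 3,
                         hwe_alpha = 0.05) {
  pol <- polarize_by_parsimony(calls, panel, max_missing = max_missing)
  pol <- add_contexts(pol, reference)
  sites <- apply_site_filters(pol$sites, doubletons_only = doubletons_only,
                              order = order, hwe_alpha = hwe_alpha)
  keep <- sites$verdict == "kept"
  list(kept = sites[keep, , drop = FALSE],
       disposition = sites,
       derived_copies = pol$derived_copies[keep, , drop = FALSE],
       samples = pol$samples,
       tally = table(factor(sites$reason[!keep])))
}

#' Partition kept sites by derived-allele frequency
#'
#' Splits a kept-site table into derived-frequency bins. `bins` is either a
#' numeric vector of DAF breakpoints (bins are half-open `[b_i, b_{i+1})`)
#' or a named list of predicate functions of `(k, n_hap)`; each site goes
#' to the first bin it matches and every site must match one.
#'
#' @param sites kept site table.
#' @param bins breakpoints or predicates (see above).
#' @return named list of site tables whose union is the input.
#' @export
frequency_stratified_subset <- function(sites, bins) {
  if (is.numeric(bins)) {
    if (length(bins) < 2) stop("need at least two breakpoints")
    daf <- sites$k / sites$n_hap
    grp <- cut(daf, breaks = bins, right = FALSE,
               include.lowest = FALSE)
    if (anyNA(grp)) stop("some sites fall outside the DAF bins")
    return(split(sites, grp))
  }
  if (!is.list(bins) || length(bins) == 0) stop("empty bin specification")
  assigned <- rep(NA_integer_, nrow(sites))
  for (i in seq_along(bins)) {
    hit <- is.na(assigned) & bins[[i]](sites$k, sites$n_hap)
    assigned[hit] <- i
  }
  if (anyNA(assigned)) stop("some sites match no bin")
  nm <- names(bins)
  if (is.null(nm)) nm <- paste0("bin", seq_along(bins))
  setNames(lapply(seq_along(bins),
                  function(i) sites[assigned == i, , drop = FALSE]), nm)
}
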