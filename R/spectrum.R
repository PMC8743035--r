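#' Restrict kept sites to a compartment
#'
#' @param flt output of [filter_sites()] (or any list with `kept` and
#'   `derived_copies`).
#' @param comp compartment `GRanges`.
#' @return the same structure with sites outside the compartment dropped.
#' @export
sites_in_compartment <- function(flt, comp) {
  gr <- GenomicRanges::GRanges(flt$kept$chrom,
                               IRanges::IRanges(flt$kept$pos, width = 1L))
  hit <- GenomicRanges::countOverlaps(gr, comp) > 0L
  flt$kept <- flt$kept[hit, , drop = FALSE]
  flt$derived_copies <- flt$derived_copies[hit, , drop = FALSE]
  flt
}

site_classes <- function(sites, order = 3) {
  ctx <- if (match_order(order) == 3L) sites$context3 else sites$context7
  classify_mutation(ctx, sites$derived)
}

empty_spectrum <- function(order = 3) {
  cls <- mutation_classes(order)
  setNames(numeric(length(cls)), cls)
}

count_classes <- function(class_labels, order = 3, weights = NULL) {
  out <- empty_spectrum(order)
  if (length(class_labels)) {
    if (is.null(weights)) weights <- rep(1, length(class_labels))
    agg <- tapply(weights, class_labels, sum)
    bad <- setdiff(names(agg), names(out))
    if (length(bad)) stop("unknown mutation class: ", bad[1])
    out[names(agg)] <- agg
  }
  out
}

#' Convert a count spectrum to frequencies
#'
#' @param counts named count vector over mutation classes.
#' @return frequency vector summing to 1, or an error for an empty
#'   spectrum (0/0 is undefined, not zero).
#' @export
spectrum_frequencies <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("empty spectrum: frequencies are undefined")
  counts / tot
}

#' Aggregate mutation spectrum of a species
#'
#' Counts every kept SNV segregating within the species (derived allele
#' present in, but not fixed across, the species' samples); each
#' segregating site contributes exactly 1 regardless of its frequency.
#'
#' @param flt filtered site set (optionally compartment-restricted).
#' @param panel panel data frame.
#' @param species species name.
#' @param order 3 or 7.
#' @return named count vector over the class catalog.
#' @export
species_spectrum <- function(flt, panel, species, order = 3) {
  idx <- panel$sample[panel$species == species]
  if (!length(idx)) stop("species not in panel: ", species)
  sub <- flt$derived_copies[, idx, drop = FALSE]
  cnt <- rowSums(sub, na.rm = TRUE)
  nh <- 2L * rowSums(!is.na(sub))
  seg <- cnt > 0L & cnt < nh
  count_classes(site_classes(flt$kept[seg, , drop = FALSE], order), order)
}

#' Full-mode mutation spectrum of one individual
#'
#' Heterozygous derived alleles contribute 1, homozygous derived alleles
#' contribute 2, so the spectrum is the average of the two phased
#' haplotypes' spectra.
#'
#' @param flt filtered site set.
#' @param sample sample id.
#' @param order 3 or 7.
#' @return named count vector.
#' @export
individual_spectrum <- function(flt, sample, order = 3) {
  if (!sample %in% colnames(flt$derived_copies))
    stop("sample not in call set: ", sample)
  w <- flt$derived_copies[, sample]
  sel <- !is.na(w) & w > 0L
  count_classes(site_classes(flt$kept[sel, , drop = FALSE], order), order,
                weights = w[sel])
}

#' Randomized (haplotype-thinned) mutation spectra
#'
#' Counts each kept SNV toward the spectrum of exactly one of the
#' haplotypes that carry the derived allele, chosen uniformly at random.
#' A heterozygous carrier therefore receives the site with probability
#' 1/k and a homozygous carrier with probability 2/k, where k is the
#' site's derived haplotype count. Summing the returned rows reproduces
#' the total site-count spectrum exactly.
#'
#' @param flt filtered site set.
#' @param order 3 or 7.
#' @param seed integer seed.
#' @return samples x classes count matrix.
#' @export
randomized_spectrum <- function(flt, order = 3, seed = 1) {
  set.seed(seed)
  copies <- flt$derived_copies
  copies[is.na(copies)] <- 0L
  n <- nrow(copies)
  m <- ncol(copies)
  cls <- mutation_classes(order)
  out <- matrix(0, m, length(cls),
                dimnames = list(colnames(copies), cls))
  if (n == 0) return(out)
  k <- rowSums(copies)
  if (any(k == 0)) stop("site with no derived carriers; filter first")
  cum <- copies %*% upper.tri(diag(m), diag = TRUE)
  r <- runif(n) * k
  chosen <- rowSums(cum < r) + 1L
  labels <- site_classes(flt$kept, order)
  tab <- table(factor(colnames(copies)[chosen],
                      levels = colnames(copies)),
               factor(labels, levels = cls))
  out + unclass(tab)
}

#' Down-sample individuals per species
#'
#' Uniform sampling without replacement of a fixed number of individuals
#' from each species, deterministic given the seed.
#'
#' @param panel panel data frame.
#' @param n_per_species target number of individuals per species; either a
#'   single number or a named vector by species.
#' @param seed integer seed.
#' @return reduced panel data frame.
#' @export
subsample_individuals <- function(panel, n_per_species, seed = 1) {
  set.seed(seed)
  sp <- unique(panel$species)
  if (is.null(names(n_per_species)))
    n_per_species <- setNames(rep_len(n_per_species, length(sp)), sp)
  keep <- unlist(lapply(sp, function(s) {
    ids <- panel$sample[panel$species == s]
    n <- n_per_species[[s]]
    if (n > length(ids))
      stop("requested ", n, " individuals from ", s, " but only ",
           length(ids), " available")
    sample(ids, n)
  }))
  panel[panel$sample %in% keep, , drop = FALSE]
}

#' Write / read a spectrum matrix as TSV with a JSON sidecar
#'
#' Rows are mutation classes in the fixed canonical order, columns are
#' samples or species; provenance (unit, context order, seed, compartment)
#' goes into `<path>.json`.
#'
#' @param mat classes-in-rows numeric matrix (a spectra x classes matrix is
#'   transposed on write).
#' @param path output TSV path.
#' @param meta named list of provenance fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(mat, path, meta = list()) {
  cls3 <- mutation_classes(3)
  cls7 <- mutation_classes(7)
  if (!is.null(colnames(mat)) &&
      (all(colnames(mat) %in% cls3) || all(colnames(mat) %in% cls7)))
    mat <- t(mat)
  utils::write.table(data.frame(class = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$class
  mat
}
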