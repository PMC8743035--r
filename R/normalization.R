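#' Rescale compartment mutation counts by reference context content
#'
#' Rescales the count of each mutation class in a compartment by the ratio
#' of the reference compartment's context content to the focal
#' compartment's, then normalizes to rates summing to 1. Classes sharing a
#' context share a scaling factor, so a compartment is compared on the
#' footing of the reference compartment's mutational opportunity.
#'
#' @param counts named count vector over the class catalog (3-mer or
#'   7-mer labels).
#' @param content_c context content of the focal compartment
#'   (from [compartment_content()]).
#' @param content_ref context content of the reference compartment.
#' @return list of class `rescaled_rates` with `weights` (the rescaled
#'   counts), `rates` (normalized, summing to 1), and `reference` (the
#'   reference compartment name, when known).
#' @export
rescale_rates <- function(counts, content_c, content_ref) {
  ctx <- class_context(names(counts))
  miss <- setdiff(ctx, names(content_c))
  if (length(miss)) stop("content lacks context ", miss[1])
  cc <- as.numeric(content_c[ctx])
  cr <- as.numeric(content_ref[ctx])
  bad <- cc == 0 & counts > 0
  if (any(bad))
    stop("zero content for context ", ctx[which(bad)[1]],
         " with nonzero mutation count")
  w <- ifelse(counts > 0, counts * cr / cc, 0)
  names(w) <- names(counts)
  tot <- sum(w)
  if (tot <= 0) stop("empty spectrum cannot be rescaled")
  structure(list(weights = w, rates = w / tot,
                 reference = attr(content_ref, "compartment")),
            class = "rescaled_rates")
}

#' Content-matched count downscaling for two-compartment tests
#'
#' For each mutation class, the compartment with the larger context
#' content has its raw count multiplied by the (at most 1) content ratio;
#' the other compartment's count is left unchanged. Scaling down rather
#' than up avoids inflating counts fed into count-based tests.
#'
#' @param counts_1,counts_2 named count vectors over the class catalog.
#' @param content_1,content_2 context contents of the two compartments.
#' @param round_counts round the adjusted counts to the nearest integer
#'   (off by default; count-based tests may prefer integers).
#' @return list with adjusted `counts_1` and `counts_2`.
#' @export
downscale_counts <- function(counts_1, content_1, counts_2, content_2,
                             round_counts = FALSE) {
  stopifnot(identical(names(counts_1), names(counts_2)))
  ctx <- class_context(names(counts_1))
  c1 <- as.numeric(content_1[ctx])
  c2 <- as.numeric(content_2[ctx])
  if (any(c1 == 0 & counts_1 > 0) || any(c2 == 0 & counts_2 > 0))
    stop("zero content with nonzero mutation count")
  bigger1 <- c1 >= c2
  a1 <- ifelse(bigger1 & counts_1 > 0, counts_1 * c2 / c1, counts_1)
  a2 <- ifelse(!bigger1 & counts_2 > 0, counts_2 * c1 / c2, counts_2)
  if (round_counts) {
    a1 <- round(a1)
    a2 <- round(a2)
  }
  list(counts_1 = setNames(a1, names(counts_1)),
       counts_2 = setNames(a2, names(counts_2)))
}

#' 7-mer content correction of triplet mutation rates
#'
#' Reweights each 7-mer mutation count in compartment `C` by the ratio of
#' the target compartment's 7-mer content to `C`'s own, sums the corrected
#' counts within each parent triplet class, and normalizes. This asks what
#' the triplet spectrum of `C` would look like if its extended sequence
#' context composition matched the target compartment.
#'
#' @param counts7 named count vector over 7-mer mutation classes (a sparse
#'   vector holding only nonzero classes is fine).
#' @param content7_c 7-mer context content of compartment `C`.
#' @param content7_target 7-mer context content of the target compartment.
#' @return list of class `rescaled_rates` with triplet-class `weights` and
#'   normalized `rates`.
#' @export
sevenmer_correct <- function(counts7, content7_c, content7_target) {
  if (is.null(names(counts7))) stop("counts7 must be named by 7-mer class")
  counts7 <- counts7[counts7 > 0]
  ctx <- class_context(names(counts7))
  if (any(nchar(ctx) != 7L)) stop("counts7 labels must be 7-mer classes")
  cc <- as.numeric(content7_c[ctx])
  if (any(cc == 0))
    stop("zero 7-mer content for context ", ctx[which(cc == 0)[1]],
         " with nonzero mutation count")
  ct <- as.numeric(content7_target[ctx])
  w7 <- counts7 * ct / cc
  parent <- class7_parent3(names(counts7))
  w <- empty_spectrum(3)
  agg <- tapply(w7, parent, sum)
  w[names(agg)] <- agg
  tot <- sum(w)
  if (tot <= 0) stop("empty spectrum cannot be corrected")
  structure(list(weights = w, rates = w / tot,
                 reference = attr(content7_target, "compartment")),
            class = "rescaled_rates")
}
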