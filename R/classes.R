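#' @importFrom stats prcomp cor.test dist hclust cutree as.dist quantile
#'   runif rbinom setNames aggregate
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of plain character DNA strings
#'
#' Small vectorized helper used throughout for strand collapsing of contexts
#' and alleles. Non-ACGT letters (e.g. N) are preserved.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Strand-collapsed mutation contexts
#'
#' All k-mer contexts whose central base is A or C, in lexicographic order.
#' At triplet resolution there are 32 such contexts; at 7-mer resolution,
#' 8,192. Every raw k-mer maps onto this catalog either directly or via its
#' reverse complement.
#'
#' @param order context width, 3 or 7.
#' @return character vector of contexts in canonical (lexicographic) order.
#' @export
mutation_contexts <- function(order = 3) {
  order <- match_order(order)
  flank <- (order - 1L) / 2L
  sides <- do.call(expand.grid,
                   c(rep(list(DNA_BASES4), 2L * flank),
                     list(stringsAsFactors = FALSE)))
  ctr <- c("A", "C")
  out <- character(0)
  for (centre in ctr) {
    left <- do.call(paste0, sides[, seq_len(flank), drop = FALSE])
    right <- do.call(paste0, sides[, flank + seq_len(flank), drop = FALSE])
    out <- c(out, unique(paste0(left, centre, right)))
  }
  sort(unique(out))
}

#' Strand-collapsed mutation class catalog
#'
#' The full catalog of strand-collapsed substitution classes at triplet or
#' 7-mer resolution, labelled `<ancestral context>><derived central base>`
#' (e.g. `"ACG>T"`). There are 96 triplet classes (32 contexts x 3 derived
#' alleles) and 24,576 7-mer classes. The order returned here is the fixed
#' canonical order used by every spectrum in the package.
#'
#' @param order context width, 3 or 7.
#' @return character vector of class labels in canonical order.
#' @export
mutation_classes <- function(order = 3) {
  ctx <- mutation_contexts(order)
  centre <- substr(ctx, (order + 1L) / 2L, (order + 1L) / 2L)
  out <- unlist(lapply(seq_along(ctx), function(i) {
    alt <- setdiff(DNA_BASES4, centre[i])
    paste0(ctx[i], ">", alt)
  }))
  sort(out)
}

match_order <- function(order) {
  order <- as.integer(order)
  if (!order %in% c(3L, 7L)) stop("context order must be 3 or 7")
  order
}

#' Context of a mutation class label
#' @param class character vector of class labels.
#' @return ancestral context string for each class.
#' @export
class_context <- function(class) sub(">.*$", "", class)

#' Derived central base of a mutation class label
#' @param class character vector of class labels.
#' @return derived central base for each class.
#' @export
class_derived <- function(class) sub("^.*>", "", class)

#' Parent triplet class of a 7-mer mutation class
#'
#' Each triplet class is a collapsed equivalence class of 256 7-mer classes;
#' this maps a 7-mer class label to its parent by trimming the outer two
#' flanking bases on each side.
#'
#' @param class7 character vector of 7-mer class labels.
#' @return character vector of triplet class labels.
#' @export
class7_parent3 <- function(class7) {
  ctx <- class_context(class7)
  stopifnot(all(nchar(ctx) == 7L))
  paste0(substr(ctx, 3L, 5L), ">", class_derived(class7))
}

#' Classify a polarized substitution into its strand-collapsed class
#'
#' Takes the ancestral context (3 or 7 bases, centered on the ancestral
#' allele) and the derived allele, and returns the strand-collapsed class
#' label. When the central base is G or T the context is reverse
#' complemented and the derived allele complemented, so that each biological
#' event and its reverse-strand reading map to one class.
#'
#' @param context character vector of ancestral contexts (all same width,
#'   3 or 7); the central base is the ancestral allele.
#' @param derived character vector of derived alleles (single bases).
#' @return character vector of class labels.
#' @examples
#' classify_mutation("ACG", "T")   # "ACG>T"
#' classify_mutation("CGT", "A")   # also "ACG>T", via reverse complement
#' @export
classify_mutation <- function(context, derived) {
  n <- nchar(context)
  if (length(unique(n)) != 1L) stop("mixed context widths")
  order <- match_order(n[1])
  mid <- (order + 1L) / 2L
  context <- toupper(context)
  derived <- toupper(derived)
  if (any(grepl("N", context, fixed = TRUE)))
    stop("context contains N; such sites must be filtered out first")
  centre <- substr(context, mid, mid)
  if (any(centre == derived))
    stop("derived allele equals ancestral allele")
  flip <- centre %in% c("G", "T")
  if (any(flip)) {
    context[flip] <- revcomp(context[flip])
    derived[flip] <- complement_base(derived[flip])
  }
  paste0(context, ">", derived)
}
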