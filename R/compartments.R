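#' Construct a genomic compartment
#'
#' A compartment is a named set of genomic intervals sharing an annotation
#' (a replication-timing quartile, a repeat class, a chromatin state, ...).
#' Internally compartments are `GRanges`; on disk they are BED (0-based,
#' half-open). This constructor takes 0-based half-open coordinates, the
#' BED dialect.
#'
#' @param name compartment name.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return a `GRanges` with the compartment name in its metadata, sorted and
#'   with zero-length intervals dropped.
#' @export
compartment <- function(name, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  keep <- end > start
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = start[keep] + 1L, end = end[keep]))
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$compartment <- name
  gr
}

compartment_name <- function(gr) {
  nm <- S4Vectors::metadata(gr)$compartment
  if (is.null(nm)) "unnamed" else nm
}

set_compartment_name <- function(gr, name) {
  S4Vectors::metadata(gr)$compartment <- name
  gr
}

#' Total length of a compartment in bases
#' @param gr compartment `GRanges`.
#' @return integer total width after merging overlapping intervals.
#' @export
compartment_length <- function(gr) {
  sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
}

#' Read / write compartments as BED
#'
#' Three-column BED, 0-based half-open, one file per compartment. The
#' compartment name defaults to the file's base name.
#'
#' @param path file path.
#' @param name compartment name (read) or compartment `GRanges` (write).
#' @return `read_bed` returns a compartment `GRanges`; `write_bed` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  compartment(name, df$chrom, df$start, df$end)
}

#' @rdname read_bed
#' @param gr compartment `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count strand-collapsed k-mer contexts inside a compartment
#'
#' Slides a window of the given width one base at a time across each
#' compartment segment, counting windows that lie wholly inside a segment.
#' Windows containing N contribute nothing. Counts are strand collapsed so
#' that every context has a central A or C.
#'
#' @param reference a `DNAStringSet` of chromosome sequences (names are
#'   chromosome names).
#' @param comp compartment `GRanges`.
#' @param order window width, 3 or 7.
#' @return named numeric vector over `mutation_contexts(order)` with
#'   attributes `order` and `total` (number of windows counted).
#' @export
compartment_content <- function(reference, comp, order = 3) {
  order <- match_order(order)
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  comp <- GenomicRanges::reduce(comp)
  chroms <- as.character(GenomicRanges::seqnames(comp))
  bad <- !chroms %in% names(reference)
  if (any(bad)) stop("compartment chromosome absent from reference: ",
                     paste(unique(chroms[bad]), collapse = ", "))
  raw <- integer(4L^order)
  for (chr in unique(chroms)) {
    sel <- comp[chroms == chr]
    if (any(GenomicRanges::end(sel) > length(reference[[chr]])))
      stop("interval beyond end of chromosome ", chr)
    v <- Biostrings::Views(reference[[chr]], GenomicRanges::ranges(sel))
    counts <- Biostrings::oligonucleotideFrequency(
      v, width = order, step = 1, simplify.as = "collapsed")
    raw <- raw + counts
  }
  collapse_context_counts(raw, order)
}

# collapse a 4^order count vector (names = raw k-mers) onto the canonical
# central-A/C context catalog
collapse_context_counts <- function(raw, order) {
  if (is.null(names(raw)))
    names(raw) <- Biostrings::mkAllStrings(DNA_BASES4, order)
  mid <- (order + 1L) / 2L
  nm <- names(raw)
  flip <- substr(nm, mid, mid) %in% c("G", "T")
  nm[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(nm[flip])))
  ctx <- mutation_contexts(order)
  out <- setNames(numeric(length(ctx)), ctx)
  agg <- tapply(as.numeric(raw), nm, sum)
  out[names(agg)] <- agg
  attr(out, "order") <- order
  attr(out, "total") <- sum(out)
  out
}

#' Interval algebra on compartments
#'
#' Standard half-open interval set operations; the result is merged and
#' sorted.
#'
#' @param a,b compartment `GRanges` on the same reference.
#' @param mode one of `"intersect"`, `"subtract"`, `"union"`.
#' @param name name for the derived compartment.
#' @return compartment `GRanges`.
#' @export
combine_compartments <- function(a, b,
                                 mode = c("intersect", "subtract", "union"),
                                 name = NULL) {
  mode <- match.arg(mode)
  out <- switch(mode,
    intersect = GenomicRanges::intersect(a, b, ignore.strand = TRUE),
    subtract = GenomicRanges::setdiff(a, b, ignore.strand = TRUE),
    union = GenomicRanges::union(a, b, ignore.strand = TRUE))
  out <- GenomicRanges::sort(GenomicRanges::reduce(out))
  if (is.null(name))
    name <- paste(compartment_name(a), mode, compartment_name(b))
  set_compartment_name(out, name)
}

#' Length-preserving bootstrap of a compartment inside a background
#'
#' Builds null compartments that have the same per-chromosome multiset of
#' segment lengths as `target`, with every segment placed uniformly at
#' random among the positions where it fits wholly inside a `background`
#' segment. Placements overlapping an N in the reference are resampled;
#' placed segments are allowed to overlap each other.
#'
#' @param target compartment whose segment lengths are preserved.
#' @param background compartment within which segments are placed.
#' @param reference `DNAStringSet` used only to reject placements over N.
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param max_retries retry budget per segment before failing.
#' @return list of `n_reps` compartment `GRanges`.
#' @export
bootstrap_ervlike <- function(target, background, reference, n_reps = 100,
                              seed = 1, max_retries = 1000) {
  set.seed(seed)
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  background <- GenomicRanges::reduce(background)
  bg_chrom <- as.character(GenomicRanges::seqnames(background))
  tg_chrom <- as.character(GenomicRanges::seqnames(target))
  has_n <- vapply(names(reference), function(chr)
    Biostrings::letterFrequency(reference[[chr]], "N") > 0, logical(1))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    chroms <- character(0); starts <- integer(0); widths <- integer(0)
    for (chr in unique(tg_chrom)) {
      lens <- GenomicRanges::width(target[tg_chrom == chr])
      bg <- background[bg_chrom == chr]
      bg_start <- GenomicRanges::start(bg)
      bg_width <- GenomicRanges::width(bg)
      for (L in lens) {
        slots <- bg_width - L + 1L
        ok <- slots > 0L
        if (!any(ok))
          stop("no background segment on ", chr, " can hold length ", L)
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          seg <- sample.int(sum(ok), 1L, prob = slots[ok])
          idx <- which(ok)[seg]
          s <- bg_start[idx] + sample.int(slots[idx], 1L) - 1L
          if (has_n[[chr]]) {
            sub <- Biostrings::subseq(reference[[chr]], s, s + L - 1L)
            if (Biostrings::letterFrequency(sub, "N") > 0) next
          }
          chroms <- c(chroms, chr); starts <- c(starts, s)
          widths <- c(widths, L)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place segment of length ", L, " on ", chr,
               " within ", max_retries, " attempts (N-dense background?)")
      }
    }
    gr <- GenomicRanges::GRanges(chroms,
                                 IRanges::IRanges(start = starts,
                                                  width = widths))
    reps[[r]] <- set_compartment_name(gr, paste0(compartment_name(target),
                                                 "_boot", r))
  }
  reps
}

#' Earliest/latest replication-timing quartile compartments
#'
#' Averages replication-timing measurements in non-overlapping windows
#' (default 20 kb), drops windows with no measurement, and returns the
#' windows in the lowest and highest quartile of window means. Ties at the
#' quartile boundary are broken by window start order, so each quartile
#' holds exactly `floor(n/4)` windows (minimum 1).
#'
#' @param timing data frame with columns `chrom`, `start`, `end`, `value`
#'   (BedGraph-style, 0-based half-open intervals carrying a timing value).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param window window size in bases (default 20000).
#' @return list with compartments `earliest` and `latest` plus the window
#'   table `windows` (chrom, start, end, mean value).
#' @export
replication_timing_quartiles <- function(timing, seqlengths,
                                         window = 20000L) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(timing)))
  mids <- (timing$start + timing$end) / 2
  win_index <- floor(mids / window)
  key <- paste(timing$chrom, win_index, sep = ":")
  means <- tapply(timing$value, key, mean)
  parts <- strsplit(names(means), ":", fixed = TRUE)
  wchrom <- vapply(parts, `[`, character(1), 1L)
  wstart <- as.numeric(vapply(parts, `[`, character(1), 2L)) * window
  wend <- pmin(wstart + window, seqlengths[wchrom])
  if (length(means) == 0) stop("no windows with measurements")
  ord <- order(as.numeric(means), wchrom, wstart)
  k <- max(1L, floor(length(means) / 4))
  lo <- ord[seq_len(k)]
  hi <- rev(ord)[seq_len(k)]
  windows <- data.frame(chrom = wchrom, start = wstart, end = wend,
                        mean = as.numeric(means))
  list(
    earliest = compartment("rt_earliest", wchrom[lo], wstart[lo], wend[lo]),
    latest = compartment("rt_latest", wchrom[hi], wstart[hi], wend[hi]),
    windows = windows)
}
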