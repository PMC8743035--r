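#' Stack spectra into an analysis matrix
#'
#' Binds a named list of spectrum vectors (counts, frequencies, or
#' rescaled rates) into a rows-are-spectra matrix, checking that all share
#' the canonical class order. Row names carry the provenance.
#'
#' @param spectra named list of equal-length named numeric vectors, or of
#'   `rescaled_rates` objects (whose `rates` are used).
#' @return numeric matrix, rows = spectra, columns = mutation classes.
#' @export
build_spectrum_matrix <- function(spectra) {
  vecs <- lapply(spectra, function(s) {
    if (inherits(s, "rescaled_rates")) s$rates else s
  })
  cls <- names(vecs[[1]])
  ok <- vapply(vecs, function(v) identical(names(v), cls), logical(1))
  if (!all(ok)) stop("spectra do not share the same class order")
  mat <- do.call(rbind, vecs)
  rownames(mat) <- names(spectra)
  mat
}

#' PCA of a spectrum matrix
#'
#' Centered and scaled principal component analysis of a rows-are-spectra
#' matrix. Zero-variance columns are dropped before scaling. Each loading
#' vector is oriented so that its largest-magnitude entry is positive,
#' making the result deterministic.
#'
#' @param mat rows-are-spectra matrix.
#' @param center,scale passed to [prcomp()].
#' @return list with `scores`, `loadings`, `var_explained` (fractions),
#'   `kept_classes`, and the centering/scaling vectors.
#' @export
run_pca <- function(mat, center = TRUE, scale = TRUE) {
  if (nrow(mat) < 2) stop("PCA needs at least two spectra")
  v <- apply(mat, 2, stats::var)
  keep <- if (scale) v > 0 else rep(TRUE, ncol(mat))
  p <- stats::prcomp(mat[, keep, drop = FALSE],
                     center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  list(scores = scores, loadings = rot,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       kept_classes = colnames(mat)[keep],
       center = p$center, scale = p$scale)
}

#' Mean silhouette of labelled rows in PC space
#'
#' Convenience wrapper measuring how cleanly a labelling (species,
#' compartment, ...) separates spectra in the score space of a PCA.
#'
#' @param scores score matrix (rows = spectra).
#' @param labels grouping vector, one per row.
#' @param dims number of leading components to use (default all).
#' @return mean silhouette width.
#' @export
group_silhouette <- function(scores, labels, dims = ncol(scores)) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least two groups")
  d <- stats::dist(scores[, seq_len(dims), drop = FALSE])
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

#' Two-sided t-test on one principal component's scores
#'
#' @param pca result of [run_pca()].
#' @param labels two-level grouping vector.
#' @param pc component index.
#' @return an `htest` object.
#' @export
pc_score_ttest <- function(pca, labels, pc = 1) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("t-test needs exactly two groups")
  stats::t.test(pca$scores[, pc] ~ labels)
}

#' Non-negative matrix factorization of a spectrum matrix
#'
#' Frobenius-objective NMF fitted by multiplicative updates from random
#' non-negative starts; the best of `restarts` fits is kept. Signature
#' rows are normalized to sum to 1, with the mass moved into the
#' exposures.
#'
#' @param mat non-negative rows-are-spectra matrix.
#' @param k number of signatures (less than both dimensions).
#' @param restarts number of random restarts (default 20).
#' @param max_iter,tol update budget and relative-change stopping rule.
#' @param seed integer seed.
#' @return list with `signatures` (k x classes, rows sum to 1),
#'   `exposures` (spectra x k), `residual` (relative Frobenius error) and
#'   `objective` (the best run's objective trace, non-increasing).
#' @export
run_nmf <- function(mat, k, restarts = 20, max_iter = 2000, tol = 1e-9,
                    seed = 1) {
  if (any(mat < 0)) stop("NMF input must be non-negative")
  if (k >= min(dim(mat))) stop("k must be below both matrix dimensions")
  set.seed(seed)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(restarts)) {
    W <- matrix(runif(nrow(mat) * k, 0.1, 1), nrow(mat), k)
    H <- matrix(runif(k * ncol(mat), 0.1, 1), k, ncol(mat))
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (t(W) %*% mat) / (t(W) %*% W %*% H + eps)
      W <- W * (mat %*% t(H)) / (W %*% H %*% t(H) + eps)
      f <- sum((mat - W %*% H)^2)
      obj <- c(obj, f)
      if (prev - f < tol * max(f, eps)) break
      prev <- f
    }
    if (is.null(best) || tail(obj, 1) < tail(best$obj, 1))
      best <- list(W = W, H = H, obj = obj)
  }
  rs <- rowSums(best$H)
  H <- best$H / rs
  W <- sweep(best$W, 2, rs, `*`)
  dimnames(H) <- list(paste0("S", seq_len(k)), colnames(mat))
  dimnames(W) <- list(rownames(mat), paste0("S", seq_len(k)))
  list(signatures = H, exposures = W,
       residual = sqrt(tail(best$obj, 1)) / sqrt(sum(mat^2)),
       objective = best$obj)
}

#' Cosine similarity between signature vectors
#' @param a,b numeric vectors.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Agglomerative clustering of mutational signatures
#'
#' Groups signature loading vectors (possibly from independently fitted
#' NMFs across runs or species) by hierarchical agglomerative clustering,
#' by default on cosine distance with average linkage.
#'
#' @param signatures matrix of signatures in rows (same class set).
#' @param k number of clusters to cut (alternative to `h`).
#' @param h dendrogram height to cut at.
#' @param metric `"cosine"` or `"euclidean"`.
#' @param linkage linkage passed to [hclust()].
#' @return list with `assignment` (named cluster ids) and the `hclust`
#'   tree.
#' @export
cluster_signatures <- function(signatures, k = NULL, h = NULL,
                               metric = c("cosine", "euclidean"),
                               linkage = "average") {
  metric <- match.arg(metric)
  if (nrow(signatures) < 2) stop("need at least two signatures")
  d <- if (metric == "cosine") {
    s <- signatures / sqrt(rowSums(signatures^2))
    stats::as.dist(pmax(1 - tcrossprod(s), 0))
  } else {
    stats::dist(signatures)
  }
  tree <- stats::hclust(d, method = linkage)
  if (is.null(k) && is.null(h)) k <- 2L
  assignment <- stats::cutree(tree, k = k, h = h)
  names(assignment) <- rownames(signatures)
  list(assignment = assignment, tree = tree)
}

#' Within- and between-group Euclidean spectrum distances
#'
#' Computes Euclidean distances between all pairs of individual spectra:
#' choose-2 pairs within each group and k x l pairs between each pair of
#' groups.
#'
#' @param mat rows-are-spectra matrix (one row per individual).
#' @param groups group label per row (species, subspecies, ...).
#' @param unit `"frequency"` (rows renormalized to sum 1, the default) or
#'   `"count"` (rows used as-is).
#' @return data frame with columns `group_a`, `group_b`, `type`
#'   (within/between) and `distance`.
#' @export
pairwise_distance_distributions <- function(mat, groups,
                                            unit = c("frequency", "count")) {
  unit <- match.arg(unit)
  if (nrow(mat) < 2) stop("need at least two individuals")
  if (unit == "frequency") mat <- mat / rowSums(mat)
  d <- as.matrix(stats::dist(mat))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ga <- groups[idx[, 1]]
  gb <- groups[idx[, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  data.frame(group_a = ga, group_b = gb,
             type = ifelse(ga == gb, "within", "between"),
             distance = d[idx])
}

#' Log-odds heatmap between two compartments' rescaled rates
#'
#' Per-class natural-log ratio of the rescaled mutation rates of two
#' compartments. Classes where either rate is zero are masked (`NA`)
#' rather than pseudocounted. Swapping the arguments negates the result.
#'
#' @param rates_1,rates_2 `rescaled_rates` objects or named rate vectors
#'   on the same classes.
#' @return named numeric vector of log ratios (`NA` = masked).
#' @export
log_odds_heatmap <- function(rates_1, rates_2) {
  r1 <- if (inherits(rates_1, "rescaled_rates")) rates_1$rates else rates_1
  r2 <- if (inherits(rates_2, "rescaled_rates")) rates_2$rates else rates_2
  if (!identical(names(r1), names(r2)))
    stop("rate vectors are not on the same class set")
  out <- ifelse(r1 > 0 & r2 > 0, log(r1) - log(r2), NA_real_)
  setNames(out, names(r1))
}

#' Pearson correlation between two log-odds heatmaps
#'
#' Masked classes are dropped pairwise; the remaining paired log-odds are
#' tested with a standard product-moment correlation.
#'
#' @param h1,h2 log-odds vectors on the same class set.
#' @return list with `estimate`, `p_value`, `n` and the full `htest`.
#' @export
heatmap_correlation <- function(h1, h2) {
  if (!identical(names(h1), names(h2)))
    stop("heatmaps are not on the same class set")
  ok <- !is.na(h1) & !is.na(h2)
  if (sum(ok) < 3) stop("fewer than 3 unmasked class pairs")
  ct <- stats::cor.test(h1[ok], h2[ok], method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = sum(ok), test = ct)
}

#' Multinomial likelihood fit of a de novo mutation spectrum
#'
#' For each candidate species, converts its segregating-site counts into
#' class probabilities and scores the observed de novo mutation (DNM)
#' counts by the multinomial log likelihood (the multinomial coefficient,
#' constant across species, is omitted). The effect size is the fold range
#' `exp(max - min)` across species; the fit is called significant when the
#' fold range reaches the threshold (20, matching alpha = 0.05).
#'
#' @param dnm_counts named count vector of the individual's DNMs.
#' @param species_counts species x classes count matrix of segregating
#'   sites.
#' @param fold_threshold significance threshold on the fold range.
#' @return list with `log_likelihood` (per species), `probabilities`,
#'   `fold_range`, `log_fold_range` (its logarithm, safe against
#'   overflow), `best_species`, `significant` and `threshold`.
#' @export
dnm_fit_test <- function(dnm_counts, species_counts, fold_threshold = 20) {
  if (is.null(dim(species_counts)) || nrow(species_counts) < 2)
    stop("need at least two candidate species")
  if (!identical(colnames(species_counts), names(dnm_counts)))
    stop("DNM counts and species counts must share the class set")
  p <- species_counts / rowSums(species_counts)
  logp <- log(p)
  obs <- dnm_counts > 0
  logp[, obs][!is.finite(logp[, obs, drop = FALSE])] <- -Inf
  ll <- as.numeric(logp[, obs, drop = FALSE] %*% dnm_counts[obs])
  names(ll) <- rownames(species_counts)
  log_fold <- max(ll) - min(ll)
  # significance is decided on the log scale so that very large
  # likelihood gaps do not overflow exp()
  list(log_likelihood = ll, probabilities = p,
       fold_range = exp(log_fold), log_fold_range = log_fold,
       best_species = names(ll)[which.max(ll)],
       significant = log_fold >= log(fold_threshold),
       threshold = fold_threshold,
       degenerate = any(!is.finite(ll)))
}

#' Bootstrap enrichment test of one mutation class between compartments
#'
#' Tests whether the enrichment of a mutation class in a target
#' compartment relative to a background compartment exceeds what
#' same-shaped compartments drawn from the background produce. The
#' statistic is the log-odds of the class computed from content-matched,
#' down-scaled counts (see [downscale_counts()]). The null distribution
#' comes from replicates built by [bootstrap_ervlike()]; the observed
#' statistic additionally gets a nonparametric percentile confidence
#' interval from resampling the target compartment's SNVs.
#'
#' @param flt filtered site set (genome-wide).
#' @param reference `DNAStringSet` reference sequence.
#' @param target,background compartment `GRanges`.
#' @param replicates list of null compartments with the target's segment
#'   lengths (from [bootstrap_ervlike()]).
#' @param class mutation class of interest (e.g. `"ACG>G"`).
#' @param order 3 or 7.
#' @param n_boot resamples for the observed statistic's CI (default 1000).
#' @param conf CI level (default 0.95).
#' @param seed integer seed for the CI resampling.
#' @return list with `observed`, `ci`, `null` (one value per replicate),
#'   and `outside_null` (observed outside the null's min-max range).
#' @export
bootstrap_enrichment_test <- function(flt, reference, target, background,
                                      replicates, class, order = 3,
                                      n_boot = 1000, conf = 0.95,
                                      seed = 1) {
  set.seed(seed)
  cls <- mutation_classes(order)
  if (!class %in% cls) stop("unknown mutation class: ", class)
  pooled_counts <- function(comp) {
    sub <- sites_in_compartment(flt, comp)
    count_classes(site_classes(sub$kept, order), order)
  }
  pair_lo <- function(cnt_a, content_a, cnt_b, content_b) {
    ds <- downscale_counts(cnt_a, content_a, cnt_b, content_b)
    log(ds$counts_1[class] / sum(ds$counts_1)) -
      log(ds$counts_2[class] / sum(ds$counts_2))
  }
  content_t <- compartment_content(reference, target, order)
  content_b <- compartment_content(reference, background, order)
  cnt_t <- pooled_counts(target)
  cnt_b <- pooled_counts(background)
  observed <- unname(pair_lo(cnt_t, content_t, cnt_b, content_b))

  null <- vapply(replicates, function(rep) {
    unname(pair_lo(pooled_counts(rep),
                   compartment_content(reference, rep, order),
                   cnt_b, content_b))
  }, numeric(1))

  # percentile CI by multinomial resampling of the target's SNVs
  n_t <- sum(cnt_t)
  boots <- stats::rmultinom(n_boot, n_t, prob = cnt_t / n_t)
  rownames(boots) <- names(cnt_t)
  ctx <- class_context(cls)
  fac <- setNames(ifelse(content_t[ctx] >= content_b[ctx],
                         as.numeric(content_b[ctx]) /
                           as.numeric(content_t[ctx]), 1), cls)
  bg_fac <- setNames(ifelse(content_b[ctx] > content_t[ctx],
                            as.numeric(content_t[ctx]) /
                              as.numeric(content_b[ctx]), 1), cls)
  a2 <- cnt_b * bg_fac
  lo_b <- log(fac[class] * boots[class, ] / colSums(boots * fac)) -
    log(a2[class] / sum(a2))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(lo_b, c(alpha, 1 - alpha)))
  list(observed = observed, ci = ci, null = null,
       outside_null = observed < min(null) | observed > max(null))
}
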