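# Detection filtering, library-size normalization factors, the three count
# transformations the downstream analyses run on (log-CPM, precision-weighted
# log-CPM, NB variance-stabilizing transform) and sample-space PCA.
#
# The transforms are faithful-in-spirit simplifications of the standard
# RNA-seq toolchain, validated by distributional properties rather than
# bit-compatibility with any particular package.

#' Construct a transformed expression matrix
#'
#' @param values numeric matrix (features x samples) of transformed values.
#' @param transform_id one of `"logcpm"`, `"weighted_logcpm"`, `"vst"`.
#' @param weights optional positive observation weights (same shape), present
#'   iff `transform_id == "weighted_logcpm"`.
#' @param params list of parameters used (prior count, factors, dispersion).
#' @return A `transformed_matrix` object.
#' @export
transformed_matrix <- function(values, transform_id, weights = NULL, params = list()) {
  transform_id <- match.arg(transform_id, c("logcpm", "weighted_logcpm", "vst"))
  if (!all(is.finite(values))) stop("transformed values must be finite", call. = FALSE)
  if (!is.null(weights)) {
    if (!identical(dim(weights), dim(values))) stop("weights shape mismatch", call. = FALSE)
    if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  }
  if (xor(transform_id == "weighted_logcpm", !is.null(weights))) {
    stop("weights present iff transform is weighted_logcpm", call. = FALSE)
  }
  structure(list(values = values, transform_id = transform_id,
                 weights = weights, params = params),
            class = "transformed_matrix")
}

#' Filter features by detection
#'
#' Retains a feature iff the fraction of samples with at least `min_reads`
#' reads is `>= min_fraction` (both comparisons inclusive, so 1 of 4 samples
#' passes the default 25% rule). Idempotent; preserves feature order.
#'
#' @param cm count matrix.
#' @param min_reads minimum read count for a sample to count as detecting.
#' @param min_fraction minimum detecting-sample fraction.
#' @return The filtered count matrix.
#' @export
filter_detected <- function(cm, min_reads = 1, min_fraction = 0.25) {
  if (min_reads < 1) stop("min_reads must be >= 1", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]", call. = FALSE)
  keep <- rowMeans(cm >= min_reads) >= min_fraction
  if (!any(keep)) warning("no features pass the detection filter", call. = FALSE)
  cm[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the per-feature geometric mean,
#' computed over features with nonzero counts in every sample, then rescaled
#' to geometric mean 1.
#'
#' @param cm count matrix.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors_median_ratio <- function(cm) {
  all_pos <- rowSums(cm == 0) == 0
  if (!any(all_pos)) stop("no feature has nonzero counts in every sample", call. = FALSE)
  sub <- cm[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  f <- apply(sub, 2L, function(col) stats::median(col / geo))
  f <- f / geo_mean(f)
  stats::setNames(f, colnames(cm))
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Composition-robust between-sample factors: per sample, a precision-weighted
#' mean of log2 CPM ratios against a reference sample, after trimming 30% of
#' the log-ratios (M) and 5% of the average abundances (A) on each side;
#' factors rescaled to geometric mean 1. The reference is the sample whose
#' CPM upper quartile is closest to the mean upper quartile.
#'
#' @param cm count matrix.
#' @param reference_sample column id or index; `NULL` selects automatically.
#' @return Named positive numeric vector of per-sample factors (to multiply
#'   the raw library sizes).
#' @export
norm_factors_tmm <- function(cm, reference_sample = NULL) {
  lib <- colSums(cm)
  if (any(lib == 0)) stop("degenerate sample with all-zero counts", call. = FALSE)
  cpm <- sweep(cm, 2L, lib, "/") * 1e6
  if (is.null(reference_sample)) {
    uq <- apply(cpm, 2L, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(reference_sample)) match(reference_sample, colnames(cm)) else reference_sample
  }
  f <- vapply(seq_len(ncol(cm)), function(j) {
    tmm_pair_factor(cm[, j], cm[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / geo_mean(f)
  stats::setNames(f, colnames(cm))
}

# Single-sample TMM factor vs a reference (2^ weighted trimmed mean of M).
tmm_pair_factor <- function(y, yr, n, nr, trim_m = 0.3, trim_a = 0.05) {
  keep <- y > 0 & yr > 0
  if (!any(keep)) return(1)
  y <- y[keep]; yr <- yr[keep]
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  if (max(abs(m)) < 1e-6) return(1)
  nk <- length(m)
  lo_m <- floor(nk * trim_m) + 1; hi_m <- nk + 1 - lo_m
  lo_a <- floor(nk * trim_a) + 1; hi_a <- nk + 1 - lo_a
  rm_ <- rank(m, ties.method = "first"); ra <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2) || all(w[keep2] == 0)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

effective_libsize <- function(cm, factors) {
  if (is.null(factors)) factors <- rep(1, ncol(cm))
  colSums(cm) * factors
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective_library + 2 * prior) * 1e6)` with
#' effective library = column sum times the normalization factor.
#'
#' @param cm count matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior prior count (> 0).
#' @return A `transformed_matrix` with id `"logcpm"`.
#' @export
log_cpm <- function(cm, factors = NULL, prior = 0.5) {
  if (prior <= 0) stop("prior count must be > 0", call. = FALSE)
  lib <- effective_libsize(cm, factors)
  if (any(lib <= 0)) stop("zero effective library size", call. = FALSE)
  vals <- log2(sweep(cm + prior, 2L, lib + 2 * prior, "/") * 1e6)
  transformed_matrix(vals, "logcpm",
                     params = list(prior = prior, factors = factors))
}

#' Precision weights from the mean-variance trend of log-CPM
#'
#' Fits a LOWESS curve of per-feature sqrt(residual sd of log-CPM) against
#' average log2 count, then assigns each observation the weight
#' `fitted_sqrt_sd^(-4)` (the inverse variance implied by the trend) at its
#' predicted log-count. Residual sd is computed about group means when
#' `groups` is supplied, otherwise about feature means.
#'
#' @param cm count matrix.
#' @param factors per-sample normalization factors.
#' @param span LOWESS span.
#' @param prior prior count for the underlying log-CPM.
#' @param groups optional group labels for the residual fit.
#' @return A `transformed_matrix` with id `"weighted_logcpm"` carrying
#'   strictly positive weights.
#' @export
precision_weights <- function(cm, factors = NULL, span = 0.5, prior = 0.5,
                              groups = NULL) {
  if (nrow(cm) < 10L) stop("need >= 10 features to fit the mean-variance trend", call. = FALSE)
  tm <- log_cpm(cm, factors, prior)
  y <- tm$values
  n <- ncol(y)
  if (is.null(groups)) groups <- rep("all", n)
  groups <- as.character(groups)
  fitted <- y * 0
  for (g in unique(groups)) {
    idx <- groups == g
    fitted[, idx] <- rowMeans(y[, idx, drop = FALSE])
  }
  df <- n - length(unique(groups))
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  res_sd <- sqrt(rowSums((y - fitted)^2) / df)
  lib <- effective_libsize(cm, factors)
  # average log2 count per feature, and per-observation predicted log2 count
  sx <- rowMeans(y) + mean(log2(lib + 2 * prior)) - log2(1e6)
  sy <- sqrt(res_sd)
  lo <- stats::lowess(sx, sy, f = span)
  lo_x <- unique(lo$x)
  lo_y <- vapply(lo_x, function(v) mean(lo$y[lo$x == v]), numeric(1))
  trend <- if (length(lo_x) < 2L) function(x) rep(lo_y[1L], length(x)) else
    stats::approxfun(lo_x, lo_y, rule = 2)
  pred_logcount <- fitted + matrix(log2(lib + 2 * prior), nrow(y), n, byrow = TRUE) - log2(1e6)
  fit_sqrt_sd <- pmax(trend(pred_logcount), 1e-4)
  w <- matrix(fit_sqrt_sd^(-4), nrow(y), n, dimnames = dimnames(y))
  transformed_matrix(y, "weighted_logcpm", weights = w,
                     params = list(prior = prior, factors = factors, span = span))
}

#' Negative-binomial variance-stabilizing transform
#'
#' `value = (2 / ln 2) * asinh(sqrt(dispersion * cpm))`: monotone in the
#' count, zero at zero, and converging to `log2(cpm) + const` for large
#' normalized counts, with approximately constant variance under
#' `var = mu + dispersion * mu^2`.
#'
#' @param cm count matrix.
#' @param factors per-sample normalization factors.
#' @param dispersion a single trend-level dispersion (> 0), typically the
#'   asymptotic coefficient from [estimate_dispersions()].
#' @return A `transformed_matrix` with id `"vst"`.
#' @export
vst_counts <- function(cm, factors = NULL, dispersion = 0.1) {
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  lib <- effective_libsize(cm, factors)
  if (any(lib <= 0)) stop("zero effective library size", call. = FALSE)
  cpm <- sweep(cm, 2L, lib, "/") * 1e6
  vals <- (2 / log(2)) * asinh(sqrt(dispersion * cpm))
  transformed_matrix(vals, "vst",
                     params = list(dispersion = dispersion, factors = factors))
}

#' Principal component scores of samples
#'
#' Feature-centered SVD of the sample-by-feature matrix.
#'
#' @param tm a `transformed_matrix` (or plain features x samples matrix).
#' @param n_components number of components to return.
#' @return List with `scores` (samples x components), `explained` (variance
#'   fractions, non-increasing, summing to <= 1) and `sdev`.
#' @export
pca_scores <- function(tm, n_components = 2L) {
  x <- if (inherits(tm, "transformed_matrix")) tm$values else tm
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (n_components > min(dim(x))) stop("n_components exceeds min(features, samples)", call. = FALSE)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}
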