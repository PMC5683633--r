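# Nearest-centroid classification with filter-based feature selection and
# three validation protocols (train/test split iterations, LOOCV, multiple
# random validation), reporting misclassification distributions and
# per-feature inclusion rates.

get_values <- function(tm) if (inherits(tm, "transformed_matrix")) tm$values else tm

#' Rank features by a two-sample filter statistic
#'
#' Orders features by decreasing absolute Welch t statistic; exact ties (and
#' degenerate zero-SE features, ranked last) are broken lexicographically by
#' feature id.
#'
#' @param tm features x samples matrix (or `transformed_matrix`).
#' @param labels two-level labels.
#' @param statistic `"t"` (Welch) or `"fc"` (absolute mean difference).
#' @return Character vector of feature ids, best first.
#' @export
rank_features <- function(tm, labels, statistic = c("t", "fc")) {
  statistic <- match.arg(statistic)
  x <- get_values(tm)
  gr <- split_two_groups(labels)
  if (length(gr$idx_ref) < 2L || length(gr$idx_alt) < 2L) {
    stop("each class needs >= 2 samples for ranking", call. = FALSE)
  }
  x1 <- x[, gr$idx_alt, drop = FALSE]; x2 <- x[, gr$idx_ref, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  if (statistic == "fc") {
    stat <- abs(m1 - m2)
  } else {
    v1 <- apply(x1, 1L, stats::var) / ncol(x1)
    v2 <- apply(x2, 1L, stats::var) / ncol(x2)
    se <- sqrt(v1 + v2)
    stat <- ifelse(se > 0, abs(m1 - m2) / se, -Inf)
  }
  ids <- rownames(x)
  ids[order(-stat, ids)]
}

#' Fit a nearest-centroid model
#'
#' Selects the top `n_features` by [rank_features()], standardizes them with
#' training-set means/SDs, and stores the per-class mean vectors (centroids).
#'
#' @param tm training features x samples matrix (or `transformed_matrix`).
#' @param labels training class labels (two classes, each >= 2 samples).
#' @param n_features panel size.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param statistic filter statistic passed to [rank_features()].
#' @return A `centroid_model`.
#' @export
fit_nearest_centroid <- function(tm, labels, n_features,
                                 metric = c("euclidean", "correlation"),
                                 statistic = "t") {
  metric <- match.arg(metric)
  x <- get_values(tm)
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stop("each class needs >= 2 training samples", call. = FALSE)
  if (n_features < 1L || n_features > nrow(x)) {
    stop("n_features must be in 1..nrow", call. = FALSE)
  }
  ranked <- rank_features(x, labels, statistic = statistic)
  feats <- ranked[seq_len(n_features)]
  sub <- x[feats, , drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1L, stats::sd)
  sd_[sd_ == 0] <- 1  # constant feature: centering only
  z <- sweep(sweep(sub, 1L, mu, "-"), 1L, sd_, "/")
  classes <- unique(labels)
  centroids <- vapply(classes, function(cl) {
    rowMeans(z[, labels == cl, drop = FALSE])
  }, numeric(length(feats)))
  centroids <- matrix(centroids, nrow = length(feats),
                      dimnames = list(feats, classes))
  structure(list(features = feats, mean = mu, sd = sd_,
                 centroids = centroids, classes = classes, metric = metric),
            class = "centroid_model")
}

#' Predict with a nearest-centroid model
#'
#' Applies the model's training standardization, then assigns each sample to
#' the class of the nearest centroid. Exact distance ties go to the class
#' listed first and are flagged ambiguous.
#'
#' @param object a `centroid_model`.
#' @param newdata features x samples matrix (or `transformed_matrix`)
#'   containing the model's features.
#' @param ... unused.
#' @return List with `labels`, `distances` (samples x classes) and
#'   `ambiguous`.
#' @export
predict.centroid_model <- function(object, newdata, ...) {
  x <- get_values(newdata)
  missing <- setdiff(object$features, rownames(x))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x[object$features, , drop = FALSE], 1L, object$mean, "-"),
             1L, object$sd, "/")
  k <- length(object$classes)
  d <- matrix(NA_real_, ncol(z), k, dimnames = list(colnames(z), object$classes))
  for (c_i in seq_len(k)) {
    cen <- object$centroids[, c_i]
    d[, c_i] <- if (object$metric == "euclidean") {
      sqrt(colSums((z - cen)^2))
    } else {
      1 - suppressWarnings(stats::cor(z, cen))
    }
  }
  d[is.na(d)] <- Inf
  best <- apply(d, 1L, which.min)  # first index on ties
  ambiguous <- apply(d, 1L, function(r) sum(r == min(r)) > 1L)
  list(labels = object$classes[best], distances = d, ambiguous = ambiguous)
}

new_validation_report <- function(rates, inclusion_counts, n_iter, protocol,
                                  train_fraction = NA_real_, n_features, seed = NA_integer_) {
  structure(list(
    rates = rates,
    summary = c(median = stats::median(rates),
                q25 = unname(stats::quantile(rates, 0.25)),
                q75 = unname(stats::quantile(rates, 0.75))),
    inclusion_counts = inclusion_counts,
    inclusion_rate = inclusion_counts / n_iter,
    protocol = protocol, n_iterations = n_iter,
    train_fraction = train_fraction, seed = seed
  ), class = "validation_report")
}

stratified_split <- function(labels, train_fraction) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(2L, round(length(idx) * train_fraction))
    if (n_tr > length(idx) - 1L) n_tr <- length(idx) - 1L
    if (n_tr < 2L) stop("impossible stratification: class too small", call. = FALSE)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Multiple random validation of the nearest-centroid protocol
#'
#' Repeats: a stratified random split, a full refit (feature ranking,
#' standardization and centroids computed on the training half only), and
#' misclassification on the held-out half. Reports the per-iteration
#' misclassification distribution (median, IQR) and each feature's inclusion
#' rate in the selected panel.
#'
#' @param tm features x samples matrix (or `transformed_matrix`).
#' @param labels two-level labels (each class >= 4 samples).
#' @param n_iter number of random splits.
#' @param train_fraction fraction of each class used for training.
#' @param n_features panel size per fit.
#' @param seed RNG seed (identical seed, identical report).
#' @param stratified keep class proportions in the split (recommended at
#'   these cohort sizes); `FALSE` reproduces fully random subsets.
#' @return A `validation_report`.
#' @export
validate_mrv <- function(tm, labels, n_iter = 1000L, train_fraction = 0.5,
                         n_features, seed = 1L, stratified = TRUE) {
  x <- get_values(tm)
  labels <- as.character(labels)
  if (any(table(labels) < 4L)) stop("each class needs >= 4 samples for MRV", call. = FALSE)
  with_seed(seed, {
    rates <- numeric(n_iter)
    incl <- stats::setNames(integer(nrow(x)), rownames(x))
    n <- ncol(x)
    for (it in seq_len(n_iter)) {
      tr <- if (stratified) {
        stratified_split(labels, train_fraction)
      } else {
        repeat {
          cand <- sort(sample(n, max(4L, round(n * train_fraction))))
          if (all(table(labels[cand]) >= 2L) &&
              length(unique(labels[cand])) == 2L &&
              length(unique(labels[-cand])) >= 1L) break
        }
        cand
      }
      model <- fit_nearest_centroid(x[, tr, drop = FALSE], labels[tr], n_features)
      pred <- predict(model, x[, -tr, drop = FALSE])
      rates[it] <- mean(pred$labels != labels[-tr])
      incl[model$features] <- incl[model$features] + 1L
    }
    new_validation_report(rates, incl, n_iter, "mrv", train_fraction,
                          n_features, seed)
  })
}

#' Leave-one-out cross-validation of the nearest-centroid protocol
#'
#' Full refit per fold; deterministic (no randomness).
#'
#' @inheritParams validate_mrv
#' @return A `validation_report` with a single overall misclassification rate.
#' @export
validate_loocv <- function(tm, labels, n_features) {
  x <- get_values(tm)
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stop("each class needs >= 2 samples", call. = FALSE)
  n <- ncol(x)
  wrong <- logical(n)
  incl <- stats::setNames(integer(nrow(x)), rownames(x))
  for (j in seq_len(n)) {
    if (any(table(labels[-j]) < 2L)) stop("a class would vanish from training", call. = FALSE)
    model <- fit_nearest_centroid(x[, -j, drop = FALSE], labels[-j], n_features)
    pred <- predict(model, x[, j, drop = FALSE])
    wrong[j] <- pred$labels != labels[j]
    incl[model$features] <- incl[model$features] + 1L
  }
  new_validation_report(mean(wrong), incl, n, "loocv", NA_real_, n_features)
}

#' Misclassification rate vs panel size
#'
#' Runs the chosen validation protocol at each panel size and tabulates the
#' median misclassification rate (for external plotting of the plateau).
#'
#' @inheritParams validate_mrv
#' @param panel_sizes integer vector of panel sizes (>= 1).
#' @param protocol `"mrv"` or `"loocv"`.
#' @param ... passed to the protocol function.
#' @return Data frame: `panel_size`, `median_rate`.
#' @export
misclassification_curve <- function(tm, labels, panel_sizes, protocol = c("mrv", "loocv"),
                                    seed = 1L, ...) {
  protocol <- match.arg(protocol)
  if (any(panel_sizes < 1L)) stop("panel sizes must be >= 1", call. = FALSE)
  rates <- vapply(seq_along(panel_sizes), function(k) {
    if (protocol == "mrv") {
      rep_ <- validate_mrv(tm, labels, n_features = panel_sizes[k],
                           seed = stage_seed(seed, paste0("curve", k)), ...)
      unname(rep_$summary["median"])
    } else {
      validate_loocv(tm, labels, n_features = panel_sizes[k])$rates
    }
  }, numeric(1))
  data.frame(panel_size = sort(panel_sizes),
             median_rate = rates[order(panel_sizes)])
}
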