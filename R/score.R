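# Per-feature standardization, the composite up-minus-down biomarker score,
# and Mann-Whitney ROC/AUC for single features and panels.

#' Standardize features on a reference cohort
#'
#' Each feature is centered and scaled using the mean and SD computed on the
#' cohort samples only; the resulting z-scores are applied to ALL samples, so
#' samples outside the cohort are projected with the cohort's parameters.
#' Zero-SD features are dropped with a warning.
#'
#' @param tm a `transformed_matrix` (or plain features x samples matrix).
#' @param cohort_ids sample ids defining the standardization cohort
#'   (default: all samples).
#' @return List with `z` (features x samples) and `params`
#'   (`feature`, `mean`, `sd`, plus the cohort ids as an attribute).
#' @export
standardize_features <- function(tm, cohort_ids = NULL) {
  x <- if (inherits(tm, "transformed_matrix")) tm$values else tm
  cohort_ids <- cohort_ids %||% colnames(x)
  if (length(cohort_ids) < 2L) stop("cohort needs >= 2 samples", call. = FALSE)
  missing <- setdiff(cohort_ids, colnames(x))
  if (length(missing)) stop("cohort sample(s) absent: ", paste(missing, collapse = ", "), call. = FALSE)
  sub <- x[, cohort_ids, drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1L, stats::sd)
  keep <- sd_ > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-SD feature(s) dropped from standardization", call. = FALSE)
  }
  z <- sweep(sweep(x[keep, , drop = FALSE], 1L, mu[keep], "-"), 1L, sd_[keep], "/")
  params <- data.frame(feature = rownames(x)[keep], mean = mu[keep], sd = sd_[keep],
                       stringsAsFactors = FALSE)
  attr(params, "cohort") <- cohort_ids
  list(z = z, params = params)
}

#' Construct a biomarker score panel
#'
#' @param up,down disjoint sets of feature ids; up-regulated features add to
#'   the composite score, down-regulated features subtract.
#' @return A `score_panel` object.
#' @export
score_panel <- function(up = character(0), down = character(0)) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down))) stop("up and down feature sets must be disjoint", call. = FALSE)
  structure(list(up = up, down = down), class = "score_panel")
}

#' Composite biomarker score
#'
#' `score_j = sum over up-features of z_ij - sum over down-features of z_ij`.
#'
#' @param z standardized features x samples matrix (see
#'   [standardize_features()]).
#' @param panel a [score_panel()].
#' @return Named numeric vector of per-sample scores (z-units).
#' @export
composite_score <- function(z, panel) {
  feats <- c(panel$up, panel$down)
  missing <- setdiff(feats, rownames(z))
  if (length(missing)) stop("panel feature(s) absent: ", paste(missing, collapse = ", "), call. = FALSE)
  up_part <- if (length(panel$up)) colSums(z[panel$up, , drop = FALSE]) else 0
  dn_part <- if (length(panel$down)) colSums(z[panel$down, , drop = FALSE]) else 0
  out <- up_part - dn_part
  if (length(out) == 1L && ncol(z) > 1L) out <- rep(out, ncol(z))
  stats::setNames(as.numeric(out), colnames(z))
}

#' Mann-Whitney AUC with two-sided p-value
#'
#' `AUC = P(case value > control value) + 0.5 * P(equal)` via midranks
#' (`U / (n1 * n2)`). The p-value uses the normal approximation with the
#' tie-corrected variance; for <= 12 untied observations the exact Wilcoxon
#' null is used instead.
#'
#' @param values numeric vector.
#' @param labels two-level factor/character vector.
#' @param case_level the level treated as cases (default: the non-control /
#'   second level).
#' @return List with `auc` and `p`.
#' @export
auc_mw <- function(values, labels, case_level = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  case_level <- case_level %||% if ("control" %in% lev) setdiff(lev, "control") else lev[2L]
  is_case <- labels == case_level
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0L || n2 == 0L) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(values)  # midranks
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n2)
  n <- n1 + n2
  ties <- table(values)
  if (n <= 12L && all(ties == 1L)) {
    # exact Wilcoxon null
    p <- stats::pwilcox(min(u, n1 * n2 - u), n1, n2) +
      stats::pwilcox(max(u, n1 * n2 - u) - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, p)
  } else {
    tie_term <- sum(ties^3 - ties)
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v <= 0) return(list(auc = 0.5, p = 1))
    z <- (u - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p = p)
}

#' Per-feature discrimination AUCs
#'
#' Mann-Whitney AUC of every feature for patients vs controls, with BH
#' adjustment across features. Orientation is fixed (patient vs control) so
#' AUC < 0.5 indicates down-regulation.
#'
#' @param tm a `transformed_matrix` (or matrix).
#' @param labels two-level labels per sample.
#' @param case_level see [auc_mw()].
#' @return Data frame: `feature`, `auc`, `pvalue`, `qvalue`.
#' @export
per_feature_auc <- function(tm, labels, case_level = NULL) {
  x <- if (inherits(tm, "transformed_matrix")) tm$values else tm
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    a <- auc_mw(x[i, ], labels, case_level)
    c(a$auc, a$p)
  }, numeric(2)))
  data.frame(feature = rownames(x), auc = res[, 1L], pvalue = res[, 2L],
             qvalue = bh_adjust(res[, 2L]), stringsAsFactors = FALSE)
}

#' Score panels from consensus calls
#'
#' Builds the three composite-score panels: up-regulated only, down-regulated
#' only, and all dysregulated miRNAs (union with signs).
#'
#' @param consensus a consensus table from [consensus_calls()].
#' @return Named list of [score_panel()]s: `up`, `down`, `all`.
#' @export
score_panels_from_consensus <- function(consensus) {
  up <- consensus$feature[consensus$consensus & consensus$direction == "up"]
  down <- consensus$feature[consensus$consensus & consensus$direction == "down"]
  if (!length(up) && !length(down)) {
    warning("no consensus calls; panels are empty", call. = FALSE)
  }
  list(up = score_panel(up = up),
       down = score_panel(down = down),
       all = score_panel(up = up, down = down))
}
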