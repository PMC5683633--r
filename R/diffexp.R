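# Three independent two-group differential-abundance tests on counts
# (negative-binomial Wald, exact conditional negative-binomial, moderated t on
# precision-weighted log-CPM), Benjamini-Hochberg adjustment, and the 2-of-3
# consensus caller.

#' Estimate per-feature NB dispersions with trend shrinkage
#'
#' Method-of-moments dispersions `max(0, (s^2 - mean)/mean^2)` on
#' size-factor-normalized counts pooled within groups, a robust least-squares
#' trend `phi(mu) = a0 + a1/mu`, and shrinkage
#' `phi_shrunk = w * trend + (1 - w) * raw`.
#'
#' @param cm count matrix.
#' @param factors per-sample relative-depth factors (geometric mean 1), e.g.
#'   from [size_factors_median_ratio()].
#' @param groups group label per sample (each group needs >= 2 samples).
#' @param prior_weight shrinkage weight toward the trend.
#' @return A `dispersion_fit` list: `raw`, `trend_coefs`, `shrunk`,
#'   `prior_weight`, `mean`.
#' @export
estimate_dispersions <- function(cm, factors, groups, prior_weight = 0.5) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) stop("each group needs at least 2 samples", call. = FALSE)
  if (nrow(cm) < 20L) stop("need >= 20 features for the trend fit", call. = FALSE)
  norm <- sweep(cm, 2L, factors, "/")
  mu_bar <- rowMeans(norm)
  # pooled within-group residual variance
  ss <- rep(0, nrow(cm))
  for (g in names(tab)) {
    idx <- groups == g
    gm <- rowMeans(norm[, idx, drop = FALSE])
    ss <- ss + rowSums((norm[, idx, drop = FALSE] - gm)^2)
  }
  s2 <- ss / (ncol(cm) - length(tab))
  raw <- ifelse(mu_bar > 0, pmax(0, (s2 - mu_bar) / mu_bar^2), 0)

  ok <- mu_bar > 0
  x <- 1 / mu_bar[ok]; y <- raw[ok]
  fit <- stats::lm(y ~ x)
  r <- stats::residuals(fit)
  inliers <- abs(r) <= 3 * stats::mad(r) + 1e-12
  if (sum(inliers) >= 5) fit <- stats::lm(y[inliers] ~ x[inliers])
  a0 <- max(unname(stats::coef(fit)[1L]), 1e-4)
  a1 <- max(unname(stats::coef(fit)[2L]), 0)
  trend <- a0 + a1 / pmax(mu_bar, 1e-8)
  shrunk <- prior_weight * trend + (1 - prior_weight) * raw
  structure(list(raw = raw, trend_coefs = c(a0 = a0, a1 = a1),
                 shrunk = pmax(shrunk, 0), prior_weight = prior_weight,
                 mean = mu_bar),
            class = "dispersion_fit")
}

# Resolve a two-level comparison: reference (control) first level.
split_two_groups <- function(groups) {
  groups <- as.character(groups)
  lev <- if ("control" %in% groups) {
    c("control", setdiff(unique(groups), "control"))
  } else unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  list(ref = lev[1L], alt = lev[2L],
       idx_ref = which(groups == lev[1L]), idx_alt = which(groups == lev[2L]))
}

de_table <- function(feature, log2fc, pvalue, method, comparison,
                     stat = NA_real_) {
  data.frame(feature = feature, log2fc = log2fc, stat = stat, pvalue = pvalue,
             qvalue = bh_adjust(pvalue), method = method,
             comparison = comparison, stringsAsFactors = FALSE)
}

# Vectorized per-group NB log-mean MLE at fixed dispersion.
# counts: features x samples (one group); s: depth offsets; phi: per feature.
nb_group_mle <- function(counts, s, phi, max_iter = 50L, tol = 1e-10) {
  tot <- rowSums(counts)
  beta <- log(pmax(tot, 0.5) / sum(s))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% s
    denom <- 1 + phi * mu
    score <- rowSums((counts - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% s
  info <- rowSums(mu / (1 + phi * mu))
  list(beta = beta, info = info, all_zero = tot == 0)
}

#' Negative-binomial Wald test
#'
#' Per feature, a log-link NB model with one mean per group is fitted by
#' maximum likelihood at the shrunken dispersion; the Wald statistic for the
#' log fold-change (patient vs control) uses the expected information.
#' All-zero features and non-finite fits get p = 1.
#'
#' @param cm count matrix.
#' @param groups two-level group labels (the `control` level, when present, is
#'   the reference).
#' @param factors per-sample relative-depth factors.
#' @param disp a `dispersion_fit`.
#' @param comparison comparison id recorded in the output.
#' @return A DE table: `feature`, `log2fc`, `pvalue`, `qvalue`, `method`,
#'   `comparison`.
#' @export
de_test_nbwald <- function(cm, groups, factors, disp,
                           comparison = NULL) {
  gr <- split_two_groups(groups)
  comparison <- comparison %||% paste0(gr$alt, "_vs_", gr$ref)
  phi <- pmax(disp$shrunk, 1e-8)
  fit_ref <- nb_group_mle(cm[, gr$idx_ref, drop = FALSE], factors[gr$idx_ref], phi)
  fit_alt <- nb_group_mle(cm[, gr$idx_alt, drop = FALSE], factors[gr$idx_alt], phi)
  delta <- fit_alt$beta - fit_ref$beta
  se <- sqrt(1 / pmax(fit_ref$info, 1e-12) + 1 / pmax(fit_alt$info, 1e-12))
  z <- delta / se
  p <- 2 * stats::pnorm(-abs(z))
  lfc <- delta / log(2)
  degenerate <- fit_ref$all_zero | fit_alt$all_zero | !is.finite(z)
  if (any(degenerate)) {
    # pseudo-count fold-change retained for direction; test is uninformative
    m_ref <- rowMeans(sweep(cm[, gr$idx_ref, drop = FALSE], 2L, factors[gr$idx_ref], "/"))
    m_alt <- rowMeans(sweep(cm[, gr$idx_alt, drop = FALSE], 2L, factors[gr$idx_alt], "/"))
    lfc[degenerate] <- log2((m_alt[degenerate] + 0.5) / (m_ref[degenerate] + 0.5))
    p[degenerate] <- 1
  }
  both_zero <- fit_ref$all_zero & fit_alt$all_zero
  lfc[both_zero] <- 0
  de_table(rownames(cm), lfc, pmin(p, 1), "nbwald", comparison, stat = z)
}

# Two-sided exact conditional NB p for one feature: the group sum, given the
# total, is beta-binomial(T, n1/phi, n2/phi); doubling the smaller tail.
nbexact_pvalue <- function(s1, total, r1, r2, big_total = 2e5) {
  if (total == 0) return(1)
  if (total <= big_total) {
    s <- 0:total
    lp <- lgamma(s + r1) - lgamma(s + 1) + lgamma(total - s + r2) - lgamma(total - s + 1)
    lp <- lp - max(lp)
    pr <- exp(lp); pr <- pr / sum(pr)
    pl <- sum(pr[s <= s1]); pu <- sum(pr[s >= s1])
  } else {
    m <- total * r1 / (r1 + r2)
    v <- total * r1 * r2 * (r1 + r2 + total) / ((r1 + r2)^2 * (r1 + r2 + 1))
    pl <- stats::pnorm(s1 + 0.5, m, sqrt(v))
    pu <- stats::pnorm(s1 - 0.5, m, sqrt(v), lower.tail = FALSE)
  }
  min(1, 2 * min(pl, pu))
}

#' Exact conditional negative-binomial test
#'
#' Counts are scaled to a common effective library size (rounded
#' pseudo-counts); the p-value is the probability, under equal means and
#' conditional on the two group sums' total, of splits at least as extreme as
#' observed. Group sums are NB with size multiplied by group size, so the
#' conditional law is beta-binomial; two-sided by doubling the smaller tail.
#' For very large totals a moment-matched normal tail is used.
#'
#' @inheritParams de_test_nbwald
#' @param factors per-sample normalization factors multiplying library sizes
#'   (e.g. TMM).
#' @param big_total totals above this use the normal tail approximation.
#' @return A DE table (see [de_test_nbwald()]).
#' @export
de_test_nbexact <- function(cm, groups, factors, disp, comparison = NULL,
                            big_total = 2e5) {
  gr <- split_two_groups(groups)
  comparison <- comparison %||% paste0(gr$alt, "_vs_", gr$ref)
  lib <- effective_libsize(cm, factors)
  common <- geo_mean(lib)
  pseudo <- round(sweep(cm, 2L, common / lib, "*"))
  n1 <- length(gr$idx_alt); n2 <- length(gr$idx_ref)
  s_alt <- rowSums(pseudo[, gr$idx_alt, drop = FALSE])
  s_ref <- rowSums(pseudo[, gr$idx_ref, drop = FALSE])
  phi <- pmax(disp$shrunk, 1e-8)
  p <- vapply(seq_len(nrow(cm)), function(i) {
    nbexact_pvalue(s_alt[i], s_alt[i] + s_ref[i],
                   r1 = n1 / phi[i], r2 = n2 / phi[i], big_total = big_total)
  }, numeric(1))
  lfc <- log2((s_alt / n1 + 0.5) / (s_ref / n2 + 0.5))
  lfc[s_alt + s_ref == 0] <- 0
  de_table(rownames(cm), lfc, p, "nbexact", comparison)
}

# Newton inversion of trigamma, for the moderation prior df.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Moderated t-test on precision-weighted log-CPM
#'
#' Per feature, a weighted two-group least-squares fit; residual variances are
#' shrunk toward a common prior estimated by method of moments on the log
#' variances across features, and the moderated t uses `d0 + d` degrees of
#' freedom. With a single feature (or a degenerate moment fit) no moderation
#' is applied and the statistic reduces to the classical pooled t.
#'
#' @param tm a `weighted_logcpm` [transformed_matrix()] (weights required).
#' @param groups two-level group labels.
#' @param comparison comparison id recorded in the output.
#' @return A DE table (see [de_test_nbwald()]).
#' @export
de_test_modt <- function(tm, groups, comparison = NULL) {
  if (!inherits(tm, "transformed_matrix") || is.null(tm$weights)) {
    stop("de_test_modt requires a weighted_logcpm transformed matrix", call. = FALSE)
  }
  gr <- split_two_groups(groups)
  comparison <- comparison %||% paste0(gr$alt, "_vs_", gr$ref)
  y <- tm$values; w <- tm$weights
  n <- ncol(y)
  d <- n - 2L
  if (d < 1L) stop("moderated t needs more than 2 samples", call. = FALSE)
  w1 <- w[, gr$idx_alt, drop = FALSE]; y1 <- y[, gr$idx_alt, drop = FALSE]
  w2 <- w[, gr$idx_ref, drop = FALSE]; y2 <- y[, gr$idx_ref, drop = FALSE]
  sw1 <- rowSums(w1); sw2 <- rowSums(w2)
  m1 <- rowSums(w1 * y1) / sw1
  m2 <- rowSums(w2 * y2) / sw2
  delta <- m1 - m2
  rss <- rowSums(w1 * (y1 - m1)^2) + rowSums(w2 * (y2 - m2)^2)
  s2 <- rss / d
  cc <- 1 / sw1 + 1 / sw2

  d0 <- 0; s02 <- 0
  if (nrow(y) >= 2L) {
    z <- log(pmax(s2, 1e-12))
    e <- z - digamma(d / 2) + log(d / 2)
    ve <- stats::var(e)
    excess <- ve - trigamma(d / 2)
    if (is.finite(excess) && excess > 1e-8) {
      d0 <- 2 * trigamma_inverse(excess)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else if (is.finite(excess)) {
      # log-variances under-dispersed relative to pure chi-square sampling:
      # infinite prior df; the prior value is the geometric mean variance, so
      # identical s2 across features shrink to themselves (no-op)
      d0 <- Inf
      s02 <- exp(mean(z))
    }
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  tstat <- delta / sqrt(s2_mod * cc)
  df_total <- min(d0 + d, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  lfc <- delta  # log2 scale already
  de_table(rownames(y), lfc, p, "modt", comparison, stat = tstat)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to the input
#' order.
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' 2-of-3 consensus differential-abundance calls
#'
#' A method votes for a feature iff its (adjusted) p-value is `<= alpha`; a
#' feature is a consensus call iff at least two methods vote with the same
#' fold-change sign. Mixed-sign vote sets are flagged discordant and excluded.
#'
#' @param tables list of three DE tables over identical feature sets.
#' @param alpha significance cutoff.
#' @param use_adjusted vote on `qvalue` (default) or raw `pvalue`.
#' @return Data frame: `feature`, `n_significant`, `direction` (`up`, `down`,
#'   `discordant`, `none`), `consensus`, `mean_log2fc`.
#' @export
consensus_calls <- function(tables, alpha = 0.05, use_adjusted = TRUE) {
  if (length(tables) != 3L) stop("exactly three DE tables expected", call. = FALSE)
  feats <- tables[[1L]]$feature
  for (t in tables[-1L]) {
    if (!identical(sort(t$feature), sort(feats))) {
      stop("DE tables cover different feature sets", call. = FALSE)
    }
  }
  tabs <- lapply(tables, function(t) t[match(feats, t$feature), ])
  pmat <- sapply(tabs, function(t) if (use_adjusted) t$qvalue else t$pvalue)
  fmat <- sapply(tabs, function(t) t$log2fc)
  votes <- pmat <= alpha
  n_sig <- rowSums(votes)
  direction <- character(length(feats))
  consensus <- logical(length(feats))
  for (i in seq_along(feats)) {
    if (n_sig[i] < 2L) {
      direction[i] <- "none"
    } else {
      signs <- sign(fmat[i, votes[i, ]])
      if (all(signs > 0)) {
        direction[i] <- "up"; consensus[i] <- TRUE
      } else if (all(signs < 0)) {
        direction[i] <- "down"; consensus[i] <- TRUE
      } else {
        direction[i] <- "discordant"
      }
    }
  }
  data.frame(feature = feats, n_significant = n_sig, direction = direction,
             consensus = consensus, mean_log2fc = rowMeans(fmat),
             stringsAsFactors = FALSE)
}
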