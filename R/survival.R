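# Rank-based survival screen for miRNA-mortality association with a
# permutation null and Q-Q expected scores, Cox proportional-hazards models on
# median-dichotomized levels, and Kaplan-Meier curves.

#' Depth-standardized averaged ranks
#'
#' Equalizes sequencing depth before rank-transforming: in each of
#' `n_resamples` rounds every sample's counts are binomially thinned to the
#' minimum library depth, each feature's values are midrank-transformed across
#' samples, and the ranks are averaged over rounds.
#'
#' @param cm count matrix (patients only, typically).
#' @param n_resamples number of thinning rounds.
#' @param seed RNG seed.
#' @return Real matrix (features x samples) of averaged ranks.
#' @export
depth_standardized_ranks <- function(cm, n_resamples = 20L, seed = 1L) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  depth <- colSums(cm)
  if (any(depth == 0)) stop("zero-depth sample", call. = FALSE)
  pthin <- min(depth) / depth
  with_seed(seed, {
    acc <- matrix(0, nrow(cm), ncol(cm), dimnames = dimnames(cm))
    for (r in seq_len(n_resamples)) {
      thinned <- cm
      for (j in which(pthin < 1)) {
        thinned[, j] <- stats::rbinom(nrow(cm), cm[, j], pthin[j])
      }
      acc <- acc + t(apply(thinned, 1L, rank))  # midranks for ties
    }
    acc / n_resamples
  })
}

#' Cox score screen of all features
#'
#' Per feature, the Cox partial-likelihood score statistic at beta = 0 on the
#' supplied values (typically averaged ranks): the log-rank-type sum over
#' event times of (failing value - risk-set mean), normalized by the square
#' root of the hypergeometric variance. Ties are handled Breslow-style (all
#' deaths at a time share the risk set). Positive scores mean higher level,
#' higher hazard.
#'
#' @param ranks features x samples real matrix.
#' @param time,event right-censored outcome per sample.
#' @return Named numeric vector of per-feature scores.
#' @export
cox_score_screen <- function(ranks, time, event) {
  if (sum(event) < 1) stop("no events", call. = FALSE)
  nf <- nrow(ranks)
  u <- numeric(nf); v <- numeric(nf)
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    nr <- sum(at_risk)
    fails <- which(time == t0 & event == 1)
    d <- length(fails)
    xr <- ranks[, at_risk, drop = FALSE]
    xbar <- rowMeans(xr)
    xf <- ranks[, fails, drop = FALSE]
    u <- u + rowSums(xf) - d * xbar
    if (nr > 1L) {
      varx <- rowSums((xr - xbar)^2) / nr
      v <- v + d * varx * (nr - d) / (nr - 1L)
    }
  }
  score <- ifelse(v > 0, u / sqrt(v), 0)
  stats::setNames(score, rownames(ranks))
}

#' Permutation null for the survival screen
#'
#' Permutes the (time, event) pairs jointly across samples `n_perm` times and
#' recomputes all feature scores. Expected score at rank position k is the
#' mean k-th order statistic across permutations; the q-value at threshold
#' |t| is the median permuted exceedance count over the observed exceedance
#' count, capped at 1 and monotonized in |score|.
#'
#' @param ranks features x samples real matrix.
#' @param time,event outcome per sample.
#' @param n_perm number of permutations (>= 20).
#' @param seed RNG seed.
#' @return List: `table` (`feature`, `score`, `qvalue`), `qq`
#'   (`expected`, `observed`, `feature`, sorted ascending), `n_perm`, `seed`.
#' @export
permutation_null <- function(ranks, time, event, n_perm = 100L, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be >= 20", call. = FALSE)
  obs <- cox_score_screen(ranks, time, event)
  nf <- length(obs)
  n <- length(time)
  with_seed(seed, {
    perm_scores <- matrix(NA_real_, n_perm, nf)
    for (b in seq_len(n_perm)) {
      idx <- sample(n)
      perm_scores[b, ] <- cox_score_screen(ranks, time[idx], event[idx])
    }
    sorted_perm <- t(apply(perm_scores, 1L, sort))
    expected <- colMeans(sorted_perm)

    ord <- order(-abs(obs))
    thr <- abs(obs)[ord]
    perm_abs <- abs(perm_scores)
    q <- vapply(seq_len(nf), function(k) {
      exceed <- vapply(seq_len(n_perm), function(b) sum(perm_abs[b, ] >= thr[k]),
                       numeric(1))
      min(1, stats::median(exceed) / k)
    }, numeric(1))
    q <- cummax(q)  # monotone: larger |score| never has larger q
    qvalue <- numeric(nf)
    qvalue[ord] <- q

    oo <- order(obs)
    qq <- data.frame(expected = expected, observed = obs[oo],
                     feature = names(obs)[oo], stringsAsFactors = FALSE)
    list(table = data.frame(feature = names(obs), score = unname(obs),
                            qvalue = qvalue, stringsAsFactors = FALSE),
         qq = qq, n_perm = n_perm, seed = seed)
  })
}

#' Dichotomize at the median
#'
#' 1 iff strictly above the median; ties at the median go to the low group.
#'
#' @param values numeric vector (>= 2 values).
#' @return Integer 0/1 vector.
#' @export
dichotomize_median <- function(values) {
  if (length(values) < 2L) stop("need >= 2 samples", call. = FALSE)
  as.integer(values > stats::median(values))
}

#' Cox proportional-hazards fit for a binary predictor
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow tie
#' handling (tolerance 1e-8 on beta, max 50 iterations). With a monotone
#' likelihood (all events in one level) the hazard ratio is reported as
#' infinite (or zero) with the score-test p-value and a flag.
#'
#' @param x binary 0/1 predictor (both levels present).
#' @param time,event right-censored outcome.
#' @return A `cox_result` list: `hr`, `log_hr`, `se`, `pvalue`, `n_events`,
#'   `monotone` flag, `predictor`.
#' @export
cox_fit_binary <- function(x, time, event) {
  if (length(unique(x)) != 2L) stop("both predictor levels must be present", call. = FALSE)
  if (sum(event) < 1) stop("at least one event required", call. = FALSE)
  x <- as.numeric(x)

  deriv <- function(beta) {
    # Breslow partial likelihood derivatives for a scalar covariate
    u <- 0; i2 <- 0
    for (t0 in sort(unique(time[event == 1]))) {
      at_risk <- time >= t0
      fails <- which(time == t0 & event == 1)
      d <- length(fails)
      w <- exp(beta * x[at_risk])
      s0 <- sum(w); s1 <- sum(w * x[at_risk]); s2 <- sum(w * x[at_risk]^2)
      u <- u + sum(x[fails]) - d * s1 / s0
      i2 <- i2 + d * (s2 / s0 - (s1 / s0)^2)
    }
    c(u, i2)
  }

  events_high <- sum(event[x == 1]); events_low <- sum(event[x == 0])
  monotone <- events_high == 0 || events_low == 0
  d0 <- deriv(0)
  score_p <- if (d0[2L] > 0) 2 * stats::pnorm(-abs(d0[1L] / sqrt(d0[2L]))) else 1
  if (monotone) {
    hr <- if (events_high == 0) 0 else Inf
    return(structure(list(hr = hr, log_hr = log(hr), se = NA_real_,
                          pvalue = score_p, n_events = sum(event),
                          monotone = TRUE, predictor = "above median"),
                     class = "cox_result"))
  }
  beta <- 0
  for (it in 1:50) {
    dd <- deriv(beta)
    if (dd[2L] <= 0) break
    step <- dd[1L] / dd[2L]
    beta <- beta + step
    if (abs(step) < 1e-8) break
    if (abs(beta) > 15) {  # effectively monotone
      return(structure(list(hr = if (beta > 0) Inf else 0, log_hr = beta,
                            se = NA_real_, pvalue = score_p,
                            n_events = sum(event), monotone = TRUE,
                            predictor = "above median"),
                       class = "cox_result"))
    }
  }
  info <- deriv(beta)[2L]
  se <- 1 / sqrt(info)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(hr = exp(beta), log_hr = beta, se = se, pvalue = p,
                 n_events = sum(event), monotone = FALSE,
                 predictor = "above median"),
            class = "cox_result")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood variance and log-transformed 95%
#' confidence intervals (upper bound capped at 1).
#'
#' @param time,event right-censored outcome (times > 0).
#' @return Data frame: `time` (distinct event times), `n_risk`, `n_event`,
#'   `surv`, `var`, `lower`, `upper`.
#' @export
km_curve <- function(time, event) {
  if (any(time < 0)) stop("negative times", call. = FALSE)
  if (length(time) < 1L) stop("need >= 1 subject", call. = FALSE)
  etimes <- sort(unique(time[event == 1]))
  s <- 1
  gw <- 0  # cumulative Greenwood sum d/(n(n-d))
  out <- data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                    surv = numeric(0), var = numeric(0),
                    lower = numeric(0), upper = numeric(0))
  for (t0 in etimes) {
    n_r <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    s <- s * (1 - d / n_r)
    if (n_r > d) gw <- gw + d / (n_r * (n_r - d)) else gw <- Inf
    v <- s^2 * gw
    if (s > 0 && is.finite(gw)) {
      half <- stats::qnorm(0.975) * sqrt(gw)
      lower <- s * exp(-half)
      upper <- min(1, s * exp(half))
    } else {
      lower <- s; upper <- s
    }
    out <- rbind(out, data.frame(time = t0, n_risk = n_r, n_event = d,
                                 surv = s, var = ifelse(is.finite(v), v, NA_real_),
                                 lower = lower, upper = upper))
  }
  out
}
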