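# Dispersion estimation, the three DE tests, BH, consensus calls.

test_that("dispersion estimation: Poisson limit and NB consistency", {
  # Poisson counts: shrunken dispersions collapse toward zero
  set.seed(51)
  cm <- count_matrix(matrix(rpois(2000 * 40, 200), 2000, 40),
                     feature_ids = paste0("f", 1:2000),
                     sample_ids = paste0("s", 1:40))
  g <- rep(c("control", "DLBCL"), each = 20)
  sf <- setNames(rep(1, 40), colnames(cm))
  d <- estimate_dispersions(cm, sf, g)
  expect_lt(median(d$shrunk), 0.05)

  # NB at phi = 0.4
  set.seed(52)
  cm2 <- count_matrix(matrix(rnbinom(2000 * 40, mu = 200, size = 1 / 0.4), 2000, 40),
                      feature_ids = paste0("f", 1:2000),
                      sample_ids = paste0("s", 1:40))
  d2 <- estimate_dispersions(cm2, sf, g)
  expect_gt(median(d2$shrunk), 0.3)
  expect_lt(median(d2$shrunk), 0.5)

  # constant feature has raw dispersion 0
  cm3 <- cm2
  cm3[1, ] <- 100L
  d3 <- estimate_dispersions(count_matrix(cm3), sf, g)
  expect_equal(unname(d3$raw[1]), 0)
  expect_error(estimate_dispersions(cm[, 1:3], sf[1:3], c("a", "a", "b")),
               "at least 2 samples")
})

test_that("NB Wald: exact zero log2FC under duplicated groups, consistency", {
  set.seed(61)
  y <- matrix(rnbinom(30 * 10, mu = 100, size = 5), 30, 10)
  cm <- count_matrix(cbind(y, y),
                     feature_ids = paste0("f", 1:30),
                     sample_ids = paste0("s", 1:20))
  g <- rep(c("control", "DLBCL"), each = 10)
  sf <- setNames(rep(1, 20), colnames(cm))
  tab <- de_test_nbwald(cm, g, sf, fixed_disp(30, 0.1))
  expect_equal(tab$log2fc, rep(0, 30), tolerance = 1e-8)

  # estimator consistency: mu ratio 4 => log2FC near 2
  lfcs <- replicate(100, {
    c1 <- matrix(rnbinom(20, mu = 100, size = 10), 1)
    c2 <- matrix(rnbinom(14, mu = 400, size = 10), 1)
    m <- count_matrix(cbind(c1, c2), feature_ids = "f1",
                      sample_ids = paste0("s", 1:34))
    de_test_nbwald(m, rep(c("control", "DLBCL"), c(20, 14)),
                   setNames(rep(1, 34), colnames(m)), fixed_disp(1, 0.1))$log2fc
  })
  expect_lt(abs(median(lfcs) - 2), 0.3)
})

test_that("label swap negates log2FC and preserves p for all three tests", {
  sim <- simulate_cohort(quick_config(seed = 63L, n_features = 60L,
                                      group_sizes = c(control = 8L, DLBCL = 7L),
                                      de_spec = inject_spec(n_up = 3L, n_down = 3L)))
  cm <- filter_detected(sim$counts)
  g <- as.character(sim$samples$group)
  g_swap <- ifelse(g == "control", "DLBCL", "control")
  sf <- size_factors_median_ratio(cm)
  disp <- fixed_disp(nrow(cm), 0.2)

  a <- de_test_nbwald(cm, g, sf, disp, "fwd")
  b <- de_test_nbwald(cm, g_swap, sf, disp, "rev")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-6)

  tmm <- norm_factors_tmm(cm)
  a <- de_test_nbexact(cm, g, tmm, disp, "fwd")
  b <- de_test_nbexact(cm, g_swap, tmm, disp, "rev")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)

  tw <- precision_weights(cm, tmm, groups = g)
  a <- de_test_modt(tw, g, "fwd")
  b <- de_test_modt(tw, g_swap, "rev")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
})

test_that("exact NB test: balanced split, enumeration oracle, binomial limit", {
  # perfectly balanced split with equal group sizes -> p = 1
  cm <- count_matrix(matrix(c(5L, 7L, 5L, 7L), 2, 2),
                     feature_ids = c("a", "b"), sample_ids = c("s1", "s2"))
  tab <- de_test_nbexact(cm, c("control", "DLBCL"), setNames(c(1, 1), c("s1", "s2")),
                         fixed_disp(2, 0.3))
  expect_equal(tab$pvalue, c(1, 1))

  # exhaustive-enumeration oracle via explicit NB convolution (totals <= 50)
  phi <- 0.25
  n1 <- 3L; n2 <- 4L  # patient, control
  conv_pmf <- function(n, mu, upper) {
    pmf <- dnbinom(0:upper, mu = mu, size = 1 / phi)
    out <- pmf
    for (i in seq_len(n - 1L)) {
      full <- convolve(out, rev(pmf), type = "open")
      out <- full[1:(upper + 1L)]
    }
    out
  }
  set.seed(71)
  for (rep in 1:5) {
    y1 <- rpois(n1, 4) + 1L; y2 <- rpois(n2, 4) + 1L
    s1 <- sum(y1); tot <- s1 + sum(y2)
    p1 <- conv_pmf(n1, mu = 3, upper = tot)
    p2 <- conv_pmf(n2, mu = 3, upper = tot)
    joint <- p1 * rev(p2)
    joint <- joint / sum(joint)
    pl <- sum(joint[seq_len(s1 + 1L)])
    pu <- sum(joint[(s1 + 1L):(tot + 1L)])
    oracle <- min(1, 2 * min(pl, pu))
    cmx <- count_matrix(matrix(c(y2, y1), 1),
                        feature_ids = "f",
                        sample_ids = paste0("s", 1:(n1 + n2)))
    g <- rep(c("control", "DLBCL"), c(n2, n1))
    # factors equalize effective libraries so pseudo-counts are the raw counts
    got <- de_test_nbexact(cmx, g, setNames(1 / colSums(cmx), colnames(cmx)),
                           fixed_disp(1, phi))$pvalue
    expect_equal(got, oracle, tolerance = 1e-8)
  }

  # Poisson limit: phi -> 0 reduces to the exact binomial split test
  set.seed(72)
  for (rep in 1:5) {
    y1 <- rpois(2, 20) + 1L; y2 <- rpois(3, 20) + 1L
    s1 <- sum(y1); tot <- s1 + sum(y2)
    if (tot > 200) next
    pr <- 2 / 5
    pl <- pbinom(s1, tot, pr)
    pu <- 1 - pbinom(s1 - 1, tot, pr)
    oracle <- min(1, 2 * min(pl, pu))
    cmx <- count_matrix(matrix(c(y2, y1), 1), feature_ids = "f",
                        sample_ids = paste0("s", 1:5))
    g <- rep(c("control", "DLBCL"), c(3, 2))
    got <- de_test_nbexact(cmx, g, setNames(1 / colSums(cmx), colnames(cmx)),
                           fixed_disp(1, 1e-8))$pvalue
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("moderated t: no-op at common variance, classical-t oracle, null", {
  # all residual variances identical -> moderation is a no-op
  set.seed(81)
  base <- matrix(rnorm(12), 1, 12)
  y <- rbind(base, base + 1, base - 2, base * 1)  # identical residual patterns
  rownames(y) <- paste0("f", 1:4); colnames(y) <- paste0("s", 1:12)
  tm <- transformed_matrix(y, "weighted_logcpm", weights = y * 0 + 1)
  g <- rep(c("control", "DLBCL"), each = 6)
  tab <- de_test_modt(tm, g)
  # identical variances: t must equal the classical pooled t of each feature
  classic_t <- function(v) {
    x1 <- v[7:12]; x2 <- v[1:6]
    sp <- sqrt(((5) * var(x1) + (5) * var(x2)) / 10)
    (mean(x1) - mean(x2)) / (sp * sqrt(1 / 6 + 1 / 6))
  }
  for (i in 1:4) {
    # statistic unchanged by moderation (s2_mod == s2); the prior df widen
    # only the reference distribution
    expect_equal(tab$stat[i], classic_t(y[i, ]), tolerance = 1e-8)
  }

  # single feature, equal weights -> classical pooled two-sample t (d0 = 0)
  set.seed(82)
  v <- rnorm(12)
  one <- matrix(v, 1, dimnames = list("f1", paste0("s", 1:12)))
  tm1 <- transformed_matrix(one, "weighted_logcpm", weights = one * 0 + 1)
  tab1 <- de_test_modt(tm1, g)
  expect_equal(tab1$pvalue, 2 * pt(-abs(classic_t(v)), df = 10), tolerance = 1e-10)

  # null Gaussian calibration: KS distance of p-values small
  ks <- replicate(50, {
    yy <- matrix(rnorm(159 * 12), 159, 12,
                 dimnames = list(paste0("f", 1:159), paste0("s", 1:12)))
    tmx <- transformed_matrix(yy, "weighted_logcpm", weights = yy * 0 + 1)
    p <- de_test_modt(tmx, g)$pvalue
    suppressWarnings(ks.test(p, "punif")$statistic)
  })
  expect_lt(median(ks), 0.1)
})

test_that("BH adjustment: hand-computed step-up and properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(91)
  for (i in 1:10) {
    p <- runif(20)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_equal(q, p.adjust(p, "BH"))  # independent reference
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("consensus rules: votes, direction, discordance, order invariance", {
  mk <- function(q, lfc, method) {
    data.frame(feature = c("a", "b"), log2fc = lfc, pvalue = q, qvalue = q,
               method = method, comparison = "x", stringsAsFactors = FALSE)
  }
  # feature a: q = (.01, .04, .8), lfc all positive -> consensus up
  # feature b: q = (.01, .01, .9), lfc mixed signs -> discordant
  t1 <- mk(c(0.01, 0.01), c(1.2, 1.0), "nbwald")
  t2 <- mk(c(0.04, 0.01), c(0.9, -1.0), "nbexact")
  t3 <- mk(c(0.80, 0.90), c(0.1, 0.0), "modt")
  cc <- consensus_calls(list(t1, t2, t3))
  expect_identical(cc$direction, c("up", "discordant"))
  expect_identical(cc$consensus, c(TRUE, FALSE))
  expect_identical(cc$n_significant, c(2, 2))

  # invariant to table order
  cc2 <- consensus_calls(list(t3, t1, t2))
  expect_identical(cc$direction, cc2$direction)
  expect_identical(cc$consensus, cc2$consensus)
  expect_error(consensus_calls(list(t1, t2)), "three")
})
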