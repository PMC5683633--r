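# Detection filter, normalization factors, the three transforms, PCA.

test_that("detection filter applies the inclusive >= rule and is idempotent", {
  m <- count_matrix(rbind(one = c(5L, 0L, 0L, 0L),   # 1/4 = 0.25, retained
                          none = c(0L, 0L, 0L, 0L),  # removed
                          all = c(1L, 1L, 1L, 1L)),
                    sample_ids = paste0("s", 1:4))
  f <- filter_detected(m)
  expect_identical(rownames(f), c("one", "all"))
  expect_identical(filter_detected(f), f)
  expect_warning(filter_detected(m[2, , drop = FALSE]), "no features")
  expect_error(filter_detected(m, min_fraction = 0), "min_fraction")
})

test_that("median-ratio size factors: proportional and identical columns", {
  cm <- toy_counts(nf = 40L, ns = 1L, seed = 5L, lambda = 200)
  two <- cbind(cm[, 1], 2L * cm[, 1])
  colnames(two) <- c("a", "b")
  f <- size_factors_median_ratio(count_matrix(two))
  expect_equal(unname(f[["b"]] / f[["a"]]), 2)
  same <- count_matrix(cbind(a = cm[, 1], b = cm[, 1], c = cm[, 1]))
  expect_equal(unname(size_factors_median_ratio(same)), rep(1, 3))
})

test_that("median-ratio factors match a brute-force computation", {
  set.seed(71)
  cm <- count_matrix(matrix(rnbinom(300, mu = 80, size = 5) + 1L, 50, 6),
                     feature_ids = paste0("f", 1:50), sample_ids = paste0("s", 1:6))
  f <- size_factors_median_ratio(cm)
  # independent loop-based median-of-ratios
  geo <- apply(cm, 1, function(r) prod(r)^(1 / length(r)))
  raw <- sapply(1:6, function(j) median(cm[, j] / geo))
  raw <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), raw, tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # invariant to feature order
  f2 <- size_factors_median_ratio(cm[sample(1:50), ])
  expect_equal(f, f2)
})

test_that("TMM factors: identity, composition invariance, brute-force oracle", {
  set.seed(81)
  base <- rnbinom(200, mu = 150, size = 10) + 1L
  same <- count_matrix(cbind(a = base, b = base, c = base),
                       feature_ids = paste0("f", 1:200))
  expect_equal(unname(norm_factors_tmm(same)), rep(1, 3), tolerance = 1e-9)

  scaled <- count_matrix(cbind(a = base, b = 3L * base),
                         feature_ids = paste0("f", 1:200))
  f <- norm_factors_tmm(scaled)
  expect_equal(unname(f[["b"]] / f[["a"]]), 1, tolerance = 0.02)

  cm <- count_matrix(matrix(rnbinom(200 * 4, mu = 100, size = 3) + 1L, 200, 4),
                     feature_ids = paste0("f", 1:200), sample_ids = paste0("s", 1:4))
  f <- norm_factors_tmm(cm)
  # independent reimplementation of the same trim/weight rule
  lib <- colSums(cm)
  uq <- apply(sweep(cm, 2, lib, "/") * 1e6, 2, quantile, 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  brute <- sapply(1:4, function(j) {
    y <- cm[, j]; yr <- cm[, ref]
    keep <- y > 0 & yr > 0
    m <- log2((y[keep] / lib[j]) / (yr[keep] / lib[ref]))
    a <- 0.5 * log2((y[keep] / lib[j]) * (yr[keep] / lib[ref]))
    w <- (lib[j] - y[keep]) / (lib[j] * y[keep]) +
      (lib[ref] - yr[keep]) / (lib[ref] * yr[keep])
    nk <- length(m)
    keep2 <- rank(m, ties.method = "first") >= floor(nk * 0.3) + 1 &
      rank(m, ties.method = "first") <= nk - floor(nk * 0.3) &
      rank(a, ties.method = "first") >= floor(nk * 0.05) + 1 &
      rank(a, ties.method = "first") <= nk - floor(nk * 0.05)
    if (max(abs(m)) < 1e-6) return(1)
    2^(sum((m / w)[keep2]) / sum((1 / w)[keep2]))
  })
  brute <- brute / exp(mean(log(brute)))
  expect_equal(unname(f), unname(brute), tolerance = 1e-10)
})

test_that("log-CPM closed form, scale invariance and monotonicity", {
  m <- count_matrix(matrix(as.integer(c(0, 1e6)), 2, 1),
                    feature_ids = c("z", "big"), sample_ids = "s1")
  v <- log_cpm(m, prior = 0.5)$values
  expect_equal(v["z", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  set.seed(5)
  cm <- count_matrix(matrix(rpois(100, 500) + 100L, 20, 5),
                     feature_ids = paste0("f", 1:20), sample_ids = paste0("s", 1:5))
  v1 <- log_cpm(cm)$values
  v2 <- log_cpm(count_matrix(2L * cm))$values
  expect_lt(max(abs(v1 - v2)), 0.01)

  # strictly monotone in the count at fixed effective library size
  fixed_lib <- rep(1e6 / colSums(cm)[1], 5)
  up <- cm; up[1, 1] <- up[1, 1] + 10L
  expect_gt(log_cpm(count_matrix(up), factors = 1e6 / colSums(up))$values[1, 1],
            log_cpm(cm, factors = 1e6 / colSums(cm))$values[1, 1])
})

test_that("precision weights: flat trend under homoskedastic values", {
  set.seed(31)
  nf <- 60; ns <- 12
  mu <- seq(6, 14, length.out = nf)  # log2 abundance range
  vals <- t(sapply(mu, function(m) 2^(m + rnorm(ns, 0, 0.3))))
  cm <- count_matrix(matrix(as.integer(round(vals)), nf, ns),
                     feature_ids = paste0("f", 1:nf), sample_ids = paste0("s", 1:ns))
  tm <- precision_weights(cm)
  expect_true(all(is.finite(tm$weights)) && all(tm$weights > 0))
  expect_lt(max(tm$weights) / min(tm$weights), 2)
})

test_that("precision weights increase with abundance on NB counts", {
  sim <- simulate_cohort(quick_config(seed = 17L, sdlog_abund = 2))
  cm <- filter_detected(sim$counts)
  tm <- precision_weights(cm, groups = as.character(sim$samples$group))
  rho <- cor(rowMeans(tm$weights), rowMeans(cm), method = "spearman")
  expect_gt(rho, 0.5)
  expect_true(all(tm$weights > 0))
})

test_that("vst: zero maps to zero, log2 asymptote, variance stabilization", {
  m <- count_matrix(matrix(c(0L, 999L), 2, 1), feature_ids = c("z", "o"),
                    sample_ids = "s")
  expect_equal(vst_counts(m, dispersion = 0.1)$values["z", 1], 0)

  # large-x limit: cpm 1e6 vs 1e5 differ by ~log2(10)
  phi <- 0.1
  g <- function(x) (2 / log(2)) * asinh(sqrt(phi * x))
  expect_lt(abs((g(1e6) - g(1e5)) - log2(10)) / log2(10), 0.02)

  # NB draws on a mu grid; factors chosen so cpm == count
  set.seed(9)
  grid <- 10^(2:5)
  rows <- lapply(grid, function(mu) as.integer(rnbinom(400, mu = mu, size = 1 / phi)))
  cm <- count_matrix(do.call(rbind, rows), feature_ids = paste0("g", grid),
                     sample_ids = paste0("s", 1:400))
  factors <- 1e6 / colSums(cm)
  tv <- vst_counts(cm, factors, dispersion = phi)$values
  sds <- apply(tv, 1, sd)
  expect_lt(max(sds) / min(sds), 2)
  expect_error(vst_counts(cm, dispersion = 0), "dispersion")
})

test_that("PCA separates constructed clusters and matches eigendecomposition", {
  set.seed(12)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  x[1, 1:4] <- x[1, 1:4] + 10  # offset along one feature axis
  pc <- pca_scores(x, 2)
  expect_true(min(pc$scores[1:4, 1]) > max(pc$scores[5:8, 1]) ||
                max(pc$scores[1:4, 1]) < min(pc$scores[5:8, 1]))

  full <- pca_scores(x, 8)
  expect_true(all(diff(full$explained) <= 1e-12))
  expect_lte(sum(full$explained), 1 + 1e-12)

  # eigendecomposition oracle (up to sign)
  xc <- t(scale(t(x), center = TRUE, scale = FALSE))
  ev <- eigen(stats::cov(t(xc)))
  oracle <- t(xc) %*% ev$vectors[, 1:2]
  for (k in 1:2) {
    expect_true(isTRUE(all.equal(abs(pc$scores[, k]), abs(oracle[, k]),
                                 tolerance = 1e-8, check.attributes = FALSE)))
  }
  expect_error(pca_scores(x, 0), "n_components")
})
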