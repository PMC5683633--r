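# Synthetic plasma miRNA-seq cohort generator with known ground truth.
#
# The generator emulates the structure of a small lymphoma-surveillance study:
# ~159 detected miRNAs, cohorts of 20 controls / 14 DLBCL / 11 HL patients, a
# heavily skewed plasma abundance profile (a few erythrocyte-derived species
# such as miR-451/miR-486 dominate), log-normal library sizes, NB
# overdispersion with a mean-dispersion trend, group-specific fold-changes in
# both directions, and exponential survival with hazard linked to selected
# miRNA levels.

default_de_spec <- function() {
  # Direction counts mirror the discovery cohort: DLBCL 2 up / 8 down,
  # HL 8 up / 4 down. Feature indices refer to abundance rank (1 = most
  # abundant); effects sit in the mid-abundance range where real dysregulated
  # plasma miRNAs live.
  list(
    DLBCL = data.frame(
      feature = c(30L, 35L, 40L, 42L, 44L, 46L, 48L, 50L, 52L, 54L),
      log2fc  = c(1.8, 1.5, -1.6, -1.4, -2.0, -1.3, -1.8, -1.5, -1.2, -1.7)),
    HL = data.frame(
      feature = c(31L, 33L, 36L, 38L, 41L, 43L, 45L, 47L, 49L, 51L, 53L, 55L),
      log2fc  = c(2.0, 1.6, 1.4, 1.9, 1.3, 1.5, 1.2, 1.7, -1.8, -1.5, -1.3, -2.0))
  )
}

default_surv_spec <- function() {
  # Two hazard-increasing and one protective miRNA. The latent-frailty link
  # multiplies the marginal hazard by ~exp(sum(coefs^2)/2) ~ 2.1, so a 0.03/yr
  # baseline yields ~25% five-year mortality (about 6 deaths in 25 patients);
  # follow-up horizon 5.3 years with light (10%) random censoring matches a
  # 0.9-5.3 year follow-up window.
  list(features = c(32L, 34L, 56L), coefs = c(0.8, 0.7, -0.6),
       baseline = 0.03, censoring = 0.1, horizon = 5.3, latent_sd = 0.8)
}

#' Configuration for the synthetic plasma miRNA cohort generator
#'
#' Defaults encode the emulated study design: 159 detected miRNAs; 20
#' controls, 14 DLBCL and 11 HL patients; log-normal relative abundances with
#' sdlog 2.5 (so the top-10 species carry most reads, as in plasma); library
#' sizes log-normal around 10^6 reads; dispersion trend
#' `phi(mu) = a0 + a1/mu`; group-specific fold-changes in both directions;
#' exponential survival linked to selected miRNAs.
#'
#' @param n_features number of simulated miRNAs.
#' @param group_sizes named integer vector over `control`, `DLBCL`, `HL`.
#' @param baseline_logmean_params `c(meanlog, sdlog)` of log-normal relative
#'   abundances (sorted decreasing, so feature 1 is the most abundant).
#' @param libsize_params `c(meanlog, sdlog)` of log-normal library sizes.
#' @param dispersion_trend `c(a0, a1)` of `phi(mu) = a0 + a1/mu`.
#' @param de_spec named list (per patient group) of data.frames with columns
#'   `feature` (index) and `log2fc`; both signs should be represented.
#' @param surv_spec list with `features`, `coefs` (log-hazard per SD of latent
#'   log abundance), `baseline` (events/year), `censoring` rate in `[0,1)`,
#'   `horizon` (years), `latent_sd` (per-sample log-normal jitter, natural
#'   log scale, applied to survival-linked features).
#' @param batch_offset optional additive log2 offset applied to a random half
#'   of the samples (single batch-effect knob; 0 disables).
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = 159L,
                       group_sizes = c(control = 20L, DLBCL = 14L, HL = 11L),
                       baseline_logmean_params = c(meanlog = 0, sdlog = 2.5),
                       libsize_params = c(meanlog = log(1e6), sdlog = 0.5),
                       dispersion_trend = c(a0 = 0.15, a1 = 3),
                       de_spec = default_de_spec(),
                       surv_spec = default_surv_spec(),
                       batch_offset = 0,
                       seed = 1L) {
  assert_scalar_number(n_features, "n_features", lower = 1)
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% GROUP_LEVELS)) {
    stop("group_sizes must be named with labels among ",
         paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (any(group_sizes <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (baseline_logmean_params[2L] < 0 || libsize_params[2L] < 0) {
    stop("sdlog parameters must be >= 0", call. = FALSE)
  }
  if (any(dispersion_trend < 0)) stop("dispersion trend coefficients must be >= 0", call. = FALSE)
  for (g in names(de_spec)) {
    sp <- de_spec[[g]]
    if (!g %in% GROUP_LEVELS) stop("de_spec group must be a known label", call. = FALSE)
    if (any(sp$feature < 1 | sp$feature > n_features)) {
      stop("de_spec indexes a feature outside 1..n_features", call. = FALSE)
    }
    if (any(abs(sp$log2fc) > 10)) stop("|log2FC| must be <= 10", call. = FALSE)
  }
  if (!is.null(surv_spec)) {
    if (surv_spec$censoring < 0 || surv_spec$censoring >= 1) {
      stop("censoring rate must be in [0, 1)", call. = FALSE)
    }
    if (surv_spec$horizon <= 0) stop("follow-up horizon must be > 0", call. = FALSE)
    if (any(surv_spec$features < 1 | surv_spec$features > n_features)) {
      stop("surv_spec indexes a feature outside 1..n_features", call. = FALSE)
    }
  }
  structure(list(n_features = as.integer(n_features),
                 group_sizes = group_sizes,
                 baseline_logmean_params = baseline_logmean_params,
                 libsize_params = libsize_params,
                 dispersion_trend = dispersion_trend,
                 de_spec = de_spec,
                 surv_spec = surv_spec,
                 batch_offset = batch_offset,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a plasma miRNA-seq cohort with known ground truth
#'
#' Counts are drawn as `NB(mean = lib_j * q_ij / sum_i q_ij,
#' var = mu + phi(mu) mu^2)` where `q_ij` is the baseline relative abundance
#' times `2^log2fc` for features altered in sample j's group. Fold-changes act
#' on latent abundances before renormalization to compositions, so injected
#' effects induce small compensatory shifts elsewhere (as in real sequencing).
#' Survival-linked features additionally carry per-sample log-normal jitter so
#' the survival stage has a per-subject signal to recover.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (count matrix), `samples` (sample table,
#'   survival columns filled when `surv_spec` is set) and `truth`
#'   (per-feature/group log2fc matrix, survival linkage, latent abundances).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nf <- config$n_features
    gs <- config$group_sizes
    n <- sum(gs)
    groups <- rep(names(gs), gs)
    feature_ids <- sprintf("miR-sim-%03d", seq_len(nf))
    prefix <- c(control = "ctrl", DLBCL = "dlbcl", HL = "hl")
    sample_ids <- unlist(lapply(names(gs), function(g) {
      sprintf("%s%02d", prefix[[g]], seq_len(gs[[g]]))
    }), use.names = FALSE)

    q_base <- sort(stats::rlnorm(nf, config$baseline_logmean_params[1L],
                                 config$baseline_logmean_params[2L]),
                   decreasing = TRUE)
    lfc <- matrix(0, nf, length(gs), dimnames = list(feature_ids, names(gs)))
    for (g in names(config$de_spec)) {
      sp <- config$de_spec[[g]]
      lfc[sp$feature, g] <- sp$log2fc
    }

    lib <- stats::rlnorm(n, config$libsize_params[1L], config$libsize_params[2L])

    # latent per-sample jitter on survival-linked features (natural log scale)
    sv <- config$surv_spec
    latent <- NULL
    jitter <- matrix(0, nf, n)
    if (!is.null(sv) && length(sv$features)) {
      latent <- matrix(stats::rnorm(length(sv$features) * n, 0, sv$latent_sd),
                       length(sv$features), n,
                       dimnames = list(feature_ids[sv$features], sample_ids))
      jitter[sv$features, ] <- latent
    }

    a0 <- config$dispersion_trend[1L]; a1 <- config$dispersion_trend[2L]
    counts <- matrix(0L, nf, n, dimnames = list(feature_ids, sample_ids))
    batch <- NULL
    boff <- rep(0, n)
    if (config$batch_offset != 0) {
      batch <- sample(rep(c("A", "B"), length.out = n))
      boff <- ifelse(batch == "B", config$batch_offset, 0)
    }
    for (j in seq_len(n)) {
      q <- q_base * 2^(lfc[, groups[j]] + boff[j]) * exp(jitter[, j])
      mu <- lib[j] * q / sum(q)
      phi <- a0 + a1 / pmax(mu, 1e-8)
      counts[, j] <- if (a0 == 0 && a1 == 0) {
        stats::rpois(nf, mu)
      } else {
        stats::rnbinom(nf, mu = mu, size = 1 / phi)
      }
    }

    samples <- sample_table(sample_ids, groups, batch = batch)
    truth <- structure(list(log2fc = lfc,
                            surv_spec = sv,
                            latent_log_abund = latent,
                            baseline_abund = stats::setNames(q_base, feature_ids),
                            library_sizes = stats::setNames(lib, sample_ids)),
                       class = "sim_truth")
    cm <- count_matrix(counts)
    if (!is.null(sv)) {
      samples <- simulate_survival(config, truth, samples)
    }
    list(counts = cm, samples = samples, truth = truth)
  })
}

#' Simulate survival outcomes for patient samples
#'
#' Event times are exponential with
#' `log hazard = log(baseline) + sum(coef * z(latent log abundance))`, where
#' `z()` standardizes each linked feature's latent log abundance across
#' patient samples. Subjects are censored independently (with probability
#' `censoring`, at a uniform time before the horizon) and administratively at
#' the follow-up horizon.
#'
#' @param config a [sim_config()] with a non-null `surv_spec`.
#' @param truth the `sim_truth` from [simulate_cohort()].
#' @param samples the cohort `sample_table`; controls are left without
#'   outcomes.
#' @return `samples` with `time` and `event` columns filled for patients.
#' @export
simulate_survival <- function(config, truth, samples) {
  sv <- config$surv_spec
  if (is.null(sv)) stop("config has no surv_spec", call. = FALSE)
  if (sv$horizon <= 0) stop("follow-up horizon must be > 0", call. = FALSE)
  if (sv$censoring < 0 || sv$censoring >= 1) {
    stop("censoring rate must be in [0, 1)", call. = FALSE)
  }
  patient <- samples$group != "control"
  if (!any(patient)) stop("no patient samples present", call. = FALSE)
  np <- sum(patient)
  eta <- rep(log(sv$baseline), np)
  if (length(sv$features) && !is.null(truth$latent_log_abund)) {
    lat <- truth$latent_log_abund[, samples$sample_id[patient], drop = FALSE]
    for (k in seq_along(sv$features)) {
      zk <- as.numeric(scale(lat[k, ]))
      eta <- eta + sv$coefs[k] * zk
    }
  }
  t_event <- stats::rexp(np, rate = exp(eta))
  cens <- rep(sv$horizon, np)
  if (sv$censoring > 0) {
    early <- stats::runif(np) < sv$censoring
    cens[early] <- stats::runif(sum(early), 0, sv$horizon)
  }
  time <- pmin(t_event, cens)
  event <- as.numeric(t_event <= cens)
  time <- pmax(time, 1e-6)
  out <- samples
  out$time <- NA_real_
  out$event <- NA_real_
  out$time[patient] <- time
  out$event[patient] <- event
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Write simulated cohort outputs to a directory
#'
#' Emits `counts.tsv`, `samples.tsv` and `truth.json` in the same dialects the
#' IO layer consumes.
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest of written files.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_counts(sim$counts, paths[["counts"]])
  write_samples(sim$samples, paths[["samples"]])
  truth <- sim$truth
  jsonlite::write_json(list(
    log2fc = as.data.frame(truth$log2fc),
    features = rownames(truth$log2fc),
    surv_spec = truth$surv_spec,
    baseline_abund = truth$baseline_abund
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
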