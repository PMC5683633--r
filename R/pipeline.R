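# End-to-end orchestration: simulate or load counts, filter, normalize,
# run the three-test DE consensus per comparison, composite scores and ROC,
# classifier validation and the survival screen, under one seeded
# configuration with a machine-readable report.

#' Pipeline configuration
#'
#' @param counts_path,samples_path paths to a count matrix and sample sheet;
#'   leave `NULL` to simulate a cohort from `sim` instead.
#' @param sim a [sim_config()] used when no input paths are given.
#' @param comparisons character vector of patient groups to compare against
#'   controls.
#' @param alpha BH significance cutoff for the consensus.
#' @param transform transform feeding PCA, scores and the classifier
#'   (`"weighted_logcpm"`, `"logcpm"` or `"vst"`).
#' @param normalize_factors `"median-ratio"`, `"tmm"` or `"none"` (equal
#'   plasma-volume reading: all factors 1).
#' @param min_reads,min_fraction detection-filter parameters.
#' @param classifier list: `n_iter`, `train_fraction`, `n_features`,
#'   `inclusion_n_iter`, `inclusion_n_features`.
#' @param survival list: `n_resamples`, `n_perm`, `top_k` features to confirm
#'   with Cox models.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, samples_path = NULL,
                            sim = sim_config(),
                            comparisons = c("DLBCL", "HL"),
                            alpha = 0.05,
                            transform = "weighted_logcpm",
                            normalize_factors = "median-ratio",
                            min_reads = 1, min_fraction = 0.25,
                            classifier = list(n_iter = 1000L, train_fraction = 0.5,
                                              n_features = 10L,
                                              inclusion_n_iter = 200L,
                                              inclusion_n_features = 80L),
                            survival = list(n_resamples = 20L, n_perm = 100L,
                                            top_k = 8L),
                            seed = 1L, out_dir = tempfile("lymphomir_run")) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  transform <- match.arg(transform, c("weighted_logcpm", "logcpm", "vst"))
  normalize_factors <- match.arg(normalize_factors, c("median-ratio", "tmm", "none"))
  structure(list(counts_path = counts_path, samples_path = samples_path,
                 sim = sim, comparisons = comparisons, alpha = alpha,
                 transform = transform, normalize_factors = normalize_factors,
                 min_reads = min_reads, min_fraction = min_fraction,
                 classifier = classifier, survival = survival,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

depth_factors <- function(cm, method) {
  switch(method,
         "median-ratio" = size_factors_median_ratio(cm),
         "tmm" = {
           f <- colSums(cm) * norm_factors_tmm(cm)
           stats::setNames(f / geo_mean(f), colnames(cm))
         },
         "none" = stats::setNames(rep(1, ncol(cm)), colnames(cm)))
}

make_transform <- function(cm, config, groups = NULL, disp = NULL) {
  f_norm <- if (config$normalize_factors == "tmm") norm_factors_tmm(cm) else NULL
  switch(config$transform,
         logcpm = log_cpm(cm, f_norm),
         weighted_logcpm = precision_weights(cm, f_norm, groups = groups),
         vst = vst_counts(cm, f_norm,
                          dispersion = if (is.null(disp)) 0.1 else
                            max(disp$trend_coefs[["a0"]], 1e-3)))
}

run_comparison <- function(cm, samples, config, grp, out_dir) {
  keep <- samples$group %in% c("control", grp)
  sub <- cm[, samples$sample_id[keep], drop = FALSE]
  groups <- as.character(samples$group[keep])
  sf <- depth_factors(sub, if (config$normalize_factors == "none") "none" else "median-ratio")
  disp <- estimate_dispersions(sub, sf, groups)
  comparison <- paste0(grp, "_vs_control")

  t_wald <- de_test_nbwald(sub, groups, sf, disp, comparison)
  ef <- if (config$normalize_factors == "none") {
    stats::setNames(rep(1, ncol(sub)), colnames(sub))
  } else norm_factors_tmm(sub)
  t_exact <- de_test_nbexact(sub, groups, ef, disp, comparison)
  tm_w <- precision_weights(sub, if (config$normalize_factors == "none") NULL else ef,
                            groups = groups)
  t_modt <- de_test_modt(tm_w, groups, comparison)
  cons <- consensus_calls(list(t_wald, t_exact, t_modt), alpha = config$alpha)

  # composite scores and AUCs on the full cohort, standardized on this
  # comparison's two groups; all three groups are projected
  tm_all <- make_transform(cm, config, groups = as.character(samples$group),
                           disp = disp)
  std <- standardize_features(tm_all, cohort_ids = samples$sample_id[keep])
  panels <- suppressWarnings(score_panels_from_consensus(cons))
  score_rows <- lapply(names(panels), function(pn) {
    pan <- panels[[pn]]
    pan$up <- intersect(pan$up, rownames(std$z))
    pan$down <- intersect(pan$down, rownames(std$z))
    if (!length(pan$up) && !length(pan$down)) return(NULL)
    sc <- composite_score(std$z, pan)
    a <- auc_mw(sc[keep], groups, case_level = grp)
    data.frame(panel = pn, n_up = length(pan$up), n_down = length(pan$down),
               auc = a$auc, pvalue = a$p, stringsAsFactors = FALSE)
  })
  score_tab <- do.call(rbind, score_rows)
  feat_auc <- per_feature_auc(
    if (inherits(tm_all, "transformed_matrix")) tm_all$values[, keep, drop = FALSE]
    else tm_all[, keep, drop = FALSE],
    groups, case_level = grp)

  # classifier validation on this comparison's samples
  vals <- (if (inherits(tm_all, "transformed_matrix")) tm_all$values else tm_all)[, keep, drop = FALSE]
  cl <- config$classifier
  mrv <- validate_mrv(vals, groups, n_iter = cl$n_iter,
                      train_fraction = cl$train_fraction,
                      n_features = min(cl$n_features, nrow(vals)),
                      seed = stage_seed(config$seed, paste0("mrv_", grp)))
  incl <- validate_mrv(vals, groups, n_iter = cl$inclusion_n_iter,
                       train_fraction = cl$train_fraction,
                       n_features = min(cl$inclusion_n_features, nrow(vals)),
                       seed = stage_seed(config$seed, paste0("incl_", grp)))

  for (obj in list(list(t_wald, "de_nbwald"), list(t_exact, "de_nbexact"),
                   list(t_modt, "de_modt"), list(cons, "consensus"),
                   list(feat_auc, "feature_auc"))) {
    write_table(obj[[1L]], file.path(out_dir, paste0(obj[[2L]], "_", comparison, ".tsv")))
  }
  if (!is.null(score_tab)) {
    write_table(score_tab, file.path(out_dir, paste0("panel_auc_", comparison, ".tsv")))
  }
  incl_tab <- data.frame(feature = names(incl$inclusion_rate),
                         inclusion_rate = unname(incl$inclusion_rate),
                         stringsAsFactors = FALSE)
  incl_tab <- incl_tab[order(-incl_tab$inclusion_rate), ]
  write_table(incl_tab, file.path(out_dir, paste0("inclusion_rate_", comparison, ".tsv")))

  list(comparison = comparison, consensus = cons, panels = score_tab,
       feature_auc = feat_auc, mrv = mrv, inclusion = incl_tab)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the detection filter, runs the
#' three-test differential-abundance consensus for every requested comparison,
#' computes composite-score panels with ROC/AUC, validates the
#' nearest-centroid classifier, and screens miRNAs for survival association
#' when outcomes are present. All stage outputs are written as TSV/JSON under
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return A report bundle: `manifest`, `summary`, `config`, plus the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$counts_path)) {
    cm <- read_counts(config$counts_path)
    samples <- read_samples(config$samples_path)
    truth <- NULL
  } else {
    simc <- config$sim
    simc$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_cohort(simc)
    cm <- sim$counts; samples <- sim$samples; truth <- sim$truth
    write_simulation(sim, out_dir)
  }
  missing <- setdiff(samples$sample_id, colnames(cm))
  if (length(missing)) stop("sample sheet ids absent from counts: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  cm <- cm[, samples$sample_id, drop = FALSE]
  cm <- filter_detected(cm, config$min_reads, config$min_fraction)

  # PCA on the full cohort
  sf_all <- depth_factors(cm, if (config$normalize_factors == "none") "none" else "median-ratio")
  tm_pca <- make_transform(cm, config, groups = as.character(samples$group))
  pca <- pca_scores(tm_pca, n_components = min(4L, min(dim(cm)) - 1L))
  pca_tab <- data.frame(sample_id = rownames(pca$scores),
                        group = as.character(samples$group), pca$scores,
                        stringsAsFactors = FALSE)
  write_table(pca_tab, file.path(out_dir, "pca_scores.tsv"))

  comp_results <- lapply(config$comparisons, function(grp) {
    tryCatch(run_comparison(cm, samples, config, grp, out_dir),
             error = function(e) stop(sprintf("stage de[%s]: %s", grp,
                                              conditionMessage(e)), call. = FALSE))
  })
  names(comp_results) <- config$comparisons

  surv_result <- NULL
  if (!is.null(samples$time) && any(!is.na(samples$time))) {
    patients <- samples[!is.na(samples$time), ]
    sv <- config$survival
    ranks <- depth_standardized_ranks(cm[, patients$sample_id, drop = FALSE],
                                      n_resamples = sv$n_resamples,
                                      seed = stage_seed(config$seed, "thin"))
    screen <- permutation_null(ranks, patients$time, patients$event,
                               n_perm = sv$n_perm,
                               seed = stage_seed(config$seed, "perm"))
    write_table(screen$table, file.path(out_dir, "survival_screen.tsv"))
    write_table(screen$qq, file.path(out_dir, "survival_qq.tsv"))
    top <- screen$table$feature[order(-abs(screen$table$score))][seq_len(min(sv$top_k, nrow(screen$table)))]
    cox_tab <- do.call(rbind, lapply(top, function(f) {
      x <- dichotomize_median(ranks[f, ])
      if (length(unique(x)) < 2L) return(NULL)
      fit <- cox_fit_binary(x, patients$time, patients$event)
      data.frame(feature = f, hr = fit$hr, log_hr = fit$log_hr, se = fit$se,
                 pvalue = fit$pvalue, n_events = fit$n_events,
                 monotone = fit$monotone, stringsAsFactors = FALSE)
    }))
    km <- km_curve(patients$time, patients$event)
    write_table(cox_tab, file.path(out_dir, "survival_cox.tsv"))
    write_table(km, file.path(out_dir, "survival_km.tsv"))
    surv_result <- list(screen = screen, cox = cox_tab, km = km)
  }

  summary <- list(
    n_features = nrow(cm), n_samples = ncol(cm),
    seed = config$seed,
    consensus_counts = lapply(comp_results, function(r) {
      list(up = sum(r$consensus$consensus & r$consensus$direction == "up"),
           down = sum(r$consensus$consensus & r$consensus$direction == "down"))
    }),
    panel_auc = lapply(comp_results, function(r) {
      if (is.null(r$panels)) NULL else
        stats::setNames(as.list(r$panels$auc), r$panels$panel)
    }),
    misclassification = lapply(comp_results, function(r) as.list(r$mrv$summary)),
    survival = if (is.null(surv_result)) "skipped" else list(
      n_events = sum(surv_result$km$n_event),
      top_feature = surv_result$cox$feature[1L],
      min_qvalue = min(surv_result$screen$table$qvalue))
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  bundle <- list(manifest = manifest, summary = summary, config = config,
                 comparisons = comp_results, survival = surv_result,
                 truth = truth, out_dir = out_dir)
  class(bundle) <- "report_bundle"
  bundle
}
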