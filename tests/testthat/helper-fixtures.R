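# Shared fixture builders. Everything is generated in code; no files.

# Tiny deterministic count matrix.
toy_counts <- function(nf = 6L, ns = 4L, seed = 11L, lambda = 50) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  m <- withr_seed(matrix(rpois(nf * ns, lambda), nf, ns))
  count_matrix(m,
               feature_ids = sprintf("miR-t%02d", seq_len(nf)),
               sample_ids = sprintf("s%02d", seq_len(ns)))
}

# A quick two-group cohort config: flat-ish abundances, constant dispersion,
# modest depth so the exact NB test enumerates quickly.
quick_config <- function(seed, n_features = 159L,
                         group_sizes = c(control = 20L, DLBCL = 14L),
                         phi = 0.2, libsize = 1e4, de_spec = list(),
                         sdlog_abund = 1, surv_spec = NULL) {
  sim_config(n_features = n_features, group_sizes = group_sizes,
             baseline_logmean_params = c(meanlog = 0, sdlog = sdlog_abund),
             libsize_params = c(meanlog = log(libsize), sdlog = 0.2),
             dispersion_trend = c(a0 = phi, a1 = 0),
             de_spec = de_spec, surv_spec = surv_spec, seed = seed)
}

# de_spec injecting n_up/n_down effects at |log2fc| = lfc on mid-rank features.
inject_spec <- function(group = "DLBCL", n_up = 20L, n_down = 20L, lfc = 1.5,
                        start = 21L) {
  idx <- seq(start, by = 2L, length.out = n_up + n_down)
  out <- list(data.frame(feature = idx,
                         log2fc = c(rep(lfc, n_up), rep(-lfc, n_down))))
  names(out) <- group
  out
}

# Fixed-dispersion fit object, bypassing estimation.
fixed_disp <- function(nf, phi) {
  structure(list(raw = rep(phi, nf), trend_coefs = c(a0 = phi, a1 = 0),
                 shrunk = rep(phi, nf), prior_weight = 0.5,
                 mean = rep(NA_real_, nf)),
            class = "dispersion_fit")
}

# Exhaustive Mann-Whitney AUC: count case/control pairs.
auc_bruteforce <- function(values, labels, case_level) {
  cases <- values[labels == case_level]
  ctrls <- values[labels != case_level]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}
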