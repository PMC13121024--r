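# End-to-end study analysis: per subject-condition information measures and
# transition energies, condition contrasts with FDR, the energy-integration
# correlation, and dominance analysis of arousal on the information measures.

#' Full analysis of a (synthetic) study
#'
#' For every subject and condition computes the pairwise global means of the
#' information-dynamic measures (revised integrated information, whole-minus-
#' sum integrated information, causal density, net information flow; plus
#' TDMI and double redundancy), and the mean transition energy under uniform
#' and map-weighted control. Conditions are contrasted per measure with
#' Welch t-tests corrected by Benjamini-Hochberg FDR; the correlation between
#' integrated information and transition energy is computed across all
#' datapoints; and arousal scores are decomposed by dominance analysis over
#' the four information measures with a permutation test of the overall fit.
#'
#' @param study A `synthetic_study` (from [synthetic_study()] or
#'   [read_study()]).
#' @param lag Lag in samples for the information measures.
#' @param debias_surrogates If > 0, also report debiased measures using this
#'   many time-shuffle surrogates per run.
#' @param n_perm Permutations for the dominance R-squared test.
#' @param seed Integer seed (permutation test and debiasing).
#' @return Object of class `study_report`: list with `per_run` (data frame),
#'   `contrasts` (data frame with q-values), `energy_phi_correlation`,
#'   `dominance`, `dominance_p`, and the settings used.
#' @export
run_study_analysis <- function(study, lag = 1L, debias_surrogates = 0L,
                               n_perm = 999L, seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  cn <- study$connectome
  sys_uniform <- control_system(cn)
  map_b <- heterogeneous_control_weights(study$truth_map)
  sys_map <- control_system(normalize_dynamics(cn), B = map_b)

  per_run <- NULL
  for (cond in names(study$subjects)) {
    runs <- study$subjects[[cond]]
    for (s in seq_along(runs)) {
      ts <- runs[[s]]
      meas <- pairwise_means_all(ts, lag)
      row <- data.frame(
        subject = s, condition = cond,
        phi_R = meas[["phi_R"]], phi_2008 = meas[["phi_2008"]],
        causal_density = meas[["causal_density"]],
        net_flow = meas[["net_flow"]], tdmi = meas[["tdmi"]],
        double_redundancy = meas[["double_redundancy"]],
        energy_uniform = transition_energy_timeseries(ts, sys_uniform)$mean_energy,
        energy_map = transition_energy_timeseries(ts, sys_map)$mean_energy
      )
      if (debias_surrogates > 0) {
        db <- debias(ts, lag, n_surrogates = debias_surrogates,
                     seed = child_seed(seed, 500L + s))
        row$phi_R_debiased <- db$debiased[["phi_R"]]
      }
      ar <- study$arousal
      row$arousal <- ar$arousal[ar$subject == s & ar$condition == cond][1]
      per_run <- rbind(per_run, row)
    }
  }

  # pairwise condition contrasts per measure, BH-corrected within the report
  conds <- unique(per_run$condition)
  meas_cols <- c("phi_R", "phi_2008", "causal_density", "net_flow",
                 "energy_uniform", "energy_map")
  contrasts <- NULL
  if (length(conds) >= 2) {
    cond_pairs <- combn(conds, 2, simplify = FALSE)
    for (cp in cond_pairs) {
      for (mc in meas_cols) {
        a <- per_run[[mc]][per_run$condition == cp[1]]
        b <- per_run[[mc]][per_run$condition == cp[2]]
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        contrasts <- rbind(contrasts, data.frame(
          measure = mc, condition_a = cp[1], condition_b = cp[2],
          mean_a = mean(a), mean_b = mean(b),
          t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
          p = if (is.null(tt)) NA_real_ else tt$p.value))
      }
    }
    ok <- !is.na(contrasts$p)
    contrasts$q <- NA_real_
    contrasts$q[ok] <- fdr_bh(contrasts$p[ok])
  }

  energy_phi_cor <- cor(per_run$phi_R, per_run$energy_uniform)

  dom_x <- as.matrix(per_run[, c("phi_R", "phi_2008", "causal_density",
                                 "net_flow")])
  dom <- tryCatch(dominance_analysis(dom_x, per_run$arousal),
                  error = function(e) NULL)
  dom_p <- if (is.null(dom)) NA_real_ else {
    permutation_r2_test(dom_x, per_run$arousal, n_perm = n_perm,
                        seed = child_seed(seed, 900L))$p_value
  }

  structure(list(per_run = per_run, contrasts = contrasts,
                 energy_phi_correlation = energy_phi_cor,
                 dominance = dom, dominance_p = dom_p,
                 lag = lag, seed = seed),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d runs, %d conditions\n",
              nrow(x$per_run), length(unique(x$per_run$condition))))
  cat(sprintf("  phi_R-energy correlation: %.3f\n", x$energy_phi_correlation))
  if (!is.null(x$dominance)) {
    cat(sprintf("  dominance R2 = %.3f (perm p = %.4g); top predictor: %s\n",
                x$dominance$total_r2, x$dominance_p,
                names(which.max(x$dominance$importance))))
  }
  invisible(x)
}

#' Write a study report as JSON
#'
#' Serializes the per-run table, contrasts, correlation and dominance shares
#' with the settings and seeds; deterministic content for fixed inputs.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  out <- list(
    per_run = report$per_run,
    contrasts = report$contrasts,
    energy_phi_correlation = report$energy_phi_correlation,
    dominance = if (is.null(report$dominance)) NULL else list(
      importance = as.list(report$dominance$importance),
      total_r2 = report$dominance$total_r2,
      adjusted_r2 = report$dominance$adjusted_r2,
      percent = as.list(report$dominance$percent_importance),
      permutation_p = report$dominance_p),
    settings = list(lag = report$lag, seed = report$seed,
                    package_version = as.character(utils::packageVersion("phidyn")))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
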