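# Whole synthetic studies: multi-subject, multi-condition VAR timeseries on a
# shared connectome, with a spatial "truth" map driving regional attenuation
# and a behavioural arousal score linked to the coupling scale.

#' Condition specification for a synthetic study
#'
#' Each condition is described by a global coupling scale (the awake-like
#' condition at 1.0, anaesthesia-like conditions lower), a common-noise
#' level (equicorrelation of the VAR innovations) and an inhibition weight
#' that attenuates each region's incoming coupling in proportion to the
#' study's truth map.
#'
#' @param conditions Named list; each element a list with `coupling_scale`
#'   (in (0, 1]), `common_noise` (in [0, 1)) and `inhibition` (in [0, 1]).
#' @return A validated `condition_spec` list.
#' @export
condition_spec <- function(conditions = list(
  awake = list(coupling_scale = 1.0, common_noise = 0.1, inhibition = 0),
  anaesthesia = list(coupling_scale = 0.4, common_noise = 0.1, inhibition = 0.5)
)) {
  if (length(conditions) < 2 || is.null(names(conditions)) ||
      any(names(conditions) == "")) {
    stop("condition_spec needs at least two named conditions")
  }
  for (nm in names(conditions)) {
    cc <- conditions[[nm]]
    need <- c("coupling_scale", "common_noise", "inhibition")
    if (!all(need %in% names(cc))) {
      stop("condition '", nm, "' must define ", paste(need, collapse = ", "))
    }
    if (cc$coupling_scale <= 0 || cc$coupling_scale > 1) {
      stop("coupling_scale must be in (0, 1]")
    }
    if (cc$common_noise < 0 || cc$common_noise >= 1) {
      stop("common_noise must be in [0, 1)")
    }
    if (cc$inhibition < 0 || cc$inhibition > 1) stop("inhibition must be in [0, 1]")
  }
  structure(conditions, class = "condition_spec")
}

# VAR coupling for one condition: connectome normalized to unit spectral
# radius, scaled by base_strength * coupling_scale, rows attenuated by the
# truth map through the inhibition weight.
condition_coupling <- function(cn, truth, coupling_scale, inhibition,
                               base_strength = 0.9) {
  a0 <- cn$weights / spectral_radius(cn$weights)
  atten <- 1 - inhibition * truth$values
  diag(atten, length(atten)) %*% (base_strength * coupling_scale * a0)
}

#' Generate a complete synthetic study
#'
#' Produces every input the analysis pipeline needs: a modular study
#' connectome, region coordinates, a smooth truth map (sigmoid normalized to
#' `[0, 1]`), and per subject-and-condition VAR timeseries whose coupling is
#' scaled per condition and attenuated region-wise by the truth map. Each
#' subject-condition also gets an arousal score on the 0-11 scale, generated
#' as `round(11 * coupling_scale)` plus integer noise in `{-1, 0, 1}`,
#' clipped to `[0, 11]`. Bit-identical regeneration from the same
#' `(spec, seed)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_regions Number of regions.
#' @param spec A [condition_spec()].
#' @param n_time Timepoints per run.
#' @param seed Integer seed.
#' @param density Connectome density.
#' @param corr_length Correlation length of the truth map relative to the
#'   unit-cube coordinate span.
#' @param subject_sd Between-subject standard deviation of the coupling
#'   scale (biological variability; each subject-condition's effective
#'   scale is the condition scale plus Gaussian jitter, clamped to
#'   (0.05, 1]). The arousal rule is applied to the effective scale.
#' @param noise_sd Between-run standard deviation of the common-noise level
#'   (shared physiological noise varies across runs independently of
#'   arousal; clamped to [0, 0.8]).
#' @param drift_sd Scale of the run-varying global slow drift: each run
#'   receives a shared AR(1) component (coefficient 0.8) added to every
#'   region with amplitude `|N(0, drift_sd)|`, emulating global
#'   physiological drift whose strength varies across runs independently of
#'   arousal. This inflates persistent redundancy without touching
#'   integration.
#' @return Object of class `synthetic_study`: list with `subjects` (nested
#'   `[[condition]][[subject]]` timeseries), `connectome`, `coords`,
#'   `truth_map`, `arousal` (data frame), `effect_params`, `seed`.
#' @export
synthetic_study <- function(n_subjects = 8L, n_regions = 20L,
                            spec = condition_spec(), n_time = 400L,
                            seed = 1L, density = 0.25, corr_length = 0.4,
                            subject_sd = 0.08, noise_sd = 0.15,
                            drift_sd = 0.8) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  spec <- if (inherits(spec, "condition_spec")) spec else condition_spec(spec)
  cn <- synthetic_connectome(n_regions, density, "modular-empirical-like",
                             seed = child_seed(seed, 1L))
  coords <- with_seed(child_seed(seed, 2L),
                      matrix(runif(n_regions * 3), n_regions, 3,
                             dimnames = list(cn$labels, c("x", "y", "z"))))
  truth <- sigmoid_normalize(spatial_map(coords, corr_length,
                                         seed = child_seed(seed, 3L)))
  truth$labels <- cn$labels
  names(truth$values) <- cn$labels

  subjects <- list()
  arousal <- NULL
  stream <- 10L
  for (cond in names(spec)) {
    cc <- spec[[cond]]
    runs <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      stream <- stream + 1L
      jit <- with_seed(child_seed(seed, stream), rnorm(2))
      g_eff <- min(1, max(0.05, cc$coupling_scale + subject_sd * jit[1]))
      cn_eff <- min(0.8, max(0, cc$common_noise + noise_sd * jit[2]))
      q <- (1 - cn_eff) * diag(n_regions) +
        cn_eff * matrix(1, n_regions, n_regions)
      a <- condition_coupling(cn, truth, g_eff, cc$inhibition)
      sys <- var_system(a, q, labels = cn$labels)
      stream <- stream + 1L
      run_ts <- generate_var(sys, n_time, seed = child_seed(seed, stream))
      stream <- stream + 1L
      if (drift_sd > 0) {
        drift <- with_seed(child_seed(seed, stream), {
          amp <- abs(rnorm(1, sd = drift_sd))
          z <- numeric(n_time)
          e <- rnorm(n_time)
          for (t in 2:n_time) z[t] <- 0.8 * z[t - 1] + e[t]
          amp * z
        })
        run_ts <- regional_timeseries(run_ts$values + drift,
                                      labels = run_ts$labels, tr = run_ts$tr)
      }
      runs[[s]] <- run_ts
      stream <- stream + 1L
      score <- with_seed(child_seed(seed, stream), {
        round(11 * g_eff) + sample(c(-1L, 0L, 1L), 1L)
      })
      arousal <- rbind(arousal, data.frame(
        subject = s, condition = cond,
        arousal = max(0L, min(11L, score))))
    }
    names(runs) <- paste0("sub", seq_len(n_subjects))
    subjects[[cond]] <- runs
  }
  structure(list(subjects = subjects, connectome = cn, coords = coords,
                 truth_map = truth, arousal = arousal,
                 effect_params = spec, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d conditions x %d subjects, %d regions\n",
              length(x$subjects), length(x$subjects[[1]]),
              length(x$truth_map$values)))
  invisible(x)
}

#' Write a study to disk with a JSON manifest
#'
#' Writes every timeseries, the connectome, the truth map and coordinates as
#' delimited text, and a `manifest.json` index listing per-subject file
#' paths, condition labels, arousal scores and the generating spec.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_connectome(study$connectome, file.path(dir, "connectome.tsv"))
  write_map(study$truth_map, file.path(dir, "truth_map.tsv"))
  coords_df <- data.frame(label = rownames(study$coords), study$coords)
  write.table(coords_df, file.path(dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  runs <- list()
  for (cond in names(study$subjects)) {
    for (s in seq_along(study$subjects[[cond]])) {
      fn <- sprintf("ts_%s_sub%02d.tsv", cond, s)
      write_timeseries(study$subjects[[cond]][[s]], file.path(dir, fn))
      score <- study$arousal$arousal[study$arousal$subject == s &
                                       study$arousal$condition == cond]
      runs[[length(runs) + 1L]] <- list(condition = cond, subject = s,
                                        file = fn, arousal = score)
    }
  }
  manifest <- list(connectome = "connectome.tsv", truth_map = "truth_map.tsv",
                   coords = "coords.tsv", runs = runs,
                   effect_params = unclass(study$effect_params),
                   seed = study$seed)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study written by [write_study()]
#' @param dir Directory containing `manifest.json`.
#' @return A `synthetic_study`-like list (without regeneration parameters).
#' @export
read_study <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in '", dir, "'")
  mf <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cn <- read_connectome(file.path(dir, mf$connectome))
  truth <- read_map(file.path(dir, mf$truth_map), labels = cn$labels)
  coords_df <- read.delim(file.path(dir, mf$coords), sep = "\t")
  coords <- as.matrix(coords_df[, c("x", "y", "z")])
  rownames(coords) <- coords_df$label
  subjects <- list()
  arousal <- NULL
  for (run in mf$runs) {
    ts <- read_timeseries(file.path(dir, run$file))
    subjects[[run$condition]][[paste0("sub", run$subject)]] <- ts
    arousal <- rbind(arousal, data.frame(subject = run$subject,
                                         condition = run$condition,
                                         arousal = run$arousal))
  }
  structure(list(subjects = subjects, connectome = cn, coords = coords,
                 truth_map = truth, arousal = arousal,
                 effect_params = mf$effect_params, seed = mf$seed),
            class = "synthetic_study")
}
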