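#' Default input distributions for probabilistic risk
#'
#' Standard practice in probabilistic soil-risk assessment, fully
#' overridable:
#' * `conc` — lognormal uncertainty on the exposure-point (site-mean)
#'   concentration: arithmetic mean equal to the per-metal site mean, CV
#'   equal to the site CV divided by sqrt(n_samples) (the standard error of
#'   the mean). Spatial variability between samples is reported by the
#'   deterministic module; the probabilistic model propagates uncertainty
#'   in the chronic exposure-point concentration.
#' * `ing_r` — lognormal (soil ingestion is the most uncertain and most
#'   right-skewed exposure factor), arithmetic mean at the deterministic
#'   default, CV 60%, truncated to \[mean/20, 5 x mean\].
#' * `bw` — normal, CV 20%, truncated to \[0.4, 2\] x mean.
#' * `inh_r`, `sa`, `af` — triangular, mode at the default, +/-30%.
#' * `ef_d`, `ed` — point values (chronic scenario definition, not
#'   uncertain quantities).
#'
#' @param metal Metal symbol.
#' @param profile An [exposure_profile()].
#' @param stats Site statistics with `metal`, `mean`, `cv_percent` columns
#'   (default [reference_stats()]).
#' @param n_samples Sample count behind `stats` (default 20), used for the
#'   standard error of the mean.
#' @return Named list of [dist_spec()]s for `conc`, `ing_r`, `inh_r`, `bw`,
#'   `sa`, `af`, `ef_d`, `ed`.
#' @export
default_risk_distributions <- function(metal, profile,
                                       stats = reference_stats(),
                                       n_samples = 20) {
  s <- stats[stats$metal == metal, ]
  if (nrow(s) != 1) stop("no statistics for metal: ", metal)
  cv_se <- (s$cv_percent / 100) / sqrt(n_samples)
  sdlog <- sqrt(log1p(cv_se^2))
  tri <- function(center) {
    dist_spec("triangular", min = 0.7 * center, mode = center,
              max = 1.3 * center)
  }
  list(
    conc = dist_spec("lognormal", meanlog = log(s$mean) - sdlog^2 / 2,
                     sdlog = sdlog),
    ing_r = dist_spec("lognormal",
                      meanlog = log(profile$ing_r) - log1p(0.36) / 2,
                      sdlog = sqrt(log1p(0.36)),
                      low = profile$ing_r / 20, high = profile$ing_r * 5),
    inh_r = tri(profile$inh_r),
    bw = dist_spec("normal", mean = profile$bw, sd = 0.2 * profile$bw,
                   low = 0.4 * profile$bw, high = 2 * profile$bw),
    sa = tri(profile$sa),
    af = tri(profile$af),
    ef_d = dist_spec("point", value = profile$ef_d),
    ed = dist_spec("point", value = profile$ed)
  )
}

#' Build a vectorized hazard-index model for one metal and receptor
#'
#' Returns a closure over the metal's reference doses and absorption
#' fraction that maps the named exposure parameters (`conc`, `ing_r`,
#' `inh_r`, `bw`, `sa`, `af`, `ef_d`, `ed`) to HI = HQ_ing + HQ_inh +
#' HQ_derm, using the non-carcinogenic averaging time `ed * 365` and the
#' fixed particle emission factor of `profile`. Suitable for
#' [run_simulation()] and [sobol_run()].
#'
#' @param metal Metal symbol.
#' @param profile An [exposure_profile()] (supplies the fixed PEF).
#' @param tox Toxicity registry (default [default_toxicity()]).
#' @return Function `f(params)` as required by [run_simulation()].
#' @export
build_hi_model <- function(metal, profile, tox = default_toxicity()) {
  r <- tox_row(tox, metal)
  if (any(is.na(c(r$rfd_ing, r$rfd_inh, r$rfd_derm)))) {
    stop("missing RfD for metal ", metal)
  }
  pef <- profile$pef
  abs_frac <- r$abs
  function(p) {
    at <- p$ed * 365
    base <- p$conc * p$ef_d * p$ed / (p$bw * at)
    hq_ing <- base * p$ing_r * 1e-6 / r$rfd_ing
    hq_inh <- base * p$inh_r / (pef * r$rfd_inh)
    hq_derm <- base * p$sa * p$af * abs_frac * 1e-6 / r$rfd_derm
    hq_ing + hq_inh + hq_derm
  }
}

#' Build a vectorized total-cancer-risk model for one metal and receptor
#'
#' As [build_hi_model()], but doses use the carcinogenic averaging time
#' `profile$at_ca` and are multiplied by the pathway slope factors
#' (pathways without a slope factor contribute zero).
#'
#' @inheritParams build_hi_model
#' @return Function `f(params)` returning TCR per draw.
#' @export
build_tcr_model <- function(metal, profile, tox = default_toxicity()) {
  r <- tox_row(tox, metal)
  csf <- c(ing = r$csf_ing, inh = r$csf_inh, derm = r$csf_derm)
  if (all(is.na(csf))) {
    stop("metal ", metal,
         " has no cancer slope factor (non-carcinogenic only)")
  }
  csf[is.na(csf)] <- 0
  pef <- profile$pef
  abs_frac <- r$abs
  at_ca <- profile$at_ca
  function(p) {
    base <- p$conc * p$ef_d * p$ed / (p$bw * at_ca)
    cr_ing <- base * p$ing_r * 1e-6 * csf[["ing"]]
    cr_inh <- base * p$inh_r / pef * csf[["inh"]]
    cr_derm <- base * p$sa * p$af * abs_frac * 1e-6 * csf[["derm"]]
    cr_ing + cr_inh + cr_derm
  }
}

#' Probabilistic risk summary across metals and receptors
#'
#' Runs one seeded Monte Carlo simulation per (receptor, metal) for HI
#' (threshold 1) and, for carcinogenic metals, TCR (threshold 1e-4). Each
#' simulation gets its own seed derived from the master seed by a counter,
#' so any single cell can be reproduced in isolation.
#'
#' @param profiles Named list of [exposure_profile()]s.
#' @param metals Metals to simulate (default all in `stats`).
#' @param stats Site statistics (default [reference_stats()]).
#' @param tox Toxicity registry.
#' @param n Iterations per simulation (default 10000).
#' @param seed Master seed.
#' @param thresholds Named list with elements `hi` and `tcr`.
#' @return Data.frame with one row per (receptor, metal, output) and
#'   columns `p5`, `p50`, `p95`, `mean`, `sd`, `p_exceed`, `threshold`,
#'   `seed`.
#' @export
mc_risk_summary <- function(profiles = default_exposure_profiles(),
                            metals = NULL, stats = reference_stats(),
                            tox = default_toxicity(), n = 10000, seed = 1,
                            thresholds = list(hi = 1, tcr = 1e-4)) {
  if (is.null(metals)) metals <- stats$metal
  rows <- list()
  counter <- 0
  for (rec in names(profiles)) {
    p <- profiles[[rec]]
    for (m in metals) {
      counter <- counter + 1
      dists <- default_risk_distributions(m, p, stats = stats)
      run_one <- function(model, threshold, output) {
        mc <- run_simulation(model, dists, n = n,
                             seed = derive_seed(seed, counter),
                             thresholds = threshold)
        data.frame(receptor = rec, metal = m, output = output,
                   p5 = mc$stats[["p5"]], p50 = mc$stats[["p50"]],
                   p95 = mc$stats[["p95"]], mean = mc$stats[["mean"]],
                   sd = mc$stats[["sd"]],
                   p_exceed = mc$exceedance$p_exceed[1],
                   threshold = threshold, seed = derive_seed(seed, counter),
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <-
        run_one(build_hi_model(m, p, tox), thresholds$hi, "hi")
      r <- tox_row(tox, m)
      if (!all(is.na(c(r$csf_ing, r$csf_inh, r$csf_derm)))) {
        counter <- counter + 1
        rows[[length(rows) + 1]] <-
          run_one(build_tcr_model(m, p, tox), thresholds$tcr, "tcr")
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
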