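#' Receptor exposure profile
#'
#' Bundles the receptor-specific exposure factors of the USEPA soil exposure
#' model. Units: `ing_r` mg/day (soil ingestion), `inh_r` m^3/day, `ef_d`
#' days/year (exposure frequency), `ed` years (exposure duration), `bw` kg,
#' `sa` cm^2 (exposed skin), `af` mg/cm^2/day (soil-to-skin adherence),
#' `pef` m^3/kg (particle emission factor). The non-carcinogenic averaging
#' time is `at_nc = ed * 365` days; the carcinogenic averaging time `at_ca`
#' defaults to a 70-year lifetime (25550 days).
#'
#' @param receptor `"child"` or `"adult"` (free label, used in reports).
#' @param ing_r,inh_r,ef_d,ed,bw,sa,af,pef Exposure factors, all > 0,
#'   `ef_d <= 365`.
#' @param at_ca Carcinogenic averaging time in days (>= `at_nc`).
#' @return List of class `"exposure_profile"`.
#' @export
exposure_profile <- function(receptor, ing_r, inh_r, ef_d, ed, bw, sa, af,
                             pef = 1.36e9, at_ca = 70 * 365) {
  vals <- c(ing_r = ing_r, inh_r = inh_r, ef_d = ef_d, ed = ed, bw = bw,
            sa = sa, af = af, pef = pef, at_ca = at_ca)
  if (any(vals <= 0)) {
    stop("exposure parameters must be strictly positive: ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  }
  if (ef_d > 365) stop("ef_d must be <= 365 days/year")
  at_nc <- ed * 365
  if (at_ca < at_nc) stop("at_ca must be >= at_nc = ed * 365")
  structure(list(receptor = receptor, ing_r = ing_r, inh_r = inh_r,
                 ef_d = ef_d, ed = ed, bw = bw, at_nc = at_nc,
                 at_ca = at_ca, sa = sa, af = af, pef = pef),
            class = "exposure_profile")
}

#' Default child and adult exposure profiles
#'
#' Standard RAGS/RSL residential soil-exposure defaults: child IngR 200
#' mg/day, InhR 7.6 m^3/day, BW 15 kg, ED 6 y, SA 2800 cm^2, AF 0.2;
#' adult IngR 100, InhR 20, BW 70, ED 24, SA 5700, AF 0.07; both with
#' EF 350 days/year and PEF 1.36e9 m^3/kg. Fully overridable via
#' [exposure_profile()] or a CSV with the same columns.
#'
#' @param path Optional CSV overriding the packaged defaults.
#' @return Named list of [exposure_profile()]s (one per receptor).
#' @export
default_exposure_profiles <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("exposure_profiles.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  profs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    exposure_profile(r$receptor, r$ing_r, r$inh_r, r$ef_d, r$ed, r$bw,
                     r$sa, r$af, pef = r$pef, at_ca = r$at_ca)
  })
  stats::setNames(profs, df$receptor)
}

#' Default toxicity registry
#'
#' Per-metal reference doses (mg/kg/day) and cancer slope factors
#' ((mg/kg/day)^-1) for the ingestion, inhalation and dermal pathways, plus
#' the dermal absorption fraction. Defaults follow IRIS/RSL conventions
#' (dermal RfD = oral RfD x gastrointestinal absorption fraction where no
#' direct value exists); each row carries a provenance string. Metals
#' without any accepted slope factor are non-carcinogenic-only and appear
#' only in HQ/HI outputs.
#'
#' @param path Optional CSV overriding the packaged registry (same columns).
#' @return Data.frame with columns `metal`, `rfd_ing`, `rfd_inh`,
#'   `rfd_derm`, `csf_ing`, `csf_inh`, `csf_derm`, `abs`, `provenance`.
#' @export
default_toxicity <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("toxicity.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- c("rfd_ing", "rfd_inh", "rfd_derm", "csf_ing", "csf_inh",
           "csf_derm", "abs")
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  if (any(df$abs <= 0 | df$abs > 1)) stop("abs must be in (0, 1]")
  df
}

tox_row <- function(tox, metal) {
  r <- tox[tox$metal == metal, ]
  if (nrow(r) != 1) stop("toxicity registry lacks metal: ", metal)
  r
}

check_dose_inputs <- function(c_soil, p, at) {
  stopifnot(inherits(p, "exposure_profile"))
  if (any(c_soil < 0) || any(is.na(c_soil))) {
    stop("c_soil must be non-negative")
  }
  if (any(at <= 0)) stop("averaging time must be > 0")
}

#' Average daily intake via soil ingestion
#'
#' \deqn{ADI_{ing} = \frac{C_{soil}\, IngR\, EF\, ED}{BW\, AT} \times 10^{-6}}
#' The 1e-6 factor converts mg of metal per kg of soil times mg of soil per
#' day into mg of metal per day.
#'
#' @param c_soil Soil concentration, mg/kg (zero allowed for linearity
#'   checks; negative is an error).
#' @param p An [exposure_profile()].
#' @param at Averaging time in days: `p$at_nc` (default) for
#'   non-carcinogenic doses, `p$at_ca` for carcinogenic doses.
#' @return Dose in mg/kg/day. Vectorized over `c_soil`.
#' @export
adi_ingestion <- function(c_soil, p, at = p$at_nc) {
  check_dose_inputs(c_soil, p, at)
  c_soil * p$ing_r * p$ef_d * p$ed / (p$bw * at) * 1e-6
}

#' Average daily intake via dust inhalation
#'
#' \deqn{ADI_{inh} = \frac{C_{soil}\, InhR\, EF\, ED}{BW\, AT\, PEF}}
#' No 1e-6 factor: the particle emission factor (m^3/kg) already carries the
#' soil-mass-to-air conversion.
#'
#' @inheritParams adi_ingestion
#' @return Dose in mg/kg/day. Vectorized over `c_soil`.
#' @export
adi_inhalation <- function(c_soil, p, at = p$at_nc) {
  check_dose_inputs(c_soil, p, at)
  c_soil * p$inh_r * p$ef_d * p$ed / (p$bw * at * p$pef)
}

#' Average daily intake via dermal contact
#'
#' \deqn{ADI_{derm} = \frac{C_{soil}\, SA\, AF\, ABS\, EF\, ED}{BW\, AT}
#'   \times 10^{-6}}
#'
#' @inheritParams adi_ingestion
#' @param abs Dermal absorption fraction, in (0, 1]; zero allowed for
#'   boundary checks.
#' @return Dose in mg/kg/day. Vectorized over `c_soil`.
#' @export
adi_dermal <- function(c_soil, p, abs, at = p$at_nc) {
  check_dose_inputs(c_soil, p, at)
  if (any(abs < 0) || any(abs > 1)) stop("abs must be in [0, 1]")
  c_soil * p$sa * p$af * abs * p$ef_d * p$ed / (p$bw * at) * 1e-6
}

#' Hazard quotients and hazard index
#'
#' Divides each pathway dose by its reference dose; the hazard index is the
#' sum of the three quotients. HI below 1 denotes no significant
#' non-carcinogenic effect; at or above 1, an adverse risk.
#'
#' @param adi Named numeric vector `c(ing = , inh = , derm = )` of
#'   non-carcinogenic daily doses (mg/kg/day).
#' @param tox One row of [default_toxicity()] (or the registry plus a
#'   `metal` to select).
#' @param metal Metal symbol, required when `tox` is the full registry.
#' @return Named list `hq_ing`, `hq_inh`, `hq_derm`, `hi`, `hi_class`.
#' @export
hazard_quotients <- function(adi, tox, metal = NULL) {
  if (!is.null(metal)) tox <- tox_row(tox, metal)
  stopifnot(all(c("ing", "inh", "derm") %in% names(adi)))
  rfd <- c(ing = tox$rfd_ing, inh = tox$rfd_inh, derm = tox$rfd_derm)
  missing <- names(rfd)[is.na(rfd)]
  if (length(missing) > 0) {
    stop("missing RfD for metal ", tox$metal, ", pathway(s): ",
         paste(missing, collapse = ", "))
  }
  hq <- as.numeric(adi[c("ing", "inh", "derm")]) / as.numeric(rfd)
  hi <- sum(hq)
  list(hq_ing = hq[1], hq_inh = hq[2], hq_derm = hq[3], hi = hi,
       hi_class = classify_index(hi, class_scheme("hq")))
}

#' Pathway cancer risks and total cancer risk
#'
#' Multiplies each carcinogenic (lifetime-averaged) dose by its cancer slope
#' factor; pathways with no slope factor contribute zero and are flagged.
#' TCR below 1e-6 is insignificant, 1e-6 to 1e-4 tolerable, above 1e-4
#' unacceptable.
#'
#' @param adi Named numeric vector `c(ing = , inh = , derm = )` of doses
#'   computed with the carcinogenic averaging time `at_ca`.
#' @inheritParams hazard_quotients
#' @return Named list `cr_ing`, `cr_inh`, `cr_derm`, `tcr`, `tcr_class`,
#'   `pathways_without_csf`.
#' @export
cancer_risks <- function(adi, tox, metal = NULL) {
  if (!is.null(metal)) tox <- tox_row(tox, metal)
  stopifnot(all(c("ing", "inh", "derm") %in% names(adi)))
  csf <- c(ing = tox$csf_ing, inh = tox$csf_inh, derm = tox$csf_derm)
  if (all(is.na(csf))) {
    stop("metal ", tox$metal,
         " has no cancer slope factor (non-carcinogenic only)")
  }
  absent <- names(csf)[is.na(csf)]
  csf[is.na(csf)] <- 0
  cr <- as.numeric(adi[c("ing", "inh", "derm")]) * as.numeric(csf)
  tcr <- sum(cr)
  list(cr_ing = cr[1], cr_inh = cr[2], cr_derm = cr[3], tcr = tcr,
       tcr_class = classify_index(tcr, class_scheme("tcr")),
       pathways_without_csf = absent)
}

#' Deterministic risk report for a sample table
#'
#' Evaluates the full exposure-dose and risk model for every combination of
#' sample, metal and receptor: non-carcinogenic doses and hazard quotients
#' (averaging time `at_nc`), and for metals with at least one slope factor,
#' lifetime-averaged doses and cancer risks (`at_ca`). Metals with no slope
#' factor at all are excluded from the cancer columns with a notice.
#'
#' @param table A [sample_table()].
#' @param profiles Named list of [exposure_profile()]s
#'   (default [default_exposure_profiles()]).
#' @param tox Toxicity registry (default [default_toxicity()]).
#' @return Data.frame of class `"risk_report"`, one row per (sample, metal,
#'   receptor) with dose, HQ/HI, CR/TCR and class columns (`NA` cancer
#'   columns for non-carcinogenic-only metals).
#' @export
#' @examples
#' tab <- moment_match(reference_stats(), n = 20, seed = 1)
#' rr <- risk_report(tab)
#' risk_summary(rr)
risk_report <- function(table, profiles = default_exposure_profiles(),
                        tox = default_toxicity()) {
  metals <- table_metals(table)
  missing_tox <- setdiff(metals, tox$metal)
  if (length(missing_tox) > 0) {
    stop("toxicity registry lacks metal(s): ",
         paste(missing_tox, collapse = ", "))
  }
  no_csf <- metals[vapply(metals, function(m) {
    r <- tox_row(tox, m)
    all(is.na(c(r$csf_ing, r$csf_inh, r$csf_derm)))
  }, logical(1))]
  if (length(no_csf) > 0) {
    message("metal(s) without cancer slope factor, excluded from TCR: ",
            paste(no_csf, collapse = ", "))
  }
  sc_hq <- class_scheme("hq"); sc_tcr <- class_scheme("tcr")
  out <- list()
  for (rec in names(profiles)) {
    p <- profiles[[rec]]
    for (m in metals) {
      r <- tox_row(tox, m)
      conc <- table[[m]]
      adi_ing <- adi_ingestion(conc, p)
      adi_inh <- adi_inhalation(conc, p)
      adi_derm <- adi_dermal(conc, p, r$abs)
      hq_ing <- adi_ing / r$rfd_ing
      hq_inh <- adi_inh / r$rfd_inh
      hq_derm <- adi_derm / r$rfd_derm
      hi <- hq_ing + hq_inh + hq_derm
      carcinogenic <- !(m %in% no_csf)
      if (carcinogenic) {
        ca_ing <- adi_ingestion(conc, p, at = p$at_ca)
        ca_inh <- adi_inhalation(conc, p, at = p$at_ca)
        ca_derm <- adi_dermal(conc, p, r$abs, at = p$at_ca)
        cr_ing <- ca_ing * ifelse(is.na(r$csf_ing), 0, r$csf_ing)
        cr_inh <- ca_inh * ifelse(is.na(r$csf_inh), 0, r$csf_inh)
        cr_derm <- ca_derm * ifelse(is.na(r$csf_derm), 0, r$csf_derm)
        tcr <- cr_ing + cr_inh + cr_derm
        tcr_class <- classify_index(tcr, sc_tcr)
      } else {
        cr_ing <- cr_inh <- cr_derm <- tcr <- rep(NA_real_, length(conc))
        tcr_class <- rep(NA_character_, length(conc))
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = table$sample_id, metal = m, receptor = rec,
        conc = conc,
        adi_ing = adi_ing, adi_inh = adi_inh, adi_derm = adi_derm,
        hq_ing = hq_ing, hq_inh = hq_inh, hq_derm = hq_derm, hi = hi,
        hi_class = classify_index(hi, sc_hq),
        carcinogenic = carcinogenic,
        cr_ing = cr_ing, cr_inh = cr_inh, cr_derm = cr_derm, tcr = tcr,
        tcr_class = tcr_class,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("risk_report", "data.frame")
  res
}

#' Summary percentiles of a deterministic risk report
#'
#' @param report A [risk_report()].
#' @param probs Percentiles across samples (default 5th, 50th, 95th).
#' @return Data.frame with one row per (metal, receptor) and percentile
#'   columns for HI and TCR.
#' @export
risk_summary <- function(report, probs = c(0.05, 0.5, 0.95)) {
  key <- interaction(report$metal, report$receptor, drop = TRUE)
  rows <- lapply(split(as.data.frame(report), key), function(d) {
    qs_hi <- stats::quantile(d$hi, probs, names = FALSE)
    qs_tcr <- if (all(is.na(d$tcr))) rep(NA_real_, length(probs)) else
      stats::quantile(d$tcr, probs, names = FALSE)
    out <- data.frame(metal = d$metal[1], receptor = d$receptor[1],
                      stringsAsFactors = FALSE)
    for (i in seq_along(probs)) {
      out[[sprintf("hi_p%g", 100 * probs[i])]] <- qs_hi[i]
      out[[sprintf("tcr_p%g", 100 * probs[i])]] <- qs_tcr[i]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
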