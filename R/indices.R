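#' Enrichment factor
#'
#' Double ratio of a metal to the conservative reference element (Fe) in the
#' sample versus the background:
#' \deqn{EF = \frac{(C_n / C_{Fe})_{sample}}{(B_n / B_{Fe})_{background}}}
#' Values near 1 indicate purely lithogenic origin; larger values indicate
#' anthropogenic enrichment.
#'
#' @param c_n Metal concentration in the sample (mg/kg, > 0).
#' @param c_ref Reference-element (Fe) concentration in the sample (mg/kg).
#' @param b_n Background concentration of the metal (mg/kg).
#' @param b_ref Background concentration of the reference element (mg/kg).
#' @return Dimensionless enrichment factor. Vectorized over its arguments.
#' @export
#' @examples
#' enrichment_factor(10, 20000, 0.3, 47200)  # 78.67
enrichment_factor <- function(c_n, c_ref, b_n, b_ref) {
  check_positive(c_n = c_n, c_ref = c_ref, b_n = b_n, b_ref = b_ref)
  (c_n / c_ref) / (b_n / b_ref)
}

#' Geo-accumulation index
#'
#' \deqn{I_{geo} = \log_2\!\left(\frac{C_n}{1.5\,B_n}\right)}
#' The factor 1.5 absorbs natural lithogenic variation in the background.
#' Negative values indicate concentrations below 1.5x background.
#'
#' @param c_n Measured concentration (mg/kg, > 0).
#' @param b_n Background concentration (mg/kg, > 0).
#' @return Dimensionless index (may be negative). Vectorized.
#' @export
#' @examples
#' geoaccumulation_index(12, 0.3)   # 4.74
#' geoaccumulation_index(5.1, 13)   # -1.93
geoaccumulation_index <- function(c_n, b_n) {
  check_positive(c_n = c_n, b_n = b_n)
  log2(c_n / (1.5 * b_n))
}

#' Contamination factor
#'
#' Simple concentration-to-background ratio \eqn{CF = C / B}.
#'
#' @param c_metal Measured concentration (mg/kg, > 0).
#' @param c_background Background concentration (mg/kg, > 0).
#' @return Dimensionless contamination factor. Vectorized.
#' @export
#' @examples
#' contamination_factor(5.27, 0.3)  # 17.57
contamination_factor <- function(c_metal, c_background) {
  check_positive(c_metal = c_metal, c_background = c_background)
  c_metal / c_background
}

#' Pollution load index
#'
#' Geometric mean of a sample's contamination factors across metals,
#' \eqn{PLI = (\prod_i CF_i)^{1/n}}. Values above 1 indicate overall
#' pollution.
#'
#' @param cfs Numeric vector of contamination factors (> 0, non-empty).
#' @return Dimensionless pollution load index.
#' @export
#' @examples
#' pollution_load_index(c(2, 8))  # 4
pollution_load_index <- function(cfs) {
  if (length(cfs) == 0) stop("cfs must be non-empty")
  check_positive(cfs = cfs)
  exp(mean(log(cfs)))
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
      stop("'", nm, "' must be strictly positive")
    }
  }
  invisible(TRUE)
}

#' Classification scheme for a pollution or risk index
#'
#' Returns the packaged scheme for one index: an ordered set of contiguous
#' left-closed intervals `[lower, upper)` with qualitative labels. The
#' packaged schemes follow the canonical sources: seven Muller classes for
#' Igeo, five enrichment groups for EF, four Hakanson groups for CF, four
#' groups for PLI, plus the HI and TCR risk bands. Boundary values belong to
#' the upper class.
#'
#' @param index One of `"igeo"`, `"ef"`, `"cf"`, `"pli"`, `"hq"`, `"tcr"`.
#' @param path Optional CSV overriding the packaged scheme file (columns
#'   `index`, `lower`, `upper`, `label`), so bounds can be corrected without
#'   code changes.
#' @return A data.frame of class `"class_scheme"` with columns `lower`,
#'   `upper`, `label`.
#' @export
class_scheme <- function(index = c("igeo", "ef", "cf", "pli", "hq", "tcr"),
                         path = NULL) {
  index <- match.arg(index)
  if (is.null(path)) path <- extdata_path("class_schemes.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$index == index, c("lower", "upper", "label")]
  if (nrow(df) == 0) stop("no classification scheme for index: ", index)
  df <- df[order(df$lower), ]
  if (any(df$upper[-nrow(df)] != df$lower[-1])) {
    stop("scheme intervals for ", index, " are not contiguous")
  }
  rownames(df) <- NULL
  structure(df, class = c("class_scheme", "data.frame"))
}

#' Classify index values against a scheme
#'
#' Assigns each value the label of the interval containing it; a value
#' exactly on a bound belongs to the upper class (left-closed intervals).
#'
#' @param value Numeric vector of index values.
#' @param scheme A [class_scheme()].
#' @return Character vector of labels, same length as `value`.
#' @export
#' @examples
#' classify_index(c(-0.5, 0, 4.74), class_scheme("igeo"))
classify_index <- function(value, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  idx <- findInterval(value, scheme$lower)
  idx[idx < 1] <- 1L           # below the first lower bound (e.g. -Inf case)
  scheme$label[idx]
}

#' Full pollution-index report for a sample table
#'
#' Computes EF, Igeo and CF per sample and metal (EF normalized to Fe), the
#' per-sample PLI (geometric mean of that sample's CFs), qualitative class
#' labels for each value, and min/max/mean summaries across samples.
#'
#' @param table A [sample_table()] that includes Fe (needed for EF).
#' @param background A [background_values()] set covering all metals in
#'   `table`.
#' @return List of class `"index_report"` with elements:
#'   \describe{
#'     \item{per_sample}{long data.frame: `sample_id`, `metal`, `conc`,
#'       `ef`, `igeo`, `cf` and their class labels}
#'     \item{pli}{data.frame: `sample_id`, `pli`, `pli_class`}
#'     \item{summary}{per-metal min/max/mean of each index plus a PLI row}
#'   }
#' @export
#' @examples
#' tab <- moment_match(reference_stats(), n = 20, seed = 1)
#' rep <- index_report(tab, background_values("ASV"))
#' subset(rep$summary, metal == "Cd")
index_report <- function(table, background = background_values("ASV")) {
  stopifnot(inherits(background, "background_set"))
  metals <- table_metals(table)
  missing_bg <- setdiff(metals, names(background$values))
  if (length(missing_bg) > 0) {
    stop("background set '", background$name, "' lacks metal(s): ",
         paste(missing_bg, collapse = ", "))
  }
  if (!"Fe" %in% metals) {
    stop("sample table must include Fe (reference element for EF)")
  }
  bg <- background$values
  conc <- as.matrix(as.data.frame(table)[, metals, drop = FALSE])
  n <- nrow(conc)

  ef <- sapply(metals, function(m) {
    enrichment_factor(conc[, m], conc[, "Fe"], bg[[m]], bg[["Fe"]])
  })
  igeo <- sapply(metals, function(m) geoaccumulation_index(conc[, m], bg[[m]]))
  cf <- sapply(metals, function(m) contamination_factor(conc[, m], bg[[m]]))
  ef <- matrix(ef, nrow = n, dimnames = list(NULL, metals))
  igeo <- matrix(igeo, nrow = n, dimnames = list(NULL, metals))
  cf <- matrix(cf, nrow = n, dimnames = list(NULL, metals))
  pli <- apply(cf, 1, pollution_load_index)

  sc <- list(ef = class_scheme("ef"), igeo = class_scheme("igeo"),
             cf = class_scheme("cf"), pli = class_scheme("pli"))
  per_sample <- data.frame(
    sample_id = rep(table$sample_id, times = length(metals)),
    metal = rep(metals, each = n),
    conc = as.vector(conc),
    ef = as.vector(ef),
    igeo = as.vector(igeo),
    cf = as.vector(cf),
    stringsAsFactors = FALSE
  )
  per_sample$ef_class <- classify_index(per_sample$ef, sc$ef)
  per_sample$igeo_class <- classify_index(per_sample$igeo, sc$igeo)
  per_sample$cf_class <- classify_index(per_sample$cf, sc$cf)

  summarize_index <- function(mat, name) {
    data.frame(index = name, metal = metals,
               min = apply(mat, 2, min), max = apply(mat, 2, max),
               mean = colMeans(mat), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  summary <- rbind(
    summarize_index(ef, "ef"),
    summarize_index(igeo, "igeo"),
    summarize_index(cf, "cf"),
    data.frame(index = "pli", metal = NA_character_, min = min(pli),
               max = max(pli), mean = mean(pli), stringsAsFactors = FALSE)
  )

  structure(list(
    per_sample = per_sample,
    pli = data.frame(sample_id = table$sample_id, pli = pli,
                     pli_class = classify_index(pli, sc$pli),
                     stringsAsFactors = FALSE),
    summary = summary,
    background = background$name
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("<index_report> background = %s\n", x$background))
  cat("Per-metal summary (min/max/mean across samples):\n")
  print(x$summary, digits = 4)
  invisible(x)
}
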