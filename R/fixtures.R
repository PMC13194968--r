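#' Packaged reference statistics for a smelter-impacted site
#'
#' Per-metal descriptive statistics (min, max, mean, SD, CV%, skewness,
#' excess kurtosis; all concentrations in mg/kg) for a 20-sample survey of
#' agricultural topsoil around a steel-smelter point source. These values
#' ship with the package so that index computations and end-to-end tests can
#' run without any site data; [moment_match()] can turn them back into a
#' concrete sample table.
#'
#' @return Data.frame with one row per metal, columns `metal`, `min`, `max`,
#'   `mean`, `sd`, `cv_percent`, `skewness`, `kurtosis`.
#' @seealso [background_values()], [moment_match()]
#' @export
#' @examples
#' reference_stats()
reference_stats <- function() {
  df <- utils::read.csv(extdata_path("reference_stats.csv"),
                        stringsAsFactors = FALSE)
  df$metal <- as.character(df$metal)
  df
}

#' Geochemical background concentration sets
#'
#' Returns one of the two packaged background sets: ASV (average shale
#' values, the default reference for all index computation in this package)
#' or UCC (upper continental crust, retained for context ratios only).
#' Values are mg/kg.
#'
#' @param set `"ASV"` or `"UCC"`.
#' @return An object of class `"background_set"`: a list with `name` and a
#'   named numeric vector `values` (one entry per metal).
#' @export
#' @examples
#' background_values("ASV")$values[["Cd"]]  # 0.3 mg/kg
background_values <- function(set = c("ASV", "UCC")) {
  set <- match.arg(set)
  df <- utils::read.csv(extdata_path("backgrounds.csv"),
                        stringsAsFactors = FALSE)
  df <- df[df$set == set, ]
  values <- stats::setNames(df$value, df$metal)[soil_metals()]
  stopifnot(all(values > 0))
  structure(list(name = set, values = values), class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat(sprintf("<background_set> %s (mg/kg)\n", x$name))
  print(x$values)
  invisible(x)
}

#' Load the full packaged reference fixture
#'
#' Convenience bundle of the reference site statistics and both background
#' sets, as used by the worked examples and the acceptance workflow.
#'
#' @return List with elements `stats` (see [reference_stats()]), `asv` and
#'   `ucc` (see [background_values()]).
#' @export
load_reference_fixture <- function() {
  list(stats = reference_stats(),
       asv = background_values("ASV"),
       ucc = background_values("UCC"))
}
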