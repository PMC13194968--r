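#' Validate and construct a soil sample table
#'
#' A sample table is a plain `data.frame` with a `sample_id` column, optional
#' `easting`/`northing` coordinates, and one strictly positive numeric
#' concentration column (mg/kg) per metal. Positivity is required because
#' every downstream index takes a ratio or a logarithm of the
#' concentrations.
#'
#' @param df A data.frame with `sample_id` and metal concentration columns.
#' @param metals Character vector of metal columns expected in `df`. Must be
#'   a subset of [soil_metals()].
#' @return The validated data.frame with class `"sample_table"` and the
#'   metal set stored in the `"metals"` attribute. Row order is preserved.
#' @export
#' @examples
#' df <- data.frame(sample_id = c("S1", "S2"), Cd = c(1.2, 3.4),
#'                  Pb = c(50, 120))
#' sample_table(df, metals = c("Cd", "Pb"))
sample_table <- function(df, metals = soil_metals()) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) {
    stop("sample table must have a 'sample_id' column")
  }
  unknown <- setdiff(metals, soil_metals())
  if (length(unknown) > 0) {
    stop("unknown metal(s): ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(metals, names(df))
  if (length(missing_cols) > 0) {
    stop("missing metal column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (m in metals) {
    x <- df[[m]]
    if (!is.numeric(x)) {
      stop("non-numeric concentration column: ", m)
    }
    bad <- which(is.na(x) | x <= 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "non-positive or missing concentration for metal %s in sample '%s' (row %d)",
        m, ids[bad[1]], bad[1]))
    }
  }
  df$sample_id <- ids
  structure(df, class = c("sample_table", "data.frame"), metals = metals)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d metals (%s)\n",
              nrow(x), length(attr(x, "metals")),
              paste(attr(x, "metals"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

table_metals <- function(table) {
  m <- attr(table, "metals")
  if (is.null(m)) intersect(soil_metals(), names(table)) else m
}

#' Read a soil sample table from CSV
#'
#' Expects a comma-separated, decimal-point file whose header names
#' `sample_id` and one column per metal; `easting`/`northing` columns are
#' carried along when present.
#'
#' @param path Path to the CSV file.
#' @param metals Metal columns that must be present (default: all known).
#' @return A validated [sample_table()]; row order is that of the file.
#' @export
read_samples <- function(path, metals = soil_metals()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  sample_table(df, metals = metals)
}

#' Write a soil sample table to CSV
#'
#' @param table A [sample_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Bias-adjusted sample skewness (adjusted Fisher-Pearson G1).
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Bias-adjusted sample excess kurtosis (G2).
sample_kurtosis <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Per-metal descriptive statistics of a sample table
#'
#' Computes min, max, mean, sample SD (n-1 denominator), coefficient of
#' variation in percent (100 * sd / mean), bias-adjusted sample skewness and
#' bias-adjusted excess kurtosis for every metal column.
#'
#' @param table A [sample_table()] with at least two samples.
#' @return A data.frame with one row per metal and columns `metal`, `min`,
#'   `max`, `mean`, `sd`, `cv_percent`, `skewness`, `kurtosis`.
#' @export
summarize_samples <- function(table) {
  metals <- table_metals(table)
  if (nrow(table) < 2) {
    stop("at least 2 samples are required (sample SD undefined for n < 2)")
  }
  rows <- lapply(metals, function(m) {
    x <- table[[m]]
    n <- length(x)
    data.frame(
      metal = m,
      min = min(x),
      max = max(x),
      mean = mean(x),
      sd = stats::sd(x),
      cv_percent = 100 * stats::sd(x) / mean(x),
      skewness = if (n >= 3) sample_skewness(x) else NA_real_,
      kurtosis = if (n >= 4) sample_kurtosis(x) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
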