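# Draw an n x P matrix of parameter values from a named list of dist_spec
# or fixed numbers. Columns are in the order of `dists`.
draw_parameters <- function(dists, n) {
  cols <- lapply(names(dists), function(nm) {
    d <- dists[[nm]]
    if (is.numeric(d) && length(d) == 1) return(rep(d, n))
    if (!inherits(d, "dist_spec")) {
      stop("parameter '", nm, "' must be a dist_spec or a fixed number")
    }
    dist_quantile(d, stats::runif(n))
  })
  names(cols) <- names(dists)
  cols
}

evaluate_model <- function(model, params, n) {
  y <- tryCatch(model(params), error = function(e) {
    stop("model evaluation failed: ", conditionMessage(e))
  })
  if (length(y) != n) stop("model must return one value per draw")
  bad <- which(!is.finite(y))
  if (length(bad) > 0) {
    vals <- vapply(params, function(p) p[bad[1]], numeric(1))
    stop("model returned a non-finite value at draw ", bad[1],
         " (parameters: ",
         paste(sprintf("%s = %.6g", names(vals), vals), collapse = ", "),
         ")")
  }
  y
}

mc_statistics <- function(y) {
  qs <- stats::quantile(y, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  c(mean = mean(y), sd = stats::sd(y), p5 = qs[1], p50 = qs[2], p95 = qs[3])
}

#' Monte Carlo propagation of parameter uncertainty through a risk model
#'
#' Draws `n` joint parameter vectors from the given distribution specs,
#' evaluates the (vectorized) model on each draw, and summarizes the output
#' distribution with its mean, SD, 5th/50th/95th percentiles (linear
#' interpolation of order statistics, R quantile type 7) and exceedance
#' probabilities against the requested thresholds.
#'
#' @param model Function taking a named list of equal-length numeric
#'   parameter vectors and returning the output vector (one value per
#'   draw). All risk models built by [build_hi_model()] /
#'   [build_tcr_model()] have this form.
#' @param dists Named list: each element a [dist_spec()] or a single fixed
#'   number.
#' @param n Number of iterations (default 10000).
#' @param seed Optional integer seed; identical `(seed, n, dists)` give
#'   bit-identical summaries.
#' @param thresholds Numeric vector of exceedance thresholds (e.g. 1 for
#'   HI, 1e-4 for TCR).
#' @param keep_draws Keep the output draws in the result (default FALSE).
#' @return List of class `"mc_summary"`: `stats` (named vector),
#'   `exceedance` (data.frame `threshold`, `p_exceed`), `n`, `seed`, and
#'   optionally `draws`.
#' @export
#' @examples
#' m <- function(p) p$x
#' run_simulation(m, list(x = dist_spec("uniform", min = 0, max = 1)),
#'                n = 1000, seed = 1, thresholds = 0.9)
run_simulation <- function(model, dists, n = 10000, seed = NULL,
                           thresholds = NULL, keep_draws = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  params <- draw_parameters(dists, n)
  y <- evaluate_model(model, params, n)
  exceed <- if (is.null(thresholds)) {
    data.frame(threshold = numeric(0), p_exceed = numeric(0))
  } else {
    data.frame(threshold = thresholds,
               p_exceed = vapply(thresholds, function(t) mean(y > t),
                                 numeric(1)))
  }
  out <- list(stats = mc_statistics(y), exceedance = exceed, n = n,
              seed = seed)
  if (keep_draws) out$draws <- y
  structure(out, class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> n = %d%s\n", x$n,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  print(round(x$stats, 6))
  if (nrow(x$exceedance) > 0) {
    for (i in seq_len(nrow(x$exceedance))) {
      cat(sprintf("P(output > %g) = %.4f\n", x$exceedance$threshold[i],
                  x$exceedance$p_exceed[i]))
    }
  }
  invisible(x)
}

#' Convergence diagnostics for a Monte Carlo model
#'
#' Draws `max(ns)` iterations once and compares the summary statistics
#' (mean, SD, P5, P50, P95) of each nested prefix of size `ns[i]` against
#' the largest run: `|stat(n_i) - stat(n_max)| / |stat(n_max)|`. Nested
#' prefixes share draws, which is the standard common-random-numbers
#' convergence diagnostic. Statistics whose relative difference exceeds
#' `tol` are flagged.
#'
#' @inheritParams run_simulation
#' @param ns Ascending iteration counts (default 5000, 10000, 15000).
#' @param tol Relative-difference tolerance (default 0.02, i.e. 2%).
#' @return Data.frame with columns `n`, `statistic`, `value`, `rel_diff`,
#'   `flag` (rows for `n = max(ns)` have `rel_diff = 0`).
#' @export
convergence_check <- function(model, dists, ns = c(5000, 10000, 15000),
                              seed = NULL, tol = 0.02) {
  ns <- as.integer(ns)
  if (is.unsorted(ns)) stop("ns must be sorted ascending")
  n_max <- max(ns)
  if (!is.null(seed)) set.seed(seed)
  params <- draw_parameters(dists, n_max)
  y <- evaluate_model(model, params, n_max)
  ref <- mc_statistics(y)
  rows <- lapply(ns, function(n) {
    s <- mc_statistics(y[seq_len(n)])
    rel <- ifelse(ref == 0, ifelse(s == 0, 0, Inf), abs(s - ref) / abs(ref))
    data.frame(n = n, statistic = names(s), value = unname(s),
               rel_diff = unname(rel), flag = unname(rel) > tol,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Deterministic per-(receptor, metal) seed stream derived from a master
# seed: master * 1009 + counter, folded into the 32-bit integer range.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1009 + counter) %% .Machine$integer.max)
}
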