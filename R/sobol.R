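#' Saltelli cross-sampling design for Sobol index estimation
#'
#' Builds the radial Saltelli design: two independent base matrices A and B
#' (each `n_base` rows, one column per parameter) plus the cross matrices
#' AB_i (A with column i taken from B) and BA_i, giving
#' `n_base * (2D + 2)` model evaluations and supporting first-, second- and
#' total-order estimation. The uniform base sample is a Latin hypercube
#' (stratified per dimension), transformed to the target marginals by
#' inverse CDF so the stratification is preserved.
#'
#' @param dists Named list of [dist_spec()]s, at least 2 parameters.
#' @param n_base Base sample size N (a power of two is recommended and
#'   warned about otherwise; default 1024).
#' @param seed Optional integer seed.
#' @return List of class `"saltelli_design"`: `X` (the evaluation matrix,
#'   `n_base * (2D + 2)` rows), `n_base`, `d`, `names`.
#' @export
saltelli_sample <- function(dists, n_base = 1024, seed = NULL) {
  d <- length(dists)
  if (d < 2) stop("at least 2 parameters are required")
  if (n_base < 2) stop("n_base must be >= 2")
  if (is.null(names(dists)) || any(!nzchar(names(dists)))) {
    stop("dists must be a fully named list")
  }
  if (abs(log2(n_base) - round(log2(n_base))) > 1e-12) {
    warning("n_base is not a power of two; estimator balance is better ",
            "when it is")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n_base, 2 * d)
  ua <- u[, seq_len(d), drop = FALSE]
  ub <- u[, d + seq_len(d), drop = FALSE]
  transform <- function(um) {
    out <- sapply(seq_len(d), function(j) dist_quantile(dists[[j]], um[, j]))
    matrix(out, nrow = n_base, dimnames = list(NULL, names(dists)))
  }
  a <- transform(ua)
  b <- transform(ub)
  blocks <- list(a, b)
  for (j in seq_len(d)) {        # AB_j
    m <- a; m[, j] <- b[, j]; blocks[[length(blocks) + 1]] <- m
  }
  for (j in seq_len(d)) {        # BA_j
    m <- b; m[, j] <- a[, j]; blocks[[length(blocks) + 1]] <- m
  }
  structure(list(X = do.call(rbind, blocks), n_base = n_base, d = d,
                 names = names(dists)), class = "saltelli_design")
}

sobol_blocks <- function(design, y) {
  n <- design$n_base; d <- design$d
  stopifnot(length(y) == n * (2 * d + 2))
  list(
    fa = y[seq_len(n)],
    fb = y[n + seq_len(n)],
    fab = lapply(seq_len(d), function(j) y[(1 + j) * n + seq_len(n)]),
    fba = lapply(seq_len(d), function(j) y[(1 + d + j) * n + seq_len(n)])
  )
}

sobol_estimate <- function(bl, d, idx = NULL) {
  if (!is.null(idx)) {
    fa <- bl$fa[idx]; fb <- bl$fb[idx]
    fab <- lapply(bl$fab, `[`, idx); fba <- lapply(bl$fba, `[`, idx)
  } else {
    fa <- bl$fa; fb <- bl$fb; fab <- bl$fab; fba <- bl$fba
  }
  # normalize by the base-block mean and SD: makes the estimators exactly
  # invariant under affine rescaling of the output
  mu <- mean(c(fa, fb)); s <- stats::sd(c(fa, fb))
  if (s > 0) {
    fa <- (fa - mu) / s; fb <- (fb - mu) / s
    fab <- lapply(fab, function(x) (x - mu) / s)
    fba <- lapply(fba, function(x) (x - mu) / s)
  }
  v <- stats::var(c(fa, fb))
  s1 <- vapply(seq_len(d), function(j) {
    mean(fb * (fab[[j]] - fa)) / v            # Saltelli 2010
  }, numeric(1))
  st <- vapply(seq_len(d), function(j) {
    0.5 * mean((fa - fab[[j]])^2) / v         # Jansen
  }, numeric(1))
  s2 <- matrix(NA_real_, d, d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      vij_closed <- mean(fba[[i]] * fab[[j]] - fa * fb) / v
      s2[i, j] <- s2[j, i] <- vij_closed - s1[i] - s1[j]
    }
  }
  list(s1 = s1, st = st, s2 = s2, v = v)
}

#' Sobol sensitivity indices from model outputs on a Saltelli design
#'
#' Estimates first-order indices with the Saltelli (2010) estimator,
#' total-order indices with the Jansen estimator, and second-order indices
#' from the closed pairwise variances. Negative estimates (possible for
#' indices near zero at finite N) are reported as-is: clipping would hide
#' non-convergence. Confidence half-widths are 1.96 x bootstrap SE over
#' resampled design rows.
#'
#' @param design A [saltelli_sample()] design.
#' @param y Numeric vector of model outputs on `design$X`, row for row.
#' @param n_boot Bootstrap resamples for confidence half-widths
#'   (default 100; 0 disables).
#' @return List of class `"sobol_result"`: `indices` (data.frame
#'   `parameter`, `s1`, `s1_conf`, `st`, `st_conf`), `s2` (symmetric matrix
#'   of second-order indices), `n_base`, `n_evaluations`, `variance`.
#' @export
sobol_indices <- function(design, y, n_boot = 100) {
  stopifnot(inherits(design, "saltelli_design"))
  if (any(!is.finite(y))) stop("model outputs must be finite")
  bl <- sobol_blocks(design, y)
  if (stats::var(c(bl$fa, bl$fb)) == 0) {
    stop("constant model: output variance is zero")
  }
  est <- sobol_estimate(bl, design$d)
  s1_conf <- st_conf <- rep(NA_real_, design$d)
  if (n_boot > 0) {
    bs1 <- matrix(0, n_boot, design$d)
    bst <- matrix(0, n_boot, design$d)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(design$n_base, replace = TRUE)
      e <- sobol_estimate(bl, design$d, idx)
      bs1[b, ] <- e$s1; bst[b, ] <- e$st
    }
    s1_conf <- 1.96 * apply(bs1, 2, stats::sd)
    st_conf <- 1.96 * apply(bst, 2, stats::sd)
  }
  dimnames(est$s2) <- list(design$names, design$names)
  structure(list(
    indices = data.frame(parameter = design$names, s1 = est$s1,
                         s1_conf = s1_conf, st = est$st, st_conf = st_conf,
                         stringsAsFactors = FALSE),
    s2 = est$s2, n_base = design$n_base,
    n_evaluations = design$n_base * (2 * design$d + 2),
    variance = est$v
  ), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> N = %d, %d model evaluations\n",
              x$n_base, x$n_evaluations))
  print(x$indices, digits = 4, row.names = FALSE)
  invisible(x)
}

#' One-call Sobol analysis of a model
#'
#' Builds the Saltelli design, evaluates the vectorized model, and returns
#' the indices.
#'
#' @param model Vectorized model as for [run_simulation()].
#' @param dists Named list of [dist_spec()]s.
#' @param n_base Base sample size (default 1024).
#' @param seed Optional seed.
#' @param n_boot Passed to [sobol_indices()].
#' @return A `"sobol_result"`.
#' @export
#' @examples
#' dists <- list(x1 = dist_spec("uniform", min = 0, max = 1),
#'               x2 = dist_spec("uniform", min = 0, max = 1))
#' sobol_run(function(p) 2 * p$x1 + p$x2, dists, n_base = 256, seed = 1)
sobol_run <- function(model, dists, n_base = 1024, seed = NULL,
                      n_boot = 100) {
  design <- saltelli_sample(dists, n_base, seed = seed)
  params <- lapply(seq_len(design$d),
                   function(j) design$X[, j])
  names(params) <- design$names
  y <- evaluate_model(model, params, nrow(design$X))
  sobol_indices(design, y, n_boot = n_boot)
}

#' Rank parameters by total-order sensitivity
#'
#' Parameters whose total-order index exceeds the cutoff, in descending
#' order of total-order index. The conventional cutoff of 0.1 marks the
#' critical drivers of output variance.
#'
#' @param result A `"sobol_result"`.
#' @param cutoff Minimum total-order index (default 0.1; 0 returns all
#'   parameters sorted).
#' @return Data.frame `parameter`, `st`, `s1`, sorted by `st` descending.
#' @export
rank_parameters <- function(result, cutoff = 0.1) {
  stopifnot(inherits(result, "sobol_result"))
  idx <- result$indices
  keep <- idx[idx$st > cutoff, c("parameter", "st", "s1")]
  keep <- keep[order(-keep$st), ]
  rownames(keep) <- NULL
  keep
}
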