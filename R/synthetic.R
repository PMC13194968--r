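#' Specify a synthetic point-source contamination site
#'
#' Describes a site where each metal's concentration decays exponentially
#' with distance from a single point source on top of a geochemical
#' background, with multiplicative lognormal noise:
#' \deqn{C_i = [b + A \exp(-d_i/\lambda)] \, e^{\epsilon_i}, \quad
#'       \epsilon_i \sim N(0, \sigma^2)}
#' Multiplicative noise keeps every concentration strictly positive and
#' produces the right-skewed, leptokurtic distributions typical of
#' smelter-impacted topsoil.
#'
#' @param metals Data.frame with columns `metal`, `background` (mg/kg, > 0),
#'   `amplitude` (mg/kg, >= 0), `decay_length` (distance units, > 0) and
#'   `noise_sigma` (log-scale SD, >= 0).
#' @param n_samples Number of samples (default 20).
#' @param coords Optional two-column matrix of sample coordinates. Default
#'   `NULL` lays the samples on a 5 x 4 grid with unit spacing.
#' @param source Source location, length-2 numeric (default the origin).
#' @param seed Integer RNG seed stored with the spec; `generate_site()` is
#'   fully reproducible given this seed.
#' @return An object of class `"site_spec"`.
#' @seealso [generate_site()], [default_site_spec()]
#' @export
site_spec <- function(metals, n_samples = 20, coords = NULL,
                      source = c(0, 0), seed = 1L) {
  stopifnot(is.data.frame(metals),
            all(c("metal", "background", "amplitude", "decay_length",
                  "noise_sigma") %in% names(metals)))
  if (any(metals$background <= 0)) stop("background_level must be > 0")
  if (any(metals$amplitude < 0)) stop("source_amplitude must be >= 0")
  if (any(metals$decay_length <= 0)) stop("decay_length must be > 0")
  if (any(metals$noise_sigma < 0)) stop("noise_sigma must be >= 0")
  unknown <- setdiff(metals$metal, soil_metals())
  if (length(unknown) > 0) {
    stop("unknown metal(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(coords)) {
    nx <- ceiling(sqrt(n_samples))
    grid <- expand.grid(x = seq_len(nx) - 1,
                        y = seq_len(ceiling(n_samples / nx)) - 1)
    coords <- as.matrix(grid[seq_len(n_samples), ])
  }
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n_samples, ncol(coords) == 2)
  structure(list(metals = metals, n_samples = n_samples, coords = coords,
                 source = source, seed = as.integer(seed)),
            class = "site_spec")
}

#' Default synthetic site emulating the packaged reference statistics
#'
#' Builds a [site_spec()] whose analytic expectations reproduce the
#' reference site's per-metal means: the background level is set to the
#' observed minimum (a far-field proxy), the log-noise SD is half the
#' lognormal-equivalent of the observed CV (the other half of the spread
#' comes from the spatial decay), and the source amplitude is solved from
#' \eqn{E[C] = [b + A \cdot \overline{\exp(-d/\lambda)}] e^{\sigma^2/2}} so
#' the generator's analytic mean equals the target mean.
#'
#' @param stats Target statistics, default [reference_stats()].
#' @param decay_length Shared decay length in grid units (default 2).
#' @param n_samples,seed Passed to [site_spec()].
#' @return A `"site_spec"`.
#' @export
default_site_spec <- function(stats = reference_stats(), decay_length = 2,
                              n_samples = 20, seed = 1L) {
  nx <- ceiling(sqrt(n_samples))
  grid <- expand.grid(x = seq_len(nx) - 1,
                      y = seq_len(ceiling(n_samples / nx)) - 1)
  coords <- as.matrix(grid[seq_len(n_samples), ])
  d <- sqrt(rowSums(coords^2))
  kernel_mean <- mean(exp(-d / decay_length))
  rows <- lapply(seq_len(nrow(stats)), function(i) {
    s <- stats[i, ]
    sigma <- 0.5 * sqrt(log1p((s$cv_percent / 100)^2))
    b <- s$min
    amp <- max(0, (s$mean * exp(-sigma^2 / 2) - b) / kernel_mean)
    data.frame(metal = s$metal, background = b, amplitude = amp,
               decay_length = decay_length, noise_sigma = sigma,
               stringsAsFactors = FALSE)
  })
  site_spec(do.call(rbind, rows), n_samples = n_samples, coords = coords,
            seed = seed)
}

#' Generate a synthetic sample table from a site specification
#'
#' @param spec A [site_spec()].
#' @return A [sample_table()] with `easting`/`northing` columns; identical
#'   for identical specs (including seed).
#' @export
#' @examples
#' spec <- default_site_spec(seed = 7)
#' site <- generate_site(spec)
#' summarize_samples(site)
generate_site <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  set.seed(spec$seed)
  d <- sqrt(colSums((t(spec$coords) - spec$source)^2))
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(spec$n_samples)),
                   easting = spec$coords[, 1], northing = spec$coords[, 2],
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(spec$metals))) {
    m <- spec$metals[i, ]
    mu <- m$background + m$amplitude * exp(-d / m$decay_length)
    eps <- if (m$noise_sigma > 0) {
      stats::rnorm(spec$n_samples, 0, m$noise_sigma)
    } else {
      rep(0, spec$n_samples)
    }
    df[[m$metal]] <- mu * exp(eps)
  }
  sample_table(df, metals = spec$metals$metal)
}

#' Build a sample table that exactly matches target min, max and mean
#'
#' Draws interior points at random, pins the extremes, and applies an affine
#' contraction of the interior toward the matched extreme so that the
#' per-metal minimum, maximum and mean equal the targets exactly. Higher
#' moments are not matched; min/max/mean is what the exactly reproducible
#' downstream summaries require, and matching SD or skewness simultaneously
#' would over-constrain a 20-point sample.
#'
#' @param target Data.frame with columns `metal`, `min`, `max`, `mean`
#'   (e.g. [reference_stats()]).
#' @param n Number of samples (default 20; `n = 2` only feasible when
#'   `mean == (min + max) / 2`).
#' @param seed RNG seed for the interior draws.
#' @return A [sample_table()] whose `summarize_samples()` min/max/mean
#'   reproduce `target` to floating-point accuracy.
#' @export
#' @examples
#' tab <- moment_match(reference_stats(), n = 20, seed = 1)
#' summarize_samples(tab)[, c("metal", "min", "max", "mean")]
moment_match <- function(target, n = 20, seed = 1L) {
  stopifnot(is.data.frame(target),
            all(c("metal", "min", "max", "mean") %in% names(target)))
  if (n < 2) stop("n must be >= 2")
  bad <- target$min >= target$max | target$mean < target$min |
    target$mean > target$max
  if (any(bad)) {
    stop("infeasible target for metal(s): ",
         paste(target$metal[bad], collapse = ", "),
         " (need min < max and min <= mean <= max)")
  }
  set.seed(seed)
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(target))) {
    t <- target[i, ]
    if (n == 2) {
      if (abs(t$mean - (t$min + t$max) / 2) > 1e-9 * max(1, abs(t$mean))) {
        stop("n = 2 is only feasible when mean = (min + max)/2 (metal ",
             t$metal, ")")
      }
      df[[t$metal]] <- c(t$min, t$max)
      next
    }
    interior <- stats::runif(n - 2, t$min, t$max)
    s_target <- n * t$mean - t$min - t$max   # required interior sum
    if (s_target < (n - 2) * t$min || s_target > (n - 2) * t$max) {
      stop("infeasible target for metal ", t$metal,
           ": mean too close to an extreme to pin both min and max at n = ",
           n)
    }
    s <- sum(interior)
    if (s > s_target) {
      # contract toward the minimum
      alpha <- (s_target - (n - 2) * t$min) / (s - (n - 2) * t$min)
      interior <- t$min + alpha * (interior - t$min)
    } else if (s < s_target) {
      alpha <- ((n - 2) * t$max - s_target) / ((n - 2) * t$max - s)
      interior <- t$max - alpha * (t$max - interior)
    }
    # exact mean up to rounding; spread residual over interior points
    interior <- interior + (s_target - sum(interior)) / (n - 2)
    df[[t$metal]] <- c(t$min, interior, t$max)
  }
  sample_table(df, metals = target$metal)
}
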