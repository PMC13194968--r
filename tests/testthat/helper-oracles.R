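# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# Two-pass moment oracle: min/max/mean/sd/cv/skew/kurtosis computed directly
# from the definitions (bias-adjusted sample estimators).
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  dev <- x - mu
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  s <- sqrt(sum(dev^2) / (n - 1))
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  list(
    min = min(x), max = max(x), mean = mu, sd = s,
    cv_percent = 100 * s / mu,
    skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
    kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  )
}

# Brute-force O(n^3) Ward clustering: at each step merge the pair of
# clusters whose fusion minimizes the increase in total within-cluster sum
# of squares; report heights on the ward.D2 scale, sqrt(2 * increase).
oracle_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          a <- x[clusters[[i]], , drop = FALSE]
          b <- x[clusters[[j]], , drop = FALSE]
          na <- nrow(a); nb <- nrow(b)
          d <- sum((colMeans(a) - colMeans(b))^2) * na * nb / (na + nb)
          if (d < best) { best <- d; bi <- i; bj <- j }
        }
      }
    }
    heights <- c(heights, sqrt(2 * best))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Analytic Ishigami variance decomposition (a sin^2 term, a quartic
# interaction term): total variance and closed-form S1/ST.
oracle_ishigami <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  list(v = v, s1 = c(v1 / v, v2 / v, 0),
       st = c((v1 + v13) / v, v2 / v, v13 / v))
}

ishigami_model <- function(a = 7, b = 0.1) {
  function(p) sin(p$x1) + a * sin(p$x2)^2 + b * p$x3^4 * sin(p$x1)
}

ishigami_dists <- function() {
  list(x1 = dist_spec("uniform", min = -pi, max = pi),
       x2 = dist_spec("uniform", min = -pi, max = pi),
       x3 = dist_spec("uniform", min = -pi, max = pi))
}

# Small helper: a valid two-metal-plus-Fe table for index tests.
tiny_table <- function() {
  sample_table(data.frame(
    sample_id = c("S1", "S2", "S3"),
    As = c(5, 10, 20), Pb = c(30, 60, 120), Zn = c(100, 150, 200),
    Fe = c(20000, 25000, 30000), Cd = c(0.5, 1, 2), Cu = c(20, 40, 60),
    Cr = c(80, 100, 120), Ni = c(50, 60, 70)))
}
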