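# shared in-code fixtures for the test suite

# a pattern of Gaussian peaks on a uniform grid
gaussian_pattern <- function(centers, heights, sigma = 0.1,
                             start = 5, step = 0.02, end = 40,
                             background_corrected = TRUE) {
  tt <- seq(start, end, by = step)
  y <- rep(0, length(tt))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-0.5 * ((tt - centers[i]) / sigma)^2)
  powder_pattern(start, step, y, background_corrected = background_corrected)
}

# a single-bin spike pattern
spike_pattern <- function(at_index, n = 200, step = 0.02, start = 10) {
  y <- rep(0, n)
  y[at_index] <- 1
  powder_pattern(start, step, y, background_corrected = TRUE)
}

# random non-negative pattern with a few smooth peaks
random_pattern <- function(n = 300, step = 0.02, start = 10, npeaks = 5) {
  tt <- start + step * (seq_len(n) - 1L)
  y <- rep(0, n)
  for (i in seq_len(npeaks)) {
    c0 <- stats::runif(1, min(tt), max(tt))
    h <- stats::runif(1, 0.2, 1)
    s <- stats::runif(1, 0.05, 0.2)
    y <- y + h * exp(-0.5 * ((tt - c0) / s)^2)
  }
  powder_pattern(start, step, y, background_corrected = TRUE)
}

# brute-force O(n^2) reference implementation of the weighted-correlation
# similarity, kept deliberately naive and independent of the package's path
s12_bruteforce <- function(p1, p2, l) {
  I1 <- p1$intensities; I2 <- p2$intensities
  n <- length(I1)
  step <- p1$step
  K <- floor(l / step)
  corr <- function(A, B) {
    tot <- 0
    for (k in -K:K) {
      w <- max(0, 1 - abs(k * step) / l)
      s <- 0
      for (i in seq_len(n)) {
        j <- i + k
        if (j >= 1 && j <= n) s <- s + A[i] * B[j]
      }
      tot <- tot + w * s
    }
    tot
  }
  corr(I1, I2) / sqrt(corr(I1, I1) * corr(I2, I2))
}

# small standard crystal fixtures
toy_p1_model <- function(seed = 7) {
  zm <- make_toy_molecule("planar_rigid")
  make_toy_structure(zm, space_group("P1"), seed = seed)
}

toy_pminus1_model <- function(seed = 202) {
  zm <- make_toy_molecule("planar_rigid")
  make_toy_structure(zm, space_group("P-1", Zprime = 0.5,
                                     site_symmetry = "-1"), seed = seed)
}

toy_cfg <- function() sim_config(two_theta_range = c(5, 35), step = 0.05,
                                 fwhm = 0.3)
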