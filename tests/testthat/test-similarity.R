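test_that("triangular weight has unit apex, FWHM l and bounded support", {
  expect_equal(weight_triangular(0, 0.7), 1)
  expect_equal(weight_triangular(0.35, 0.7), 0.5)  # at l/2: half maximum
  expect_equal(weight_triangular(1.05, 0.7), 0)
  expect_equal(weight_triangular(-0.2, 0.7), weight_triangular(0.2, 0.7))
  expect_error(weight_triangular(0, 0), "positive")
})

test_that("cross-correlation matches the defining double sum", {
  p <- spike_pattern(50)
  auto <- cross_correlation(p, p, l = 0.1)
  expect_equal(auto$value[auto$lag == 0], sum(p$intensities^2))

  # two unit spikes offset by 5 bins: profile 1 at lag +5 steps, 0 at lag 0
  q <- spike_pattern(55)
  cc <- cross_correlation(p, q, l = 0.2)
  expect_equal(cc$value[abs(cc$lag - 5 * p$step) < 1e-9], 1)
  expect_equal(cc$value[cc$lag == 0], 0)

  # random pair against a brute-force double loop
  set.seed(3)
  a <- random_pattern(n = 120)
  b <- random_pattern(n = 120)
  cc2 <- cross_correlation(a, b, l = 0.1)
  K <- floor(0.1 / a$step)
  for (k in -K:K) {
    manual <- 0
    for (i in seq_len(120)) {
      j <- i + k
      if (j >= 1 && j <= 120) manual <- manual + a$intensities[i] * b$intensities[j]
    }
    expect_equal(cc2$value[abs(cc2$lag - k * a$step) < 1e-9], manual,
                 tolerance = 1e-10)
  }
})

test_that("the similarity measure is exact against the brute-force oracle", {
  set.seed(11)
  for (rep in 1:4) {
    a <- random_pattern(n = 150)
    b <- random_pattern(n = 150)
    for (l in c(0.1, 0.5)) {
      expect_equal(s12(a, b, l = l)$value, s12_bruteforce(a, b, l),
                   tolerance = 1e-10)
    }
  }
})

test_that("self-similarity is exactly 1 and basic invariances hold", {
  set.seed(7)
  p <- random_pattern()
  for (l in c(0.05, 0.5, 2)) {
    expect_equal(s12(p, p, l = l)$value, 1, tolerance = 1e-12)
  }
  q <- random_pattern()
  v <- s12(p, q, l = 0.5)$value
  # symmetry
  expect_equal(s12(q, p, l = 0.5)$value, v, tolerance = 1e-12)
  # scale invariance
  q2 <- q; q2$intensities <- q$intensities * 123.4
  expect_equal(s12(p, q2, l = 0.5)$value, v, tolerance = 1e-12)
  # bounds for non-negative patterns
  expect_gte(v, 0); expect_lte(v, 1)
  # identically-zero pattern is rejected
  z <- powder_pattern(10, 0.02, rep(0, 300), background_corrected = TRUE)
  expect_error(s12(p, z, l = 0.5), "identically zero")
})

test_that("spike separation probes the tolerance window", {
  p <- spike_pattern(100)
  l <- 0.3
  # beyond the window: zero similarity
  far <- spike_pattern(100 + ceiling(1.5 * l / p$step))
  expect_equal(s12(p, far, l = l)$value, 0, tolerance = 1e-12)
  # within the window: strictly decreasing with separation
  seps <- 1:10
  vals <- vapply(seps, function(d)
    s12(p, spike_pattern(100 + d), l = l)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
  # and non-decreasing in l for a fixed separation
  shifted <- spike_pattern(105)
  ls <- c(0.12, 0.2, 0.4, 0.8)
  vl <- vapply(ls, function(li) s12(p, shifted, l = li)$value, numeric(1))
  expect_true(all(diff(vl) >= -1e-12))
})

test_that("the l -> 0 limit equals the Pearson coefficient on mean-free data", {
  set.seed(5)
  for (rep in 1:5) {
    a <- random_pattern(n = 200)
    b <- random_pattern(n = 200)
    # mean-free versions: the centered variant must equal stats::cor
    expect_equal(s12(a, b, zero_limit = TRUE, centered = TRUE)$value,
                 stats::cor(a$intensities, b$intensities),
                 tolerance = 1e-12)
    # uncentered limit equals the cosine of the vectors
    cosab <- sum(a$intensities * b$intensities) /
      sqrt(sum(a$intensities^2) * sum(b$intensities^2))
    expect_equal(s12(a, b, zero_limit = TRUE)$value, cosab,
                 tolerance = 1e-12)
  }
})

test_that("reference similarity is the scale-free full-range limit", {
  exp <- gaussian_pattern(c(12, 18, 25), c(1, 0.6, 0.3))
  expect_equal(reference_similarity(exp, exp)$value, 1, tolerance = 1e-12)
  expect_equal(reference_similarity(exp, exp)$variant, "reference_S12_bg0")

  scaled <- exp; scaled$intensities <- exp$intensities * 3.7
  expect_equal(reference_similarity(exp, scaled)$value, 1, tolerance = 1e-12)

  # one peak removed: equals the cosine of the two intensity vectors
  partial <- gaussian_pattern(c(12, 18), c(1, 0.6))
  cosv <- sum(exp$intensities * partial$intensities) /
    sqrt(sum(exp$intensities^2) * sum(partial$intensities^2))
  got <- reference_similarity(exp, partial)$value
  expect_lt(got, 1)
  expect_equal(got, cosv, tolerance = 1e-12)

  raw <- exp; raw$background_corrected <- FALSE
  expect_equal(reference_similarity(raw, partial)$variant, "reference_S12_0")
})

test_that("pairwise matrices are symmetric with unit diagonal", {
  p <- gaussian_pattern(12, 1)
  q <- gaussian_pattern(20, 1)
  M <- pairwise_matrix(list(p, p, q), l = 0.3)
  expect_equal(diag(M), rep(1, 3), tolerance = 1e-12)
  expect_equal(M[1, 2], 1, tolerance = 1e-12)
  expect_equal(M, t(M))
  expect_equal(M[1, 3], s12(p, q, l = 0.3)$value, tolerance = 1e-12)
  set.seed(9)
  pats <- replicate(6, random_pattern(), simplify = FALSE)
  M2 <- pairwise_matrix(pats, l = 0.2)
  expect_true(all(M2 >= 0))
})

test_that("candidate clustering merges duplicates and sums weights", {
  p <- gaussian_pattern(c(12, 20), c(1, 0.5))
  q <- gaussian_pattern(c(14, 26), c(1, 0.8))
  mk <- function(pat, ref, w, id) list(pattern = pat, ref_sim = ref,
                                       weight = w, id = id)
  # three exact duplicates: one representative with summed weight
  out <- cluster_candidates(list(mk(p, 0.99, 1, 1), mk(p, 0.98, 2, 2),
                                 mk(p, 0.97, 3, 3)))
  expect_length(out, 1L)
  expect_equal(out[[1]]$weight, 6)
  expect_equal(out[[1]]$ref_sim, 0.99)  # representative = highest reference

  # mutually dissimilar patterns stay separate
  out2 <- cluster_candidates(list(mk(p, 0.99, 1, 1), mk(q, 0.98, 2, 2)),
                             threshold = 0.995)
  expect_length(out2, 2L)

  # threshold 1.0: only bit-identical patterns merge
  q_eps <- p; q_eps$intensities[10] <- q_eps$intensities[10] + 1e-6
  out3 <- cluster_candidates(list(mk(p, 0.99, 1, 1), mk(q_eps, 0.98, 1, 2)),
                             threshold = 1.0)
  expect_length(out3, 2L)
  out4 <- cluster_candidates(list(mk(p, 0.99, 1, 1), mk(p, 0.98, 1, 2)),
                             threshold = 1.0)
  expect_length(out4, 1L)
})
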