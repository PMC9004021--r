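test_that("reflection enumeration obeys Bragg's law and extinction rules", {
  cube <- unit_cell(10, 10, 10)
  p1 <- space_group("P1")
  refl <- enumerate_reflections(cube, p1, c(5, 30), 1.5406)
  # the (0,0,1)-type family sits at d = 10 exactly
  tt100 <- 2 * asin(1.5406 / 20) * 180 / pi
  expect_true(any(abs(refl$two_theta - tt100) < 1e-9))
  expect_true(all(refl$d > 0))
  # every reflection is inside the requested window
  expect_true(all(refl$two_theta >= 5 & refl$two_theta <= 30))

  # screw axis and glide plane absences in P21/c: (0k0) k odd, (h0l) l odd
  p21c <- space_group("P21/c")
  mono <- unit_cell(8, 9, 11, 90, 102, 90)
  r2 <- enumerate_reflections(mono, p21c, c(5, 40), 1.5406)
  oko <- r2[r2$h == 0 & r2$l == 0, ]
  expect_true(all(oko$k %% 2 == 0))
  h0l <- r2[r2$k == 0, ]
  expect_true(all(h0l$l %% 2 == 0))

  # triclinic centrosymmetric: general multiplicity is the Friedel pair
  pm1 <- space_group("P-1")
  tric <- unit_cell(6, 7, 8, 85, 95, 100)
  r3 <- enumerate_reflections(tric, pm1, c(5, 30), 1.5406)
  gen <- r3[r3$h != 0 & r3$k != 0 & r3$l != 0, ]
  expect_true(all(gen$M == 2L))

  # a C-centred lattice only shows h + k even
  c2c <- space_group("C2/c")
  r4 <- enumerate_reflections(unit_cell(12, 8, 10, 90, 100, 90), c2c,
                              c(5, 35), 1.5406)
  expect_true(all((r4$h + r4$k) %% 2 == 0))
})

test_that("structure factors follow the scattering model", {
  cube <- unit_cell(8, 8, 8)
  refl <- enumerate_reflections(cube, space_group("P1"), c(5, 40), 1.5406)
  # a single carbon at the origin: F2 = f_C(s)^2 (B = 0)
  r1 <- structure_factor(refl, matrix(c(0, 0, 0), 1), "C", B = 0)
  a <- powsolve:::.scatter_table$a["C", ]
  b <- powsolve:::.scatter_table$b["C", ]
  cc <- powsolve:::.scatter_table$c["C"]
  s2 <- 1 / (4 * refl$d^2)
  fC <- cc + colSums(a * exp(-outer(b, s2)))
  expect_equal(r1$F2, unname(fC^2), tolerance = 1e-10)

  # destructive interference: identical atoms at (0,0,0) and (1/2,0,0)
  r2 <- structure_factor(refl, rbind(c(0, 0, 0), c(0.5, 0, 0)),
                         c("C", "C"), B = 0)
  odd_h <- r2$h %% 2 == 1
  expect_true(all(r2$F2[odd_h] < 1e-18))
  expect_true(all(r2$F2[!odd_h] > 0))

  # the displacement factor damps high-angle intensity
  r3 <- structure_factor(refl, matrix(c(0, 0, 0), 1), "C", B = 3)
  damp <- r3$F2 / r1$F2
  expect_true(all(diff(damp[order(refl$d, decreasing = TRUE)]) < 1e-12))

  expect_error(structure_factor(refl, matrix(0, 1, 3), "Xx"), "Xx")
})

test_that("intensity corrections multiply as s * LP * M * F2", {
  refl <- data.frame(h = 1, k = 0, l = 0, d = 5, two_theta = 30,
                     M = 2L, F2 = 50)
  out <- correct_intensity(refl, scale = 1, two_theta_m = 0)
  th <- 15 * pi / 180
  lp_expected <- (1 + cos(30 * pi / 180)^2) / (2 * sin(th)^2 * cos(th))
  expect_equal(out$intensity, 2 * 50 * lp_expected, tolerance = 1e-12)
  expect_equal(lp_factor(30, 0), lp_expected, tolerance = 1e-12)

  # doubling the scale doubles every intensity
  out2 <- correct_intensity(refl, scale = 2, two_theta_m = 0)
  expect_equal(out2$intensity, 2 * out$intensity, tolerance = 1e-12)
})

test_that("profile rendering conserves area and is linear", {
  cfg <- sim_config(two_theta_range = c(10, 30), step = 0.01, fwhm = 0.2)
  one <- data.frame(two_theta = 20, intensity = 7)
  p <- render_pattern(one, cfg)
  # maximum at the reflection position within half a grid step
  expect_lt(abs(two_theta(p)[which.max(p$intensities)] - 20), cfg$step / 2 + 1e-12)
  # integrated area equals the intensity within the truncation tolerance
  expect_lt(abs(sum(p$intensities) * cfg$step - 7) / 7, 0.01)
  # two reflections render as the sum of the singles
  two <- data.frame(two_theta = c(15, 22), intensity = c(3, 5))
  p_both <- render_pattern(two, cfg)
  p_a <- render_pattern(two[1, ], cfg)
  p_b <- render_pattern(two[2, ], cfg)
  expect_equal(p_both$intensities, p_a$intensities + p_b$intensities,
               tolerance = 1e-12)
  # all three shapes conserve area
  for (shape in c("gaussian", "lorentzian", "pseudo_voigt")) {
    cfg_s <- sim_config(two_theta_range = c(10, 30), step = 0.01,
                        fwhm = 0.2, shape = shape)
    ps <- render_pattern(one, cfg_s)
    expect_lt(abs(sum(ps$intensities) * cfg_s$step - 7) / 7, 0.015)
  }
})

test_that("the simulation pipeline caches geometry and shifts with the cell", {
  model <- toy_pminus1_model()
  cfg <- toy_cfg()
  sim_cache_clear()
  p1 <- simulate_pattern(model, cfg)
  misses1 <- sim_cache_stats()$misses
  p2 <- simulate_pattern(model, cfg)
  expect_identical(p1$intensities, p2$intensities)
  st <- sim_cache_stats()
  expect_equal(st$misses, misses1)  # second call hit the cache
  expect_gt(st$hits, 0)

  # moving only the orientation re-uses the reflection list
  rotated <- structure_model(model$cell, model$sg, model$zm, m = model$m,
                             phi = model$phi + c(5, 0, 0))
  invisible(simulate_pattern(rotated, cfg))
  expect_equal(sim_cache_stats()$misses, misses1)

  # +1% isotropic cell expansion shifts every peak to lower angle
  bigger <- structure_model(unit_cell(model$cell$a * 1.01,
                                      model$cell$b * 1.01,
                                      model$cell$c * 1.01,
                                      model$cell$alpha, model$cell$beta,
                                      model$cell$gamma),
                            model$sg, model$zm, m = model$m, phi = model$phi)
  r_small <- enumerate_reflections(model$cell, model$sg, c(5, 35), cfg$wavelength)
  r_big <- enumerate_reflections(bigger$cell, model$sg, c(5, 35), cfg$wavelength)
  common <- merge(r_small, r_big, by = c("h", "k", "l"))
  expect_true(all(common$two_theta.y < common$two_theta.x))

  # total integrated intensity matches the reflection sum (conservation)
  cfg_wide <- sim_config(two_theta_range = c(5, 60), step = 0.02, fwhm = 0.2)
  refl <- enumerate_reflections(model$cell, model$sg, c(7, 58), cfg_wide$wavelength)
  placed <- place_in_cell(model)
  refl <- structure_factor(refl, placed$frac, placed$element, B = cfg_wide$B)
  refl <- correct_intensity(refl, two_theta_m = cfg_wide$two_theta_m)
  rendered <- render_pattern(refl, cfg_wide)
  expect_lt(abs(sum(rendered$intensities) * cfg_wide$step - sum(refl$intensity)) /
              sum(refl$intensity), 0.02)
})

test_that("dropping hydrogens barely changes the pattern of an organic", {
  # hinged fragment placed in P1; hydrogens added via an extended z-matrix
  zm <- make_toy_molecule("hinged")
  df <- as.data.frame(zm)
  df <- rbind(df, data.frame(element = c("H", "H"),
                             ref_bond = c(7L, 8L), bond = c(1.09, 1.01),
                             ref_angle = c(6L, 7L), angle = c(120, 120),
                             ref_dihedral = c(4L, 6L), dihedral = c(0, 180),
                             free_bond = FALSE, free_angle = FALSE,
                             free_dihedral = FALSE))
  zmh <- zmatrix(df)
  model <- make_toy_structure(zmh, space_group("P1"), seed = 17)
  cfg_all <- toy_cfg()
  cfg_noh <- cfg_all; cfg_noh$exclude_h <- TRUE
  pa <- simulate_pattern(model, cfg_all)
  pn <- simulate_pattern(model, cfg_noh)
  expect_gt(s12(pa, pn, l = 0.1)$value, 0.99)
})
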