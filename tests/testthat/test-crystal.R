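test_that("cell volume follows the triclinic closed form", {
  expect_equal(cell_volume(unit_cell(10, 10, 10)), 1000)
  # printed molar volumes of solved structures (V/Z with the stated Z)
  expect_equal(cell_volume(unit_cell(3.675, 7.072, 14.166,
                                     98.90, 90.80, 98.78)) / 1,
               359.14, tolerance = 1e-3)
  expect_equal(cell_volume(unit_cell(3.797, 6.551, 16.125,
                                     95.33, 91.14, 101.49)) / 1,
               391.08, tolerance = 1e-3)
  expect_error(unit_cell(5, 5, 5, 10, 10, 170), "positive definite")
})

test_that("free-parameter counting reproduces the symmetry table", {
  # the nine symmetry settings of the rigid-pigment search and their
  # published fitted-parameter counts
  settings <- list(
    list(sg = space_group("P-1", 0.5, "-1"), n = 9L),
    list(sg = space_group("P1", 1, "1"), n = 9L),
    list(sg = space_group("P21", 1, "1"), n = 9L),
    list(sg = space_group("C2/m", 0.25, "2/m"), n = 5L),
    list(sg = space_group("P21/c", 0.5, "-1"), n = 7L),
    list(sg = space_group("P21/c", 1, "1"), n = 10L),
    list(sg = space_group("C2/c", 0.5, "-1"), n = 7L),
    list(sg = space_group("P212121", 1, "1"), n = 9L),
    list(sg = space_group("Pbca", 0.5, "-1"), n = 6L))
  for (s in settings)
    expect_equal(count_free_parameters(s$sg), s$n, label = s$sg$symbol)
  # torsions add to the count for flexible models
  expect_equal(count_free_parameters(space_group("P1"), rigid = FALSE,
                                     n_tau = 4), 13L)
  expect_error(space_group("F432"), "unsupported")
})

test_that("z-matrix construction is geometrically exact", {
  two <- zmatrix(data.frame(element = c("C", "C"),
                            ref_bond = c(NA, 1L), bond = c(NA, 1.54),
                            ref_angle = NA_integer_, angle = NA_real_,
                            ref_dihedral = NA_integer_, dihedral = NA_real_))
  xyz <- build_cartesian(two)$xyz
  expect_equal(sqrt(sum((xyz[2, ] - xyz[1, ])^2)), 1.54, tolerance = 1e-12)

  # trans 4-atom chain is exactly planar
  chain <- zmatrix(data.frame(
    element = c("C", "C", "C", "C"),
    ref_bond = c(NA, 1L, 2L, 3L), bond = c(NA, 1.5, 1.5, 1.5),
    ref_angle = c(NA, NA, 1L, 2L), angle = c(NA, NA, 110, 110),
    ref_dihedral = c(NA, NA, NA, 1L), dihedral = c(NA, NA, NA, 180)))
  xyz4 <- build_cartesian(chain)$xyz
  expect_lt(abs(det(cbind(xyz4[2, ] - xyz4[1, ], xyz4[3, ] - xyz4[1, ],
                          xyz4[4, ] - xyz4[1, ]))), 1e-9)

  # random z-matrices round-trip: measured internals equal the inputs
  set.seed(13)
  for (rep in 1:5) {
    n <- 6
    df <- data.frame(
      element = rep("C", n),
      ref_bond = c(NA, 1L, 2L, 3L, 4L, 5L),
      bond = c(NA, runif(n - 1, 1.2, 1.8)),
      ref_angle = c(NA, NA, 1L, 2L, 3L, 4L),
      angle = c(NA, NA, runif(n - 2, 60, 150)),
      ref_dihedral = c(NA, NA, NA, 1L, 2L, 3L),
      dihedral = c(NA, NA, NA, runif(n - 3, -179, 179)))
    zm <- zmatrix(df)
    xyz <- build_cartesian(zm)$xyz
    for (i in 2:n)
      expect_equal(sqrt(sum((xyz[i, ] - xyz[df$ref_bond[i], ])^2)),
                   df$bond[i], tolerance = 1e-9)
    for (i in 3:n) {
      u <- xyz[df$ref_bond[i], ] - xyz[i, ]
      v <- xyz[df$ref_angle[i], ] - xyz[df$ref_bond[i], ]
      ang <- acos(sum(u * -v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      expect_equal(ang, df$angle[i], tolerance = 1e-8)
    }
    for (i in 4:n)
      expect_equal(measure_dihedral(xyz, i, df$ref_bond[i], df$ref_angle[i],
                                    df$ref_dihedral[i]),
                   df$dihedral[i], tolerance = 1e-7)
  }

  # colinear angle references make the dihedral frame undefined
  bad <- zmatrix(data.frame(
    element = c("C", "C", "C", "C"),
    ref_bond = c(NA, 1L, 2L, 3L), bond = c(NA, 1.5, 1.5, 1.5),
    ref_angle = c(NA, NA, 1L, 2L), angle = c(NA, NA, 180, 110),
    ref_dihedral = c(NA, NA, NA, 1L), dihedral = c(NA, NA, NA, 0)))
  expect_error(build_cartesian(bad), "degenerate|colinear")
})

test_that("cell placement respects symmetry and conserves matter", {
  zm <- make_toy_molecule("planar_rigid")
  # identity placement in P1 reproduces the local geometry (as fractions)
  cell <- unit_cell(20, 20, 20)
  model <- structure_model(cell, space_group("P1"), zm)
  placed <- place_in_cell(model)
  loc <- build_cartesian(zm)
  centered <- sweep(loc$xyz, 2, colMeans(loc$xyz))
  wrap_diff <- placed$frac - centered / 20
  expect_true(all(abs(wrap_diff - round(wrap_diff)) < 1e-9))

  # P-1 with Z' = 1: the inversion copy doubles the atom count
  m2 <- make_toy_structure(zm, space_group("P1"), seed = 3)
  model2 <- structure_model(m2$cell, space_group("P-1", Zprime = 1), zm,
                            m = c(0.25, 0.1, 0.3), phi = c(10, 20, 30))
  placed2 <- place_in_cell(model2)
  expect_equal(nrow(placed2$frac), 2L * nrow(loc$xyz))
  expect_equal(placed2$n_copies, 2L)

  # centrosymmetric molecule on the inversion centre: copies merge (Z' = 0.5)
  m3 <- toy_pminus1_model()
  placed3 <- place_in_cell(m3)
  expect_equal(placed3$n_copies, 1L)
  expect_equal(nrow(placed3$frac), nrow(loc$xyz))

  # a molecule without inversion symmetry cannot sit on the centre
  zm_noinv <- make_toy_molecule("ml2_fragment")
  cell_big <- unit_cell(15, 15, 15, 95, 90, 90)
  expect_error(place_in_cell(structure_model(cell_big,
    space_group("P-1", Zprime = 0.5, site_symmetry = "-1"), zm_noinv)),
    "incompatible with site symmetry")

  # density consistency: mass * Z / (V * N_A) equals the analytic density
  mass <- molecular_mass(zm)
  model4 <- toy_pminus1_model()
  V <- cell_volume(model4$cell)
  Z <- model4$sg$Z
  dens <- mass * Z / (V * 6.02214076e23) * 1e24  # g/cm^3
  vz <- V / Z
  expect_equal(dens, mass / (vz * 0.602214076), tolerance = 1e-12)
})

test_that("contact checking flags overlap and respects the strict threshold", {
  zm <- make_toy_molecule("planar_rigid")
  # isolated molecule in a huge P1 cell passes
  big <- structure_model(unit_cell(50, 50, 50), space_group("P1"), zm)
  expect_true(check_contacts(big)$pass)

  # two copies rammed together fail (P-1 with a tiny cell)
  tiny <- structure_model(unit_cell(2, 2, 2, 90, 90, 90),
                          space_group("P-1", Zprime = 1), zm,
                          m = c(0.1, 0.1, 0.1))
  expect_false(check_contacts(tiny)$pass)

  # boundary rule: a distance exactly at the threshold passes
  res <- check_contacts(big)
  expect_true(res$worst > 0)
})

test_that("volume increments estimate molar volumes additively", {
  expect_error(estimate_volume_range(character(0)), "no atoms")
  one <- estimate_volume_range(c("C", "N"))$estimate
  two <- estimate_volume_range(c("C", "N", "C", "N"))$estimate
  expect_equal(two, 2 * one, tolerance = 1e-12)
  expect_error(estimate_volume_range(c("C", "Zr")), "Zr")

  # the difluoro-pigment formula with the pi-stacking correction lands close
  # to the published search setting of roughly 365 A^3 +/- 10%
  dfq <- c(rep("C", 20), rep("H", 10), "F", "F", "N", "N", "O", "O")
  est <- estimate_volume_range(dfq, packing_factor = 0.9)$estimate
  expect_lt(abs(est - 365) / 365, 0.10)
})

test_that("cell reduction reaches the published transformed setting", {
  # triclinic: the documented automatic transformation flips the acute pair
  cell <- unit_cell(3.797, 6.521, 16.131, 85.04, 91.14, 78.41)
  red <- reduce_cell(cell)
  expect_equal(c(red$a, red$b, red$c), c(3.797, 6.521, 16.131),
               tolerance = 1e-9)
  expect_equal(red$alpha, 94.96, tolerance = 1e-3)
  expect_equal(red$beta, 91.14, tolerance = 1e-3)
  expect_equal(red$gamma, 101.59, tolerance = 1e-3)

  # idempotence and volume preservation
  red2 <- reduce_cell(red)
  expect_equal(unclass(red2)[1:6], unclass(red)[1:6], tolerance = 1e-9)
  expect_equal(cell_volume(red), cell_volume(cell), tolerance = 1e-9)

  # axis permutations of a lattice all reduce to the same cell
  set.seed(21)
  for (rep in 1:5) {
    a <- runif(1, 3, 6); b <- runif(1, 4, 8); c <- runif(1, 6, 12)
    al <- runif(1, 70, 110); be <- runif(1, 70, 110); ga <- runif(1, 70, 110)
    base <- try(unit_cell(a, b, c, al, be, ga), silent = TRUE)
    if (inherits(base, "try-error")) next
    perm <- unit_cell(b, c, a, be, ga, al)  # cyclic axis relabelling
    r1 <- reduce_cell(base); r2 <- reduce_cell(perm)
    expect_equal(sort(c(r1$a, r1$b, r1$c)), sort(c(r2$a, r2$b, r2$c)),
                 tolerance = 1e-6)
    expect_equal(cell_volume(r1), cell_volume(r2), tolerance = 1e-6)
  }

  # monoclinic convention: beta >= 90 with lengths unchanged
  mono <- space_group("P21/c", Zprime = 0.5, site_symmetry = "-1")
  zm <- make_toy_molecule("planar_rigid")
  mm <- make_toy_structure(zm, mono, seed = 5)
  if (mm$cell$beta >= 90) {
    flipped <- structure_model(unit_cell(mm$cell$a, mm$cell$b, mm$cell$c,
                                         90, 180 - mm$cell$beta, 90),
                               mono, zm, m = mm$m, phi = mm$phi)
    back <- reduce_cell(flipped)
    expect_gte(back$cell$beta, 90)
    expect_equal(back$cell$beta, mm$cell$beta, tolerance = 1e-9)
  }
})

test_that("reducing a structure model leaves its powder pattern unchanged", {
  cfg <- toy_cfg()
  set.seed(31)
  zm <- make_toy_molecule("planar_rigid")
  for (rep in 1:3) {
    model <- make_toy_structure(zm, space_group("P1"), seed = 40 + rep)
    red <- reduce_cell(model)
    p1 <- simulate_pattern(model, cfg)
    p2 <- simulate_pattern(red, cfg)
    expect_gt(s12(p1, p2, zero_limit = TRUE)$value, 1 - 1e-9)
    expect_equal(cell_volume(red$cell), cell_volume(model$cell),
                 tolerance = 1e-9)
  }
})
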