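#' Toy molecules for self-contained testing
#'
#' Three abstract molecule classes mirror the use cases of the method:
#' `planar_rigid` is a centrosymmetric planar six-membered C4N2 ring (a
#' rigid pigment-like body that can sit on an inversion centre),
#' `hinged` an eight-atom fragment with two free dihedrals (conformational
#' flexibility), and `ml2_fragment` a Cu-Cl/Cu-N coordination fragment with
#' two free bond lengths, one free angle and one free dihedral (four
#' internal degrees of freedom).
#'
#' @param kind `"planar_rigid"`, `"hinged"` or `"ml2_fragment"`
#' @return a `zmatrix`
#' @export
make_toy_molecule <- function(kind = c("planar_rigid", "hinged",
                                       "ml2_fragment")) {
  kind <- match.arg(kind)
  zrow <- function(element, rb = NA, bond = NA, ra = NA, angle = NA,
                   rd = NA, dihedral = NA, fb = FALSE, fa = FALSE,
                   fd = FALSE) {
    data.frame(element = element, ref_bond = rb, bond = bond,
               ref_angle = ra, angle = angle, ref_dihedral = rd,
               dihedral = dihedral, free_bond = fb, free_angle = fa,
               free_dihedral = fd)
  }
  df <- switch(kind,
    planar_rigid = .elongated_rigid_zmatrix(),
    hinged = rbind(
      # O=C-C(-C=O)-C-C backbone with two rotatable bonds
      zrow("C"),
      zrow("C", 1, 1.50),
      zrow("O", 1, 1.22, 2, 120),
      zrow("C", 2, 1.50, 1, 112, 3, 60, fd = TRUE),
      zrow("O", 2, 1.22, 1, 120, 3, 180),
      zrow("C", 4, 1.50, 2, 112, 1, 180, fd = TRUE),
      zrow("C", 6, 1.39, 4, 120, 2, 0),
      zrow("N", 7, 1.34, 6, 120, 4, 180)),
    ml2_fragment = rbind(
      # CuCl(NC2) fragment: free Cu-Cl and Cu-N bonds, free Cl-Cu-N angle,
      # free rotation about Cu-N
      zrow("Cu"),
      zrow("Cl", 1, 2.25, fb = TRUE),
      zrow("N", 1, 2.00, 2, 90, fb = TRUE, fa = TRUE),
      zrow("C", 3, 1.34, 1, 120, 2, 0, fd = TRUE),
      zrow("C", 3, 1.34, 1, 120, 4, 180)))
  zmatrix(df)
}

# Elongated centrosymmetric planar body: two fused C6 rings (naphthalene
# skeleton) with two O substituents at inversion-related perimeter
# positions. Emulates the anisotropy and scattering contrast of pigment
# molecules: the elongated shape produces strongly anisotropic cells, which
# suppresses the pseudo-homometric lattice ambiguities of equiaxial cells.
.elongated_rigid_zmatrix <- function() {
  b <- 1.40
  h <- b * sqrt(3) / 2          # 1.2124
  xy <- rbind(
    c(0, b / 2),                # 1 shared-edge C
    c(-h, b), c(-2 * h, b / 2), # 2, 3 ring-A perimeter
    c(-2 * h, -b / 2), c(-h, -b),
    c(0, -b / 2),               # 6 shared-edge C (inversion image of 1)
    c(h, -b), c(2 * h, -b / 2), # 7, 8 ring-B perimeter
    c(2 * h, b / 2), c(h, b),
    c(-2 * h, b / 2) + 1.25 * c(-sqrt(3) / 2, 1 / 2),  # 11 O on atom 3
    c(2 * h, -b / 2) + 1.25 * c(sqrt(3) / 2, -1 / 2))  # 12 O on atom 8
  xyz <- cbind(xy, 0)
  elements <- c(rep("C", 10), "O", "O")
  refs <- lapply(seq_len(nrow(xyz)), function(i)
    if (i <= 4) c(i - 1, i - 2, i - 3)[seq_len(min(i - 1, 3))]
    else c(i - 1, i - 2, i - 3))
  refs[[11]] <- c(3, 2, 1)
  refs[[12]] <- c(8, 7, 6)
  .xyz_to_zmatrix(xyz, elements, refs)
}

# derive a z-matrix from Cartesian coordinates and a reference table
.xyz_to_zmatrix <- function(xyz, elements, refs) {
  n <- nrow(xyz)
  ang <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  rows <- lapply(seq_len(n), function(i) {
    r <- refs[[i]]
    data.frame(
      element = elements[i],
      ref_bond = if (length(r) >= 1) r[1] else NA_integer_,
      bond = if (length(r) >= 1) sqrt(sum((xyz[i, ] - xyz[r[1], ])^2))
             else NA_real_,
      ref_angle = if (length(r) >= 2) r[2] else NA_integer_,
      angle = if (length(r) >= 2) ang(i, r[1], r[2]) else NA_real_,
      ref_dihedral = if (length(r) >= 3) r[3] else NA_integer_,
      dihedral = if (length(r) >= 3)
        measure_dihedral(xyz, i, r[1], r[2], r[3]) else NA_real_,
      free_bond = FALSE, free_angle = FALSE, free_dihedral = FALSE)
  })
  zmatrix(do.call(rbind, rows))
}

#' Construct a random but valid toy crystal structure
#'
#' Samples trial structures in the given symmetry until one passes the
#' intermolecular contact check; the molar volume is inside the
#' increment-estimate window by construction of the sampler.
#'
#' @param zm a `zmatrix` (see [make_toy_molecule()])
#' @param sg a `space_group_setting`
#' @param seed RNG seed making the structure reproducible
#' @param max_attempts placement attempts before giving up
#' @param space optional `search_space` (default [make_search_space()])
#' @return a `structure_model` that passes [check_contacts()]
#' @export
make_toy_structure <- function(zm, sg, seed = 1, max_attempts = 1e4,
                               space = NULL) {
  if (is.null(space)) space <- make_search_space(zm, sg)
  set.seed(seed)
  for (i in seq_len(max_attempts)) {
    model <- sample_trial(space, sg, zm)
    ok <- try(check_contacts(model), silent = TRUE)
    if (!inherits(ok, "try-error") && ok$pass) return(model)
  }
  stop("no contact-valid structure found in ", max_attempts, " attempts")
}

#' Simulate a noisy experimental-style pattern from a known structure
#'
#' Renders the true pattern, adds a smooth quadratic background and
#' Poisson counting noise at the requested signal-to-noise ratio (defined
#' as the tallest peak height over the counting noise standard deviation at
#' that peak). The returned pattern is *not* background-corrected, so the
#' preprocessing chain is exercised downstream.
#'
#' @param truth a `structure_model`
#' @param cfg a [sim_config()]
#' @param snr signal-to-noise ratio; `Inf` for a noise-free pattern
#' @param background `"poly"` for the quadratic background or `"none"`
#' @param bg_level background height as a fraction of the tallest peak
#' @param seed RNG seed
#' @return a `powder_pattern` with `background_corrected = FALSE`
#' @export
make_noisy_pattern <- function(truth, cfg = sim_config(), snr = 10,
                               background = c("poly", "none"),
                               bg_level = 0.2, seed = 1) {
  background <- match.arg(background)
  sim <- simulate_pattern(truth, cfg)
  y <- sim$intensities
  peak <- max(y)
  if (peak <= 0) stop("true structure produced an empty pattern")
  y <- y / peak  # tallest peak = 1
  n <- length(y)
  x <- seq(0, 1, length.out = n)
  bg <- if (background == "poly")
    bg_level * (1 - 0.7 * x + 0.4 * x^2) else rep(0, n)
  total <- y + bg
  if (is.finite(snr)) {
    set.seed(seed)
    # Poisson counts scaled so that sigma at the tallest peak = peak/snr,
    # with a one-count floor so empty regions still carry noise
    s <- snr^2
    counts <- stats::rpois(n, lambda = s * total + 1)
    total <- (counts - 1) / s
  }
  out <- sim
  out$intensities <- pmax(total, 0)
  out$background_corrected <- FALSE
  out$label <- sprintf("toy pattern (snr %s)", format(snr))
  out
}

#' The shipped toy recovery suite
#'
#' Three ground-truth structures -- the rigid ring in P1 (Z = 1), on an
#' inversion centre in P-1 (Z' = 0.5) and on an inversion centre in P21/c
#' (Z' = 0.5) -- each rendered at three signal-to-noise levels (50, 10, 4).
#' Every case carries its generating structure, the noisy pattern and the
#' simulation settings, so recovery runs can verify the result against the
#' known truth.
#'
#' @param snr_levels signal-to-noise ratios of the noisy patterns
#' @param cfg simulation settings shared by all cases
#' @return list of `toy_case` lists with elements `name`, `zm`, `sg`,
#'   `truth`, `pattern`, `cfg`, `snr`, `seed`
#' @export
toy_suite <- function(snr_levels = c(50, 10, 4), cfg = NULL) {
  # a 5-45 degree window: wide enough that the ~60 reflections of these
  # small triclinic/monoclinic cells determine the lattice uniquely, as a
  # real measurement would be
  if (is.null(cfg))
    cfg <- sim_config(two_theta_range = c(5, 45), step = 0.06, fwhm = 0.3)
  zm <- make_toy_molecule("planar_rigid")
  # the centrosymmetric special-position settings of the published pigment
  # searches: triclinic, monoclinic and orthorhombic with the molecule on an
  # inversion centre (9, 7 and 6 free parameters)
  settings <- list(
    list(name = "P-1", sg = space_group("P-1", Zprime = 0.5,
                                        site_symmetry = "-1"), seed = 202L),
    list(name = "P21c", sg = space_group("P21/c", Zprime = 0.5,
                                         site_symmetry = "-1"), seed = 303L),
    list(name = "Pbca", sg = space_group("Pbca", Zprime = 0.5,
                                         site_symmetry = "-1"), seed = 404L))
  cases <- list()
  for (st in settings) {
    truth <- make_toy_structure(zm, st$sg, seed = st$seed)
    truth$fwhm <- cfg$fwhm
    for (snr in snr_levels) {
      pat <- make_noisy_pattern(truth, cfg, snr = snr,
                                seed = st$seed + round(snr))
      cases[[length(cases) + 1L]] <- structure(
        list(name = sprintf("%s_snr%g", st$name, snr), zm = zm, sg = st$sg,
             truth = truth, pattern = pat, cfg = cfg, snr = snr,
             seed = st$seed),
        class = "toy_case")
    }
  }
  cases
}

#' Did a candidate recover the generating toy structure?
#'
#' Compares the reduced cells (lengths within `cell_tol` relative, angles
#' within `angle_tol` degrees) and requires the reference similarity of the
#' candidate against the noise-free true pattern to exceed `ref_min`.
#'
#' @param candidate a candidate (from a `candidate_set`)
#' @param case a `toy_case`
#' @param cell_tol relative tolerance on reduced cell lengths
#' @param angle_tol absolute tolerance on reduced cell angles, degrees
#' @param ref_min reference-similarity threshold
#' @return logical
#' @export
recovered_truth <- function(candidate, case, cell_tol = 0.02,
                            angle_tol = 2, ref_min = 0.98) {
  # compare the lattices in their Niggli-canonical form regardless of the
  # symmetry setting, so permuted equivalent settings (e.g. orthorhombic
  # axis relabellings) are recognized
  truth_red <- .reduce_cell_impl(case$truth$cell, "triclinic")$cell
  cand_red <- .reduce_cell_impl(candidate$model$cell, "triclinic")$cell
  lengths_ok <- all(abs(c(cand_red$a, cand_red$b, cand_red$c) /
                          c(truth_red$a, truth_red$b, truth_red$c) - 1)
                    < cell_tol)
  angles_ok <- all(abs(c(cand_red$alpha, cand_red$beta, cand_red$gamma) -
                         c(truth_red$alpha, truth_red$beta, truth_red$gamma))
                   < angle_tol)
  true_pattern <- simulate_pattern(case$truth, case$cfg)
  ref <- reference_similarity(true_pattern,
                              simulate_pattern(candidate$model, case$cfg))$value
  lengths_ok && angles_ok && ref > ref_min
}

#' Write the toy suite to disk as text fixtures
#'
#' Each case is written as a CIF of the true structure, an xy file of the
#' noisy pattern and a JSON truth record (cell, parameters, seed, snr).
#'
#' @param dir output directory (created if needed)
#' @param cases toy cases from [toy_suite()]
#' @return invisibly, the written file paths
#' @export
write_toy_suite <- function(dir, cases = toy_suite()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (case in cases) {
    base <- file.path(dir, case$name)
    write_cif(case$truth, paste0(base, ".cif"))
    write_pattern(case$pattern, paste0(base, ".xy"))
    truth <- list(name = case$name, snr = case$snr, seed = case$seed,
                  space_group = case$sg$symbol, Zprime = case$sg$Zprime,
                  cell = unclass(case$truth$cell)[c("a", "b", "c", "alpha",
                                                    "beta", "gamma")],
                  m = case$truth$m, phi = case$truth$phi,
                  tau = case$truth$tau)
    jsonlite::write_json(truth, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, paste0(base, c(".cif", ".xy", ".json")))
  }
  invisible(paths)
}
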