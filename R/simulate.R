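#' Simulation configuration
#'
#' Static instrument and rendering settings for powder-pattern simulation.
#' These are set once per problem and never altered during structure fitting;
#' only the FWHM may later be refined as part of a fine fit.
#'
#' @param two_theta_range simulated range `c(lo, hi)` in degrees
#' @param step grid step in degrees
#' @param wavelength wavelength in Angstrom (default Cu K-alpha1)
#' @param fwhm reflection full width at half maximum, degrees
#' @param shape `"pseudo_voigt"` (default), `"gaussian"` or `"lorentzian"`
#' @param eta pseudo-Voigt mixing fraction (1 = pure Lorentzian)
#' @param two_theta_m monochromator angle 2theta_m in degrees for the
#'   polarization factor; 0 means unpolarized. Default 27.26 (Ge(111) with
#'   Cu K-alpha1).
#' @param B overall isotropic displacement parameter, Angstrom^2
#' @param scale overall intensity scale factor
#' @param exclude_h drop hydrogen atoms from the structure-factor sum (a
#'   performance option; hydrogens scatter weakly)
#' @return a `sim_config` list
#' @export
sim_config <- function(two_theta_range = c(5, 40), step = 0.02,
                       wavelength = 1.5406, fwhm = 0.3,
                       shape = "pseudo_voigt", eta = 0.5,
                       two_theta_m = 27.26, B = 3, scale = 1,
                       exclude_h = FALSE) {
  stopifnot(two_theta_range[1] > 0, two_theta_range[2] < 180,
            two_theta_range[1] < two_theta_range[2],
            step > 0, wavelength > 0, fwhm > 0, eta >= 0, eta <= 1)
  if (step > fwhm / 3)
    warning("grid step exceeds fwhm/3; peaks will be undersampled")
  structure(list(two_theta_range = two_theta_range, step = step,
                 wavelength = wavelength, fwhm = fwhm, shape = shape,
                 eta = eta, two_theta_m = two_theta_m, B = B, scale = scale,
                 exclude_h = exclude_h),
            class = "sim_config")
}

#' Enumerate symmetry-unique reflections in a 2-theta range
#'
#' All symmetry-unique `hkl` with Bragg angle inside the range, with
#' systematically absent reflections (zero structure factor forced by
#' translational symmetry elements) removed, and multiplicities equal to the
#' orbit size under the Laue group (Friedel pairs included).
#'
#' @param cell a `unit_cell`
#' @param sg a `space_group_setting`
#' @param two_theta_range `c(lo, hi)` in degrees
#' @param wavelength wavelength in Angstrom
#' @return data.frame with columns `h, k, l, d, two_theta, M`
#' @export
enumerate_reflections <- function(cell, sg, two_theta_range, wavelength) {
  raw <- .enumerate_raw(cell, sg, two_theta_range, wavelength)
  o <- order(raw$two_theta)
  structure(list(h = raw$h[o], k = raw$k[o], l = raw$l[o], d = raw$d[o],
                 two_theta = raw$two_theta[o], M = raw$M[o]),
            class = "data.frame", row.names = c(NA_integer_, -length(o)))
}

# hot-path version: plain list, unsorted
.enumerate_raw <- function(cell, sg, two_theta_range, wavelength) {
  stopifnot(wavelength > 0, two_theta_range[1] > 0, two_theta_range[2] < 180)
  d_min <- wavelength / (2 * sin(two_theta_range[2] * pi / 360))
  d_max <- wavelength / (2 * sin(two_theta_range[1] * pi / 360))
  Gs <- .recip_metric(cell)
  hmax <- ceiling(cell$a / d_min)
  kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  laue_mat <- sg$laue_mat %||%
    t(vapply(.laue_rotations(sg), function(R) as.numeric(t(R)), numeric(9)))
  ops_mat <- sg$ops_mat %||%
    t(vapply(sg$ops, function(op) c(as.numeric(t(op$R)), op$t), numeric(12)))
  res <- cpp_enumerate(hmax, kmax, lmax, Gs,
                       1 / d_max^2 - 1e-12, 1 / d_min^2 + 1e-12,
                       laue_mat, ops_mat)
  if (nrow(res) == 0L)
    return(list(h = integer(0), k = integer(0), l = integer(0),
                d = numeric(0), two_theta = numeric(0), M = integer(0)))
  d <- 1 / sqrt(res[, 4])
  list(h = as.integer(res[, 1]), k = as.integer(res[, 2]),
       l = as.integer(res[, 3]), d = d,
       two_theta = 2 * asin(pmin(1, wavelength / (2 * d))) * 180 / pi,
       M = as.integer(res[, 5]))
}

#' Squared structure-factor amplitudes for a reflection list
#'
#' `F = sum_j f_j(sin(theta)/lambda) exp(2 pi i (h x_j + k y_j + l z_j))`
#' with 4-term Gaussian atomic scattering factors and one overall isotropic
#' displacement factor `exp(-B sin^2(theta)/lambda^2)` applied to `F`.
#'
#' @param refl data.frame from [enumerate_reflections()]
#' @param frac n x 3 matrix of fractional coordinates of the full cell
#' @param element character vector of element symbols per atom
#' @param B overall isotropic displacement parameter, Angstrom^2
#' @return `refl` with an added column `F2` (electrons^2)
#' @export
structure_factor <- function(refl, frac, element, B = 0) {
  unknown <- setdiff(unique(element), supported_elements())
  if (length(unknown))
    stop("no scattering coefficients for element(s): ",
         paste(unknown, collapse = ", "))
  if (length(refl$d) == 0L) { refl$F2 <- numeric(0); return(refl) }
  eidx <- match(element, rownames(.scatter_table$a)) - 1L
  stol2 <- 1 / (4 * refl$d^2)
  refl$F2 <- cpp_f2(refl$h, refl$k, refl$l, stol2, eidx,
                    .scatter_table$a, .scatter_table$b, .scatter_table$c,
                    frac[, 1], frac[, 2], frac[, 3], B)
  refl
}

#' Apply intensity corrections to a reflection list
#'
#' `I = s * LP(theta) * A(theta) * T(hkl) * M * F2` with the default
#' Lorentz-polarization factor
#' `LP = (1 + cos^2(2theta_m) cos^2(2theta)) / (2 sin^2(theta) cos(theta))`;
#' absorption and preferred-orientation factors default to identity.
#'
#' @param refl data.frame with `F2` (from [structure_factor()])
#' @param scale overall scale factor s
#' @param two_theta_m monochromator angle in degrees (0 = unpolarized)
#' @param absorption function(theta_deg) -> factor, default identity
#' @param texture function(h, k, l) -> factor, default identity
#' @return `refl` with an added column `intensity`
#' @export
correct_intensity <- function(refl, scale = 1, two_theta_m = 27.26,
                              absorption = NULL, texture = NULL) {
  if (length(refl$two_theta) == 0L) { refl$intensity <- numeric(0); return(refl) }
  lp <- lp_factor(refl$two_theta, two_theta_m)
  A <- if (is.null(absorption)) 1 else absorption(refl$two_theta / 2)
  Tf <- if (is.null(texture)) 1 else texture(refl$h, refl$k, refl$l)
  refl$intensity <- scale * lp * A * Tf * refl$M * refl$F2
  refl
}

#' Lorentz-polarization factor
#' @param two_theta diffraction angle(s) 2-theta in degrees (0 and 180 excluded)
#' @param two_theta_m monochromator angle in degrees
#' @return LP factor(s)
#' @export
lp_factor <- function(two_theta, two_theta_m = 27.26) {
  th <- two_theta * pi / 360
  c2m <- cos(two_theta_m * pi / 180)^2
  (1 + c2m * cos(two_theta * pi / 180)^2) / (2 * sin(th)^2 * cos(th))
}

#' Render a reflection list as a powder pattern
#'
#' Each reflection contributes its intensity times a unit-area profile
#' centred at its 2-theta position; profiles are truncated at 6 FWHM. The
#' FWHM is constant across the range.
#'
#' @param refl data.frame with `two_theta` and `intensity`
#' @param cfg a [sim_config()]
#' @return a background-corrected `powder_pattern`
#' @export
render_pattern <- function(refl, cfg) {
  n <- floor(diff(cfg$two_theta_range) / cfg$step) + 1L
  y <- cpp_render(refl$two_theta, refl$intensity, cfg$fwhm,
                  .shape_kind(cfg$shape), cfg$eta,
                  cfg$two_theta_range[1], cfg$step, n, 6)
  powder_pattern(cfg$two_theta_range[1], cfg$step, y,
                 wavelength = cfg$wavelength, background_corrected = TRUE,
                 label = "simulated")
}

# package-local cache for reflection geometry keyed on (cell, sg, range, lambda)
.sim_cache <- new.env(parent = emptyenv())
.sim_cache$store <- new.env(parent = emptyenv())
.sim_cache$hits <- 0L
.sim_cache$misses <- 0L

#' Reflection-cache statistics and reset
#' @return list with `hits` and `misses` counters
#' @export
sim_cache_stats <- function() {
  list(hits = .sim_cache$hits, misses = .sim_cache$misses)
}

#' @rdname sim_cache_stats
#' @export
sim_cache_clear <- function() {
  .sim_cache$store <- new.env(parent = emptyenv())
  .sim_cache$hits <- 0L
  .sim_cache$misses <- 0L
  invisible(NULL)
}

.cached_reflections <- function(cell, sg, range, wavelength) {
  key <- paste(sg$symbol, sg$n_ops,
               paste(sprintf("%.9g", unlist(cell[c("a", "b", "c", "alpha",
                                                   "beta", "gamma")])),
                     collapse = ","),
               sprintf("%.6g-%.6g@%.6g", range[1], range[2], wavelength),
               sep = "|")
  store <- .sim_cache$store
  hit <- get0(key, envir = store, inherits = FALSE)
  if (!is.null(hit)) {
    .sim_cache$hits <- .sim_cache$hits + 1L
    return(hit)
  }
  .sim_cache$misses <- .sim_cache$misses + 1L
  refl <- .enumerate_raw(cell, sg, range, wavelength)
  .sim_cache$n <- (.sim_cache$n %||% 0L) + 1L
  if (.sim_cache$n > 512L) {
    .sim_cache$store <- store <- new.env(parent = emptyenv())
    .sim_cache$n <- 0L
  }
  assign(key, refl, envir = store)
  refl
}

#' Simulate the powder pattern of a structure model
#'
#' Full pipeline: reflection enumeration (with a guard band of 3 FWHM beyond
#' both range edges so truncated tails at the window edges are correct),
#' structure factors, Lorentz-polarization and multiplicity corrections, and
#' profile rendering. Reflection geometry is cached on (cell, symmetry,
#' range, wavelength), so moves that change only the molecular position,
#' orientation or torsions re-use the reflection list.
#'
#' @param model a `structure_model`
#' @param cfg a [sim_config()]
#' @param placed optional pre-computed [place_in_cell()] result
#' @return a background-corrected `powder_pattern`
#' @export
simulate_pattern <- function(model, cfg = sim_config(), placed = NULL) {
  stopifnot(inherits(model, "structure_model"), inherits(cfg, "sim_config"))
  fwhm <- model$fwhm %||% cfg$fwhm
  guard <- 3 * fwhm
  enum_range <- c(max(cfg$two_theta_range[1] - guard, 0.2),
                  min(cfg$two_theta_range[2] + guard, 179))
  refl <- .cached_reflections(model$cell, model$sg, enum_range, cfg$wavelength)
  if (is.null(placed)) placed <- place_in_cell(model)
  keep <- if (cfg$exclude_h) placed$element != "H"
          else rep(TRUE, length(placed$element))
  refl <- structure_factor(refl, placed$frac[keep, , drop = FALSE],
                           placed$element[keep], B = cfg$B)
  refl <- correct_intensity(refl, scale = cfg$scale,
                            two_theta_m = cfg$two_theta_m)
  cfg_local <- cfg
  cfg_local$fwhm <- fwhm
  render_pattern(refl, cfg_local)
}
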