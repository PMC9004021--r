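#' Unit cells
#'
#' @param a,b,c cell lengths in Angstrom (> 0)
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @return an object of class `unit_cell`
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (.cell_discriminant(cell) <= 0)
    stop("invalid cell: metric tensor not positive definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

.cell_discriminant <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Volume of a unit cell
#'
#' `V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param cell a `unit_cell`
#' @return volume in Angstrom^3
#' @export
cell_volume <- function(cell) {
  disc <- .cell_discriminant(cell)
  if (disc <= 0) stop("invalid cell: non-positive volume discriminant")
  cell$a * cell$b * cell$c * sqrt(disc)
}

# Orthogonalization matrix M: Cartesian = M %*% fractional (a along x,
# b in the xy plane).
.orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(.cell_discriminant(cell))
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

# Metric tensor of the reciprocal cell; 1/d^2 = h' G* h.
.recip_metric <- function(cell) {
  M <- .orth_matrix(cell)
  G <- t(M) %*% M
  solve(G)
}

#' Z-matrix molecular models
#'
#' A z-matrix describes a molecule by internal coordinates: each atom is
#' placed by a bond length to an earlier atom, a bond angle to a second and a
#' dihedral to a third. Individual internal coordinates can be flagged as free
#' (the torsional degrees of freedom tau fitted by the optimizer). Dummy
#' atoms (element `"X"`) may be used for construction and are excluded from
#' scattering and contact checks.
#'
#' @param df data.frame with columns `element`, `ref_bond`, `bond`,
#'   `ref_angle`, `angle`, `ref_dihedral`, `dihedral` and optional logical
#'   columns `free_bond`, `free_angle`, `free_dihedral`. References are row
#'   indices of earlier rows (`NA` where not applicable: row 1 has no
#'   references, row 2 only `ref_bond`, row 3 no dihedral).
#' @return an object of class `zmatrix`
#' @export
zmatrix <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  for (col in c("free_bond", "free_angle", "free_dihedral"))
    if (is.null(df[[col]])) df[[col]] <- FALSE
  n <- nrow(df)
  for (i in seq_len(n)) {
    refs <- c(df$ref_bond[i], df$ref_angle[i], df$ref_dihedral[i])
    need <- min(i - 1L, 3L)
    if (any(!is.na(refs) & refs >= i))
      stop("z-matrix row ", i, " references a later row")
    if (sum(!is.na(refs)) < need)
      stop("z-matrix row ", i, " is missing references")
  }
  bad <- setdiff(unique(df$element), c(supported_elements(), "X"))
  if (length(bad))
    stop("unsupported element(s) in z-matrix: ", paste(bad, collapse = ", "))
  structure(df, class = c("zmatrix", "data.frame"))
}

#' Number of free internal coordinates of a z-matrix
#' @param zm a `zmatrix`
#' @return integer count
#' @export
n_free_tau <- function(zm) {
  sum(zm$free_bond, na.rm = TRUE) + sum(zm$free_angle, na.rm = TRUE) +
    sum(zm$free_dihedral, na.rm = TRUE)
}

# default values of the free internal coordinates, in flag order
#' @keywords internal
free_tau_values <- function(zm) {
  vals <- numeric(0)
  for (i in seq_len(nrow(zm))) {
    if (isTRUE(zm$free_bond[i])) vals <- c(vals, zm$bond[i])
    if (isTRUE(zm$free_angle[i])) vals <- c(vals, zm$angle[i])
    if (isTRUE(zm$free_dihedral[i])) vals <- c(vals, zm$dihedral[i])
  }
  vals
}

#' Convert a z-matrix to local Cartesian coordinates
#'
#' Standard internal-to-Cartesian construction: atom 1 at the origin, atom 2
#' on +x, atom 3 in the xy plane; later atoms by the natural-extension
#' (NeRF-style) placement. Values of flagged free coordinates can be
#' overridden through `tau` (in flag order).
#'
#' @param zm a `zmatrix`
#' @param tau numeric vector of free internal coordinate values, or `NULL`
#'   to use the values stored in the z-matrix
#' @return list with `xyz` (n x 3 matrix, Angstrom), `element`, `dummy`
#' @export
build_cartesian <- function(zm, tau = NULL) {
  stopifnot(inherits(zm, "zmatrix"))
  df <- as.data.frame(zm)
  if (!is.null(tau)) {
    if (length(tau) != n_free_tau(zm))
      stop("tau has length ", length(tau), ", expected ", n_free_tau(zm))
    k <- 0L
    for (i in seq_len(nrow(df))) {
      if (isTRUE(df$free_bond[i])) { k <- k + 1L; df$bond[i] <- tau[k] }
      if (isTRUE(df$free_angle[i])) { k <- k + 1L; df$angle[i] <- tau[k] }
      if (isTRUE(df$free_dihedral[i])) { k <- k + 1L; df$dihedral[i] <- tau[k] }
    }
  }
  n <- nrow(df)
  xyz <- matrix(0, n, 3)
  if (n >= 2L) xyz[2, ] <- c(df$bond[2], 0, 0)
  if (n >= 3L) {
    th <- df$angle[3] * pi / 180
    if (df$angle[3] <= 1e-6 || df$angle[3] >= 180 - 1e-6)
      stop("z-matrix row 3: degenerate bond angle")
    C <- xyz[df$ref_bond[3], ]
    B <- xyz[df$ref_angle[3], ]
    u <- (B - C) / sqrt(sum((B - C)^2))
    # place in the xy plane: rotate u by theta within the plane
    perp <- c(-u[2], u[1], 0)
    xyz[3, ] <- C + df$bond[3] * (cos(th) * u + sin(th) * perp)
  }
  if (n >= 4L) {
    for (i in 4:n) {
      r <- df$bond[i]
      th <- df$angle[i] * pi / 180
      ph <- df$dihedral[i] * pi / 180
      if (df$angle[i] <= 1e-6 || df$angle[i] >= 180 - 1e-6)
        stop("z-matrix row ", i, ": degenerate bond angle")
      C <- xyz[df$ref_bond[i], ]     # bonded to
      B <- xyz[df$ref_angle[i], ]    # angle reference
      A <- xyz[df$ref_dihedral[i], ] # dihedral reference
      b1 <- B - A; b2 <- C - B
      b2n <- sqrt(sum(b2^2))
      if (b2n < 1e-9) stop("z-matrix row ", i, ": coincident references")
      b2u <- b2 / b2n
      nvec <- .cross3(b1, b2)
      nn <- sqrt(sum(nvec^2))
      if (nn < 1e-9)
        stop("z-matrix row ", i, ": colinear angle references, dihedral undefined")
      nu <- nvec / nn
      mu <- .cross3(nu, b2u)
      d <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
      xyz[i, ] <- C + d[1] * b2u + d[2] * mu + d[3] * nu
    }
  }
  list(xyz = xyz, element = df$element, dummy = df$element == "X")
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure a dihedral angle from Cartesian coordinates
#' @param xyz n x 3 coordinate matrix
#' @param i,j,k,l atom indices (dihedral about the j-k bond)
#' @return signed dihedral in degrees
#' @export
measure_dihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Structure models
#'
#' A full trial crystal structure: unit cell, space-group setting, a z-matrix
#' molecule, and the fitted parameter vector -- fractional anchor coordinates
#' `m`, orientation angles `phi` (degrees, applied as Rz(phi_z) Ry(phi_y)
#' Rx(phi_x) about the molecular centroid) and values `tau` of the free
#' internal coordinates. Parameters fixed by the crystal system, a floating
#' origin or the site symmetry are held at canonical values (90 degree
#' angles, zero coordinates/angles).
#'
#' @param cell a `unit_cell`
#' @param sg a `space_group_setting`
#' @param zm a `zmatrix`
#' @param m fractional anchor coordinates, wrapped into `[0, 1)`
#' @param phi orientation angles in degrees
#' @param tau free internal coordinate values (defaults to the z-matrix values)
#' @param fwhm optional profile FWHM carried with the model, degrees
#' @return an object of class `structure_model`
#' @export
structure_model <- function(cell, sg, zm, m = c(0, 0, 0), phi = c(0, 0, 0),
                            tau = NULL, fwhm = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "space_group_setting"),
            inherits(zm, "zmatrix"))
  if (is.null(tau)) tau <- free_tau_values(zm)
  if (length(tau) != n_free_tau(zm))
    stop("tau length does not match the z-matrix free coordinates")
  cell <- .constrain_cell(cell, sg$system)
  m <- m %% 1
  if (sg$site_symmetry %in% c("-1", "2/m")) m <- c(0, 0, 0)
  m[sg$floating] <- 0
  if (sg$site_symmetry %in% c("2", "m", "2/m")) { phi[1] <- 0; phi[3] <- 0 }
  structure(list(cell = cell, sg = sg, zm = zm,
                 m = m, phi = phi, tau = tau, fwhm = fwhm),
            class = "structure_model")
}

.constrain_cell <- function(cell, system) {
  if (system == "monoclinic") { cell$alpha <- 90; cell$gamma <- 90 }
  if (system == "orthorhombic") { cell$alpha <- 90; cell$beta <- 90; cell$gamma <- 90 }
  cell
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure model in", x$sg$symbol, "\n")
  print(x$cell)
  cat(sprintf("  m = (%.4f, %.4f, %.4f)  phi = (%.1f, %.1f, %.1f) deg  n_tau = %d\n",
              x$m[1], x$m[2], x$m[3], x$phi[1], x$phi[2], x$phi[3],
              length(x$tau)))
  invisible(x)
}

#' Count the free structural parameters of a symmetry setting
#'
#' Cell parameters not fixed by the crystal system (triclinic 6, monoclinic
#' 4, orthorhombic 3), plus anchor coordinates not fixed by a floating origin
#' or a special position, plus orientation angles not fixed by the site
#' symmetry, plus the internal degrees of freedom.
#'
#' @param sg a `space_group_setting`
#' @param rigid if `FALSE`, `n_tau` internal coordinates are added
#' @param n_tau number of free internal coordinates
#' @return integer parameter count
#' @export
count_free_parameters <- function(sg, rigid = TRUE, n_tau = 0) {
  stopifnot(inherits(sg, "space_group_setting"))
  n_cell <- switch(sg$system, triclinic = 6L, monoclinic = 4L,
                   orthorhombic = 3L,
                   stop("unsupported crystal system: ", sg$system))
  n_pos <- switch(sg$site_symmetry,
                  "1" = 3L - length(sg$floating),
                  "-1" = 0L, "2/m" = 0L, "2" = 1L, "m" = 2L)
  n_rot <- switch(sg$site_symmetry,
                  "1" = 3L, "-1" = 3L, "2" = 1L, "m" = 1L, "2/m" = 1L)
  n_cell + n_pos + n_rot + if (rigid) 0L else as.integer(n_tau)
}

# rotation matrix Rz(phi_z) Ry(phi_y) Rx(phi_x), angles in degrees
.rotation_matrix <- function(phi) {
  p <- phi * pi / 180
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Expand a structure model to the full cell contents
#'
#' Builds the molecule from its z-matrix, rotates it about its centroid,
#' places the centroid at the fractional anchor position and expands by the
#' space-group operators. For molecules on special positions (`Zprime < 1`)
#' symmetry copies that coincide with an already-placed copy are merged; a
#' model whose molecule does not actually possess the site symmetry is
#' rejected.
#'
#' @param model a `structure_model`
#' @param include_dummy keep dummy atoms in the output?
#' @return list with `frac` (n x 3 fractional coordinates), `element`,
#'   `copy` (symmetry-copy index per atom), `cart` (Cartesian coordinates),
#'   `n_copies`
#' @export
place_in_cell <- function(model, include_dummy = FALSE) UseMethod("place_in_cell")

#' @export
place_in_cell.default <- function(model, include_dummy = FALSE)
  stop("place_in_cell expects a structure_model")

# memoized internal-to-Cartesian builds; rigid molecules always hit one key
.mol_cache <- new.env(parent = emptyenv())
.site_merge_cache <- new.env(parent = emptyenv())

.build_cartesian_memo <- function(zm, tau) {
  vals <- c(zm$bond, zm$angle, zm$dihedral)
  key <- paste(nrow(zm), paste(zm$element, collapse = ""),
               paste(sprintf("%.10g", vals[!is.na(vals)]), collapse = ","),
               paste(sprintf("%.10g", tau), collapse = ","), sep = "|")
  hit <- get0(key, envir = .mol_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  loc <- build_cartesian(zm, tau)
  .mol_cache$n <- (.mol_cache$n %||% 0L) + 1L
  if (.mol_cache$n > 256L) {
    rm(list = setdiff(ls(.mol_cache), "n"), envir = .mol_cache)
    .mol_cache$n <- 0L
  }
  assign(key, loc, envir = .mol_cache)
  loc
}

#' @export
place_in_cell.structure_model <- function(model, include_dummy = FALSE) {
  loc <- .build_cartesian_memo(model$zm, model$tau)
  keep <- if (include_dummy) rep(TRUE, length(loc$dummy)) else !loc$dummy
  xyz <- loc$xyz[!loc$dummy, , drop = FALSE]
  anchor <- colMeans(xyz)
  xyz_all <- loc$xyz[keep, , drop = FALSE]
  elem <- loc$element[keep]
  R <- .rotation_matrix(model$phi)
  M <- .orth_matrix(model$cell)
  Minv <- solve(M)
  n_at <- nrow(xyz_all)
  centered <- xyz_all - rep(anchor, each = n_at)
  frac0 <- centered %*% t(Minv %*% R) + rep(model$m, each = n_at)
  make_copy <- function(op) {
    f <- frac0 %*% t(op$R) + rep(op$t, each = n_at)
    f - rep(floor(colMeans(f)), each = n_at)  # wrap the copy as a unit
  }
  # merge coincident copies (special positions). Which operators produce
  # duplicates is a structural property of (molecule, symmetry, site) --
  # the constructor pins the anchor and the constrained angles -- so the
  # kept-operator set is resolved once and cached; later placements build
  # only the kept copies.
  if (model$sg$Zprime < 1) {
    zvals <- c(model$zm$bond, model$zm$angle, model$zm$dihedral)
    mkey <- paste(model$sg$symbol, model$sg$n_ops, model$sg$Zprime,
                  model$sg$site_symmetry, nrow(model$zm),
                  paste(model$zm$element, collapse = ""),
                  paste(sprintf("%.8g", zvals[!is.na(zvals)]), collapse = ","),
                  length(model$tau), sep = "|")
    kept_ops <- get0(mkey, envir = .site_merge_cache, inherits = FALSE)
    if (!is.null(kept_ops) && length(model$tau) == 0L) {
      kept <- lapply(model$sg$ops[kept_ops], make_copy)
    } else {
      copies <- lapply(model$sg$ops, make_copy)
      kept_ops <- integer(0)
      kept <- list()
      for (ci in seq_along(copies)) {
        f <- copies[[ci]]
        dup <- FALSE
        for (g in kept) {
          if (.copies_coincide(f, g, elem, model$cell)) { dup <- TRUE; break }
        }
        if (!dup) { kept[[length(kept) + 1L]] <- f
                    kept_ops <- c(kept_ops, ci) }
      }
      assign(mkey, kept_ops, envir = .site_merge_cache)
    }
  } else kept <- lapply(model$sg$ops, make_copy)
  expected <- model$sg$n_ops * model$sg$Zprime
  if (abs(length(kept) - expected) > 1e-9)
    stop("molecule incompatible with site symmetry ", model$sg$site_symmetry,
         " in ", model$sg$symbol, ": expected ", expected,
         " distinct copies, got ", length(kept))
  frac <- do.call(rbind, kept)
  cart <- frac %*% t(M)
  list(frac = frac, element = rep(elem, length(kept)),
       copy = rep(seq_along(kept), each = n_at),
       cart = cart, n_copies = length(kept))
}

# do two symmetry copies represent the same molecule (up to lattice
# translation and atom reordering)?
.copies_coincide <- function(f, g, elem, cell, tol = 0.3) {
  M <- .orth_matrix(cell)
  n <- nrow(f)
  # all pairwise min-image fractional differences in one shot
  fi <- f[rep(seq_len(n), each = n), , drop = FALSE]
  gj <- g[rep(seq_len(n), times = n), , drop = FALSE]
  d <- gj - fi
  d <- d - round(d)
  dist2 <- rowSums((d %*% t(M))^2)
  same_elem <- elem[rep(seq_len(n), times = n)] == elem[rep(seq_len(n), each = n)]
  hit <- matrix(dist2 < tol^2 & same_elem, nrow = n, byrow = TRUE)
  all(rowSums(hit) > 0)
}

.shift27 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

#' Check a structure model for too-close intermolecular contacts
#'
#' Fails when any non-bonded distance between different symmetry copies (or
#' between a copy and its own periodic images) falls below `scale` times the
#' sum of the covalent radii. A distance exactly at the threshold passes
#' (strict inequality). Hydrogens are ignored by default.
#'
#' @param model a `structure_model`
#' @param scale threshold scale on the covalent-radius sum (default 0.7)
#' @param ignore_h exclude hydrogen atoms from the check?
#' @param placed optional pre-computed [place_in_cell()] result (shared with
#'   a subsequent simulation to avoid re-expanding the model)
#' @param early_exit stop at the first violation (faster; `worst` is then
#'   only an upper bound on the true minimum margin)
#' @return list with `pass` (logical) and `worst` (smallest margin found,
#'   Angstrom; negative = violation)
#' @export
check_contacts <- function(model, scale = 0.7, ignore_h = TRUE,
                           placed = NULL, early_exit = FALSE) {
  if (is.null(placed)) placed <- place_in_cell(model)
  keep <- if (ignore_h) placed$element != "H" else rep(TRUE, length(placed$element))
  if (!any(keep)) return(list(pass = TRUE, worst = Inf))
  radii <- scale * .covalent_radii[placed$element[keep]]
  M <- .orth_matrix(model$cell)
  shifts <- .shift27 %*% t(M)
  zero <- which(rowSums(abs(.shift27)) == 0)
  worst <- cpp_contact_margin(placed$cart[keep, , drop = FALSE],
                              placed$copy[keep], radii, shifts,
                              zero - 1L, early_exit)
  list(pass = worst >= 0, worst = worst)
}

#' Estimate a molar-volume range from atomic volume increments
#'
#' Sums shipped average atomic volume increments over the non-dummy atoms of
#' the molecule, optionally multiplied by a packing-correction factor (e.g.
#' 0.9 for densely pi-stacked planar molecules), and returns the symmetric
#' tolerance band used as the cell-volume filter of the global search.
#'
#' @param zm a `zmatrix` (or character vector of element symbols)
#' @param tolerance half-width of the band as a fraction (default 0.1)
#' @param packing_factor multiplier on the increment-sum estimate (default 1)
#' @return list with `estimate`, `lo`, `hi` in Angstrom^3 per molecule
#' @export
estimate_volume_range <- function(zm, tolerance = 0.1, packing_factor = 1) {
  elements <- if (inherits(zm, "zmatrix")) zm$element[zm$element != "X"]
              else zm[zm != "X"]
  if (length(elements) == 0L) stop("no atoms to estimate a volume from")
  unknown <- setdiff(unique(elements), names(.volume_increments))
  if (length(unknown))
    stop("no volume increment for element(s): ", paste(unknown, collapse = ", "))
  v <- sum(.volume_increments[elements]) * packing_factor
  list(estimate = v, lo = v * (1 - tolerance), hi = v * (1 + tolerance))
}

#' Molecular mass of a z-matrix molecule
#' @param zm a `zmatrix`
#' @return mass in g/mol (dummy atoms excluded)
#' @export
molecular_mass <- function(zm) {
  sum(.atomic_masses[zm$element[zm$element != "X"]])
}
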