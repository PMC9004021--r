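#' Reduce a unit cell (and transform a structure model consistently)
#'
#' Triclinic cells are brought to the Niggli reduced form by the
#' Krivy-Gruber algorithm, which also normalizes the angle signs so that all
#' three angles end up non-acute (or all acute). Monoclinic cells are brought
#' to the conventional setting with beta >= 90 degrees. Orthorhombic and
#' constrained cells are returned unchanged.
#'
#' When a `structure_model` is supplied, the anchor coordinates and
#' orientation angles are transformed along with the basis, so the described
#' crystal -- and therefore its simulated powder pattern -- is unchanged. If
#' the accumulated basis change is improper it is composed with the lattice
#' inversion, which leaves every powder pattern invariant.
#'
#' @param x a `unit_cell` or a `structure_model`
#' @return an object of the same class; for a `unit_cell` the integer basis
#'   transformation is attached as attribute `"transform"` (columns give the
#'   new basis vectors in the old basis)
#' @export
reduce_cell <- function(x) {
  if (inherits(x, "unit_cell")) {
    r <- .reduce_cell_impl(x, "triclinic")
    out <- r$cell
    attr(out, "transform") <- r$T
    return(out)
  }
  stopifnot(inherits(x, "structure_model"))
  model <- x
  system <- model$sg$system
  if (system == "orthorhombic") return(model)
  r <- .reduce_cell_impl(model$cell, system)
  if (all(r$T == diag(3))) return(model)
  Tinv <- solve(r$T)
  # new anchor; wrap into [0, 1)
  m_new <- as.numeric(Tinv %*% model$m) %% 1
  # orientation: cartesian placement must be preserved
  M_old <- .orth_matrix(model$cell)
  M_new <- .orth_matrix(r$cell)
  R_new <- M_new %*% Tinv %*% solve(M_old) %*% .rotation_matrix(model$phi)
  phi_new <- .euler_zyx(R_new)
  structure_model(r$cell, model$sg, model$zm, m = m_new, phi = phi_new,
                  tau = model$tau, fwhm = model$fwhm)
}

# Extract (phi_x, phi_y, phi_z) in degrees from R = Rz Ry Rx.
.euler_zyx <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-9) {
    x <- atan2(R[3, 2], R[3, 3])
    z <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold everything into phi_z
    x <- 0
    z <- atan2(-R[1, 2], R[2, 2])
  }
  c(x, y, z) * 180 / pi
}

.reduce_cell_impl <- function(cell, system) {
  if (system == "monoclinic") {
    if (cell$beta < 90) {
      Tm <- diag(c(-1, -1, 1))
      cell$beta <- 180 - cell$beta
      return(list(cell = cell, T = Tm))
    }
    return(list(cell = cell, T = diag(3)))
  }
  G0 <- t(.orth_matrix(cell)) %*% .orth_matrix(cell)
  T <- diag(3)
  eps <- 1e-5 * mean(c(cell$a, cell$b, cell$c))^2
  for (iter in 1:100) {
    G <- t(T) %*% G0 %*% T
    A <- G[1, 1]; B <- G[2, 2]; C <- G[3, 3]
    xi <- 2 * G[2, 3]; eta <- 2 * G[1, 3]; zeta <- 2 * G[1, 2]
    # step 1: order A <= B
    if (A > B + eps || (abs(A - B) <= eps && abs(xi) > abs(eta) + eps)) {
      T <- T %*% matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3)
      next
    }
    # step 2: order B <= C
    if (B > C + eps || (abs(B - C) <= eps && abs(eta) > abs(zeta) + eps)) {
      T <- T %*% matrix(c(-1, 0, 0, 0, 0, -1, 0, -1, 0), 3)
      next
    }
    if (xi * eta * zeta > 0) {
      # step 3: make all three positive
      i <- if (xi < -eps) -1 else 1
      j <- if (eta < -eps) -1 else 1
      k <- if (zeta < -eps) -1 else 1
      D <- diag(c(i, j, k))
      if (!all(D == diag(3))) { T <- T %*% D; next }
    } else {
      # step 4: make all three non-positive
      i <- if (xi > eps) -1 else 1
      j <- if (eta > eps) -1 else 1
      k <- if (zeta > eps) -1 else 1
      # an even number of flips keeps the product's sign; with an odd count
      # flip the remaining (zero-valued) parameter's axis as tie-break
      if (i * j * k < 0) {
        if (abs(xi) <= eps) i <- -1
        else if (abs(eta) <= eps) j <- -1
        else k <- -1
      }
      D <- diag(c(i, j, k))
      if (!all(D == diag(3))) { T <- T %*% D; next }
    }
    s <- function(v) if (v > 0) 1 else -1
    # step 5
    if (abs(xi) > B + eps ||
        (abs(xi - B) <= eps && 2 * eta < zeta - eps) ||
        (abs(xi + B) <= eps && zeta < -eps)) {
      M <- diag(3); M[2, 3] <- -s(xi)
      T <- T %*% M
      next
    }
    # step 6
    if (abs(eta) > A + eps ||
        (abs(eta - A) <= eps && 2 * xi < zeta - eps) ||
        (abs(eta + A) <= eps && zeta < -eps)) {
      M <- diag(3); M[1, 3] <- -s(eta)
      T <- T %*% M
      next
    }
    # step 7
    if (abs(zeta) > A + eps ||
        (abs(zeta - A) <= eps && 2 * xi < eta - eps) ||
        (abs(zeta + A) <= eps && eta < -eps)) {
      M <- diag(3); M[1, 2] <- -s(zeta)
      T <- T %*% M
      next
    }
    # step 8
    if (xi + eta + zeta + A + B < -eps ||
        (abs(xi + eta + zeta + A + B) <= eps && 2 * (A + eta) + zeta > eps)) {
      M <- diag(3); M[1, 3] <- 1; M[2, 3] <- 1
      T <- T %*% M
      next
    }
    break
  }
  if (det(T) < 0) T <- -T  # compose with the lattice inversion; keeps cells right-handed
  G <- t(T) %*% G0 %*% T
  a <- sqrt(G[1, 1]); b <- sqrt(G[2, 2]); c <- sqrt(G[3, 3])
  al <- acos(G[2, 3] / (b * c)) * 180 / pi
  be <- acos(G[1, 3] / (a * c)) * 180 / pi
  ga <- acos(G[1, 2] / (a * b)) * 180 / pi
  list(cell = unit_cell(a, b, c, al, be, ga), T = T)
}
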