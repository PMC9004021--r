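#' Space-group settings
#'
#' The package ships explicit operator tables for the space groups commonly
#' met in molecular crystal structure determination: P1, P-1, P21, P2/c,
#' P21/c, C2/m, C2/c, P212121, Pca21, Pna21 and Pbca (standard settings,
#' monoclinic b-unique). Other groups can be used by passing their general
#' positions as `"x,y,z"`-style triplets.
#'
#' @name spacegroups
NULL

.sg_triplets <- list(
  "P1"      = c("x,y,z"),
  "P-1"     = c("x,y,z", "-x,-y,-z"),
  "P21"     = c("x,y,z", "-x,y+1/2,-z"),
  "P2/c"    = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2"),
  "P21/c"   = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
  "C2/m"    = c("x,y,z", "-x,y,-z", "-x,-y,-z", "x,-y,z",
                "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z",
                "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z"),
  "C2/c"    = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
                "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
                "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2"),
  "P212121" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                "x+1/2,-y+1/2,-z"),
  "Pca21"   = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y,z", "-x+1/2,y,z+1/2"),
  "Pna21"   = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y+1/2,z", "-x+1/2,y+1/2,z+1/2"),
  "Pbca"    = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                "x+1/2,-y+1/2,-z", "-x,-y,-z", "x+1/2,y,-z+1/2",
                "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z"))

.sg_system <- c("P1" = "triclinic", "P-1" = "triclinic",
                "P21" = "monoclinic", "P2/c" = "monoclinic",
                "P21/c" = "monoclinic", "C2/m" = "monoclinic",
                "C2/c" = "monoclinic",
                "P212121" = "orthorhombic", "Pca21" = "orthorhombic",
                "Pna21" = "orthorhombic", "Pbca" = "orthorhombic")

# directions (1=x, 2=y, 3=z) along which the origin floats (polar directions);
# the corresponding anchor coordinates are fixed at 0 and dropped from the DOF.
.sg_floating <- list("P1" = 1:3, "P-1" = integer(0),
                     "P21" = 2L, "P2/c" = integer(0), "P21/c" = integer(0),
                     "C2/m" = integer(0), "C2/c" = integer(0),
                     "P212121" = integer(0),
                     "Pca21" = 3L, "Pna21" = 3L, "Pbca" = integer(0))

#' Parse a symmetry-operator triplet such as "-x,y+1/2,-z+1/2"
#' @param triplet character triplet
#' @return list with 3x3 rotation matrix `R` and translation vector `t`
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("\\s", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3L) stop("malformed symmetry triplet: ", triplet)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    # axis terms with optional sign
    for (ax in names(axes)) {
      m <- gregexpr(paste0("[+-]?", ax), expr)[[1]]
      if (m[1] != -1) {
        for (j in seq_along(m)) {
          tok <- substr(expr, m[j], m[j] + attr(m, "match.length")[j] - 1L)
          R[i, axes[ax]] <- R[i, axes[ax]] + if (startsWith(tok, "-")) -1 else 1
        }
      }
    }
    # translation as a fraction a/b or decimal
    rest <- gsub("[+-]?[xyz]", "", expr)
    if (nzchar(rest)) {
      m <- regmatches(rest, regexpr("[+-]?\\d+(/\\d+|\\.\\d+)?", rest))[[1]]
      if (length(m) == 1 && nzchar(m)) {
        t[i] <- if (grepl("/", m)) {
          ab <- as.numeric(strsplit(sub("^\\+", "", m), "/")[[1]])
          ab[1] / ab[2]
        } else as.numeric(m)
      }
    }
  }
  list(R = R, t = t %% 1)
}

format_symop <- function(op) {
  ax <- c("x", "y", "z")
  fr <- function(v) {
    if (abs(v) < 1e-9) return("")
    num <- round(v * 12)
    g <- .gcd(abs(num), 12L)
    paste0(if (v > 0) "+" else "-", abs(num) / g, "/", 12 / g)
  }
  paste(vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r != 0) s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r > 0) ""
                              else "-", ax[j])
    }
    paste0(s, fr(op$t[i]))
  }, character(1)), collapse = ",")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Construct a space-group setting
#'
#' @param symbol Hermann-Mauguin symbol of a shipped group (see
#'   [spacegroups]) or any label when `operators` are given explicitly
#' @param Zprime symmetry-independent molecules per asymmetric unit; values
#'   below 1 put the molecule on a special position
#' @param site_symmetry point-group label of the molecular site: `"1"`
#'   (general), `"-1"` (inversion centre), `"2"`, `"m"` or `"2/m"`
#' @param operators optional character vector of general-position triplets
#'   overriding the shipped table
#' @param system crystal system, required with explicit `operators`
#' @return an object of class `space_group_setting`
#' @export
space_group <- function(symbol, Zprime = 1, site_symmetry = "1",
                        operators = NULL, system = NULL) {
  if (is.null(operators)) {
    if (!symbol %in% names(.sg_triplets))
      stop("unsupported space group '", symbol,
           "'; pass its operators explicitly")
    operators <- .sg_triplets[[symbol]]
    system <- .sg_system[[symbol]]
    floating <- .sg_floating[[symbol]]
  } else {
    if (is.null(system)) stop("crystal system required with explicit operators")
    floating <- integer(0)
  }
  if (!site_symmetry %in% c("1", "-1", "2", "m", "2/m"))
    stop("unsupported site symmetry: ", site_symmetry)
  ops <- lapply(operators, parse_symop)
  sg <- structure(
    list(symbol = symbol, triplets = operators, ops = ops,
         n_ops = length(ops), Zprime = Zprime,
         Z = length(ops) * Zprime,
         site_symmetry = site_symmetry, system = system,
         floating = floating,
         centrosymmetric = any(vapply(ops, function(o)
           all(o$R == -diag(3)) && all(o$t == 0), logical(1)))),
    class = "space_group_setting")
  # pre-flattened operator matrices for the compiled reflection enumerator
  rots <- .laue_rotations(sg)
  sg$laue_mat <- t(vapply(rots, function(R) as.numeric(t(R)), numeric(9)))
  sg$ops_mat <- t(vapply(ops, function(op) c(as.numeric(t(op$R)), op$t),
                         numeric(12)))
  sg
}

#' @export
print.space_group_setting <- function(x, ...) {
  cat(sprintf("space group %s (%s), %d operators, Z' = %g, Z = %g, site %s\n",
              x$symbol, x$system, x$n_ops, x$Zprime, x$Z, x$site_symmetry))
  invisible(x)
}

# Is reflection hkl systematically absent?  True iff some operator maps hkl
# onto itself (h R = h) with a non-integral phase shift h . t.
.is_absent <- function(hkl, sg) {
  for (op in sg$ops) {
    if (all((hkl %*% op$R) == hkl)) {
      ph <- sum(hkl * op$t)
      if (abs(ph - round(ph)) > 1e-9) return(TRUE)
    }
  }
  FALSE
}

# Vectorized systematic-absence mask for an n x 3 integer matrix of hkl.
.absent_mask <- function(H, sg) {
  out <- rep(FALSE, nrow(H))
  for (op in sg$ops) {
    if (all(op$t == 0)) next
    HR <- H %*% op$R
    fixed <- HR[, 1] == H[, 1] & HR[, 2] == H[, 2] & HR[, 3] == H[, 3]
    if (any(fixed)) {
      ph <- H[fixed, , drop = FALSE] %*% op$t
      out[fixed] <- out[fixed] | abs(ph - round(ph)) > 1e-9
    }
  }
  out
}

# Rotation parts of the Laue group (point group plus inversion), unique.
.laue_rotations <- function(sg) {
  Rs <- lapply(sg$ops, `[[`, "R")
  Rs <- c(Rs, lapply(Rs, function(R) -R))
  keys <- vapply(Rs, function(R) paste(R, collapse = ","), character(1))
  Rs[!duplicated(keys)]
}
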