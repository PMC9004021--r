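#' Write a structure model as a CIF file
#'
#' Writes the cell, the symmetry operators as `_symmetry_equiv_pos_as_xyz`
#' and the fractional coordinates of the asymmetric molecule (one symmetry
#' copy; the operators regenerate the rest).
#'
#' @param model a `structure_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cif <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  placed <- place_in_cell(model)
  first <- placed$copy == 1L
  con <- file(path, "w")
  on.exit(close(con))
  cat(file = con, sep = "\n",
      "data_powsolve",
      sprintf("_cell_length_a    %.6f", model$cell$a),
      sprintf("_cell_length_b    %.6f", model$cell$b),
      sprintf("_cell_length_c    %.6f", model$cell$c),
      sprintf("_cell_angle_alpha %.6f", model$cell$alpha),
      sprintf("_cell_angle_beta  %.6f", model$cell$beta),
      sprintf("_cell_angle_gamma %.6f", model$cell$gamma),
      sprintf("_symmetry_space_group_name_H-M '%s'", model$sg$symbol),
      "loop_",
      "_symmetry_equiv_pos_as_xyz",
      sprintf("  '%s'", model$sg$triplets),
      "loop_",
      "_atom_site_label",
      "_atom_site_type_symbol",
      "_atom_site_fract_x",
      "_atom_site_fract_y",
      "_atom_site_fract_z",
      sprintf("%s%d %s %.6f %.6f %.6f",
              placed$element[first], seq_len(sum(first)),
              placed$element[first],
              placed$frac[first, 1], placed$frac[first, 2],
              placed$frac[first, 3]))
  invisible(path)
}

#' Read the CIF subset written by [write_cif()]
#'
#' Parses cell parameters, the space-group symbol, symmetry-operator
#' triplets and fractional coordinates. This is a minimal reader for the
#' package's own files and similarly plain CIFs, not a general CIF parser.
#'
#' @param path CIF file
#' @return list with `cell` (`unit_cell`), `symbol`, `triplets`, `frac`
#'   (n x 3 matrix), `element`
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0L) stop("CIF tag not found: ", tag)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"),
                    num("_cell_length_c"), num("_cell_angle_alpha"),
                    num("_cell_angle_beta"), num("_cell_angle_gamma"))
  sym_ln <- grep("_symmetry_space_group_name_H-M", lines, value = TRUE)
  symbol <- if (length(sym_ln))
    gsub(".*'(.*)'.*", "\\1", sym_ln[1]) else "P1"
  i_ops <- grep("_symmetry_equiv_pos_as_xyz", lines)
  triplets <- character(0)
  if (length(i_ops)) {
    j <- i_ops[1] + 1L
    while (j <= length(lines) && grepl("^\\s*'", lines[j])) {
      triplets <- c(triplets, gsub(".*'(.*)'.*", "\\1", lines[j]))
      j <- j + 1L
    }
  }
  i_sites <- grep("_atom_site_fract_z", lines)
  if (length(i_sites) == 0L) stop("no atom sites in ", path)
  j <- i_sites[1] + 1L
  elems <- character(0); coords <- list()
  while (j <= length(lines) && nzchar(trimws(lines[j])) &&
         !grepl("^(loop_|_|data_)", trimws(lines[j]))) {
    f <- strsplit(trimws(lines[j]), "\\s+")[[1]]
    elems <- c(elems, f[2])
    coords[[length(coords) + 1L]] <- as.numeric(f[3:5])
    j <- j + 1L
  }
  list(cell = cell, symbol = symbol, triplets = triplets,
       frac = do.call(rbind, coords), element = elems)
}

#' Turn a parsed CIF back into a structure model
#'
#' Recovers the anchor position and orientation by aligning the molecule
#' built from the z-matrix onto the CIF coordinates (assumed to list the
#' asymmetric molecule's atoms in z-matrix order, as files written by
#' [write_cif()] do; rigid-body alignment by the Kabsch procedure).
#'
#' @param cif list from [read_cif()]
#' @param zm the molecule's `zmatrix`
#' @param sg the `space_group_setting` to attach
#' @return a `structure_model`
#' @export
cif_to_model <- function(cif, zm, sg) {
  loc <- build_cartesian(zm)
  xyz <- loc$xyz[!loc$dummy, , drop = FALSE]
  if (nrow(cif$frac) != nrow(xyz))
    stop("CIF atom count does not match the z-matrix")
  M <- .orth_matrix(cif$cell)
  obs <- t(M %*% t(cif$frac))
  anchor <- colMeans(xyz)
  A <- sweep(xyz, 2, anchor)
  Bc <- sweep(obs, 2, colMeans(obs))
  S <- t(A) %*% Bc
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  phi <- .euler_zyx(R)
  m <- as.numeric(solve(M) %*% colMeans(obs)) %% 1
  structure_model(cif$cell, sg, zm, m = m, phi = phi)
}

#' Write molecule coordinates as an XYZ file
#' @param zm a `zmatrix`
#' @param path output file
#' @param tau optional free internal coordinate values
#' @return `path`, invisibly
#' @export
write_xyz <- function(zm, path, tau = NULL) {
  loc <- build_cartesian(zm, tau)
  keep <- !loc$dummy
  con <- file(path, "w")
  on.exit(close(con))
  cat(file = con, sep = "\n",
      as.character(sum(keep)), "molecule",
      sprintf("%s %12.6f %12.6f %12.6f", loc$element[keep],
              loc$xyz[keep, 1], loc$xyz[keep, 2], loc$xyz[keep, 3]))
  invisible(path)
}

#' Read a plain-text z-matrix
#'
#' Gaussian-style layout: one atom per line, `element [ref bond ref angle
#' ref dihedral]`, whitespace-separated, `#`-comments allowed. A value
#' suffixed with `*` marks that internal coordinate as free (a fitted tau).
#' Dummy atoms use element `X`.
#'
#' @param path text file
#' @return a `zmatrix`
#' @export
read_zmatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    val <- function(tok) as.numeric(sub("\\*$", "", tok))
    free <- function(tok) grepl("\\*$", tok)
    rows[[i]] <- data.frame(
      element = f[1],
      ref_bond = if (length(f) >= 3) as.integer(f[2]) else NA_integer_,
      bond = if (length(f) >= 3) val(f[3]) else NA_real_,
      ref_angle = if (length(f) >= 5) as.integer(f[4]) else NA_integer_,
      angle = if (length(f) >= 5) val(f[5]) else NA_real_,
      ref_dihedral = if (length(f) >= 7) as.integer(f[6]) else NA_integer_,
      dihedral = if (length(f) >= 7) val(f[7]) else NA_real_,
      free_bond = if (length(f) >= 3) free(f[3]) else FALSE,
      free_angle = if (length(f) >= 5) free(f[5]) else FALSE,
      free_dihedral = if (length(f) >= 7) free(f[7]) else FALSE)
  }
  zmatrix(do.call(rbind, rows))
}

#' Write a z-matrix in the plain-text format of [read_zmatrix()]
#' @param zm a `zmatrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_zmatrix <- function(zm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v, free) if (is.na(v)) "" else
    paste0(format(v, digits = 8), if (isTRUE(free)) "*" else "")
  for (i in seq_len(nrow(zm))) {
    parts <- c(zm$element[i])
    if (!is.na(zm$ref_bond[i]))
      parts <- c(parts, zm$ref_bond[i], fmt(zm$bond[i], zm$free_bond[i]))
    if (!is.na(zm$ref_angle[i]))
      parts <- c(parts, zm$ref_angle[i], fmt(zm$angle[i], zm$free_angle[i]))
    if (!is.na(zm$ref_dihedral[i]))
      parts <- c(parts, zm$ref_dihedral[i],
                 fmt(zm$dihedral[i], zm$free_dihedral[i]))
    writeLines(paste(parts, collapse = " "), con)
  }
  invisible(path)
}
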