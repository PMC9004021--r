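#' Powder diffraction patterns
#'
#' A `powder_pattern` is a diffractogram on a uniform 2-theta grid: a start
#' angle, a step and a vector of non-negative intensities, plus the wavelength
#' and a flag recording whether the background has been subtracted. All binary
#' pattern operations in the package put their second operand onto the grid of
#' the first before doing anything else.
#'
#' @param two_theta_start first grid point, degrees 2-theta
#' @param step grid step, degrees (> 0)
#' @param intensities numeric vector of intensities (>= 2 points)
#' @param wavelength radiation wavelength in Angstrom (default Cu K-alpha1)
#' @param background_corrected has the background been subtracted already?
#' @param label free-text label carried through I/O and reports
#' @return an object of class `powder_pattern`
#' @export
powder_pattern <- function(two_theta_start, step, intensities,
                           wavelength = 1.5406,
                           background_corrected = FALSE,
                           label = "") {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0,
            is.numeric(intensities), length(intensities) >= 2L,
            is.numeric(two_theta_start), length(two_theta_start) == 1L,
            wavelength > 0)
  structure(
    list(start = as.numeric(two_theta_start), step = as.numeric(step),
         intensities = as.numeric(intensities),
         wavelength = as.numeric(wavelength),
         background_corrected = isTRUE(background_corrected),
         label = as.character(label)),
    class = "powder_pattern")
}

#' Grid of a pattern
#' @param p a `powder_pattern`
#' @return numeric vector of 2-theta values, degrees
#' @export
two_theta <- function(p) {
  p$start + p$step * (seq_along(p$intensities) - 1L)
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf(
    "powder_pattern: %d points, 2theta %.3f-%.3f deg (step %.4f), lambda %.4f A%s%s\n",
    length(x$intensities), x$start,
    x$start + x$step * (length(x$intensities) - 1L), x$step, x$wavelength,
    if (x$background_corrected) ", background-corrected" else "",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Read a powder pattern from a two- or three-column text file
#'
#' Reads whitespace-separated `xy` (2-theta, intensity) or `xye` (with a third
#' column of uncertainties, currently parsed and discarded) files. Lines
#' starting with `#` or `!` are comments. Irregular grids are resampled onto a
#' uniform grid at the median step.
#'
#' @param path file path
#' @param format `"xy"` or `"xye"`
#' @param wavelength wavelength metadata to attach (not read from the file)
#' @param background_corrected metadata flag to attach
#' @param negative `"clamp"` (default: warn and clamp to zero) or `"error"`
#' @return a `powder_pattern`
#' @export
read_pattern <- function(path, format = c("xy", "xye"), wavelength = 1.5406,
                         background_corrected = FALSE,
                         negative = c("clamp", "error")) {
  format <- match.arg(format)
  negative <- match.arg(negative)
  if (!file.exists(path)) stop("pattern file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#!]|$)", lines)
  rows <- which(keep)
  if (length(rows) < 2L) stop("pattern file has fewer than 2 data rows: ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  tt <- vapply(fields, function(f) as.numeric(f[[1]]), numeric(1))
  ii <- vapply(fields, function(f) as.numeric(f[[2]]), numeric(1))
  if (anyNA(tt) || anyNA(ii)) {
    bad <- rows[which(is.na(tt) | is.na(ii))[1]]
    stop("unparseable numeric field at line ", bad, " of ", path)
  }
  dtt <- diff(tt)
  if (any(dtt <= 0)) {
    bad <- rows[which(dtt <= 0)[1] + 1L]
    stop("non-monotone 2theta at line ", bad, " of ", path)
  }
  if (any(ii < 0)) {
    if (negative == "error") stop("negative intensities in ", path)
    warning("negative intensities clamped to 0 in ", path)
    ii[ii < 0] <- 0
  }
  step <- stats::median(dtt)
  if (max(abs(dtt - step)) > 1e-6 * step) {
    # irregular grid: interpolate onto uniform grid at the median step
    n <- floor((tt[length(tt)] - tt[1]) / step) + 1L
    grid <- tt[1] + step * (seq_len(n) - 1L)
    ii <- stats::approx(tt, ii, xout = grid, rule = 2)$y
    tt <- grid
  }
  powder_pattern(tt[1], step, ii, wavelength = wavelength,
                 background_corrected = background_corrected,
                 label = basename(path))
}

#' Write a pattern as a two-column xy text file
#' @param p a `powder_pattern`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pattern <- function(p, path) {
  stopifnot(inherits(p, "powder_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", p$label), con)
  writeLines(sprintf("%.6f %.8g", two_theta(p), p$intensities), con)
  invisible(path)
}

#' Resample a pattern onto a new uniform grid
#'
#' Linear interpolation inside the source range, zero outside.
#'
#' @param p a `powder_pattern`
#' @param start new grid start, degrees
#' @param step new grid step, degrees
#' @param n number of points
#' @return a `powder_pattern` on the requested grid
#' @export
resample <- function(p, start, step, n) {
  stopifnot(inherits(p, "powder_pattern"), step > 0, n >= 2)
  src <- two_theta(p)
  grid <- start + step * (seq_len(n) - 1L)
  if (grid[n] < src[1] || grid[1] > src[length(src)])
    stop("resample target grid does not overlap the source range")
  if (isTRUE(all.equal(p$start, start)) &&
      isTRUE(all.equal(p$step, step)) && n == length(p$intensities))
    return(p)
  y <- stats::approx(src, p$intensities, xout = grid, yleft = 0, yright = 0)$y
  out <- p
  out$start <- start; out$step <- step; out$intensities <- y
  out
}

#' Put pattern `q` onto the grid of pattern `p`
#' @keywords internal
on_common_grid <- function(p, q) {
  resample(q, p$start, p$step, length(p$intensities))
}

#' Subtract a smooth background estimated by iterative peak clipping
#'
#' A SNIP-style estimator: the intensities are repeatedly replaced by the
#' minimum of themselves and the average of their neighbours at a decreasing
#' window, which strips peaks while following the smooth baseline. The
#' corrected intensities are clamped at zero.
#'
#' @param p a `powder_pattern` that is not yet background-corrected
#' @param window_deg widest clipping half-window in degrees (should exceed the
#'   widest peak FWHM; default 2)
#' @param iterations number of window-shrinking passes
#' @param smooth_points odd width (points) of the Savitzky-Golay pre-smoothing
#'   applied to the copy on which the baseline is estimated; keeps the
#'   min-clipping from tracking the lower noise envelope. 0 disables.
#' @return list with elements `pattern` (corrected, flagged) and `background`
#' @export
subtract_background <- function(p, window_deg = 2, iterations = 24,
                                smooth_points = 9) {
  stopifnot(inherits(p, "powder_pattern"))
  if (p$background_corrected)
    stop("pattern is already background-corrected")
  y <- p$intensities
  n <- length(y)
  ysm <- if (smooth_points >= 5 && n > 3 * smooth_points)
    signal::sgolayfilt(y, p = 2, n = smooth_points + (1 - smooth_points %% 2))
  else y
  wmax <- max(1L, min(round(window_deg / p$step), (n - 1L) %/% 2L))
  # decreasing windows give a conservative (low) baseline under peaks;
  # a dense ladder keeps the clipped chords close to the true baseline
  windows <- unique(pmax(1L, round(wmax * (iterations:1) / iterations)))
  if (wmax <= 128L) windows <- wmax:1L
  b <- ysm
  for (w in windows) {
    i <- (w + 1L):(n - w)
    avg <- (b[i - w] + b[i + w]) / 2
    b[i] <- pmin(b[i], avg)
  }
  corrected <- pmax(p$intensities - b, 0)
  bg <- p; bg$intensities <- b; bg$label <- paste0(p$label, " (background)")
  out <- p; out$intensities <- corrected; out$background_corrected <- TRUE
  list(pattern = out, background = bg)
}

#' Savitzky-Golay smoothing of a pattern
#'
#' Second-order polynomial smoothing, used for noisy low-count data before
#' peak extraction. Off by default throughout the package.
#'
#' @param p a `powder_pattern`
#' @param width odd filter width in points (default 11)
#' @return smoothed `powder_pattern`
#' @export
smooth_pattern <- function(p, width = 11) {
  stopifnot(inherits(p, "powder_pattern"))
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  out <- p
  out$intensities <- pmax(signal::sgolayfilt(p$intensities, p = 2, n = width), 0)
  out
}

#' Extract peaks from a background-corrected pattern
#'
#' Local maxima whose prominence (height above the higher of the two
#' surrounding minima separating them from taller peaks) exceeds
#' `min_prominence` times the global maximum. Positions are refined by a
#' parabola through the three points around each maximum.
#'
#' @param p a background-corrected `powder_pattern`
#' @param min_prominence prominence threshold as a fraction of the pattern
#'   maximum (default 0.02)
#' @return a data.frame with columns `position` (degrees) and `intensity`,
#'   ordered by position; zero rows if nothing qualifies
#' @export
extract_peaks <- function(p, min_prominence = 0.02) {
  stopifnot(inherits(p, "powder_pattern"))
  if (!p$background_corrected)
    stop("extract_peaks expects a background-corrected pattern")
  y <- p$intensities
  n <- length(y)
  ymax <- max(y)
  empty <- data.frame(position = numeric(0), intensity = numeric(0))
  if (ymax <= 0) return(empty)
  idx <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(idx) == 0L) return(empty)
  prom <- vapply(idx, function(i) {
    # walk outwards until a higher point is met; prominence is height above
    # the higher of the two minima found on the way (edge walks use the
    # lowest point seen, so a flat pedestal earns no prominence)
    lo_l <- y[i]; j <- i
    while (j > 1L && y[j] <= y[i]) { j <- j - 1L; lo_l <- min(lo_l, y[j]) }
    lo_r <- y[i]; j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1L; lo_r <- min(lo_r, y[j]) }
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence * ymax
  idx <- idx[keep]
  if (length(idx) == 0L) return(empty)
  tt <- two_theta(p)
  pos <- vapply(idx, function(i) {
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < .Machine$double.eps) 0 else
      0.5 * (y1 - y3) / denom
    tt[i] + delta * p$step
  }, numeric(1))
  o <- order(pos)
  data.frame(position = pos[o], intensity = y[idx][o])
}

#' Estimate the reflection FWHM of a pattern from its extracted peaks
#'
#' Renders a stick pattern from the peak positions and intensities at trial
#' FWHM values and maximizes the narrow-window similarity of the rendered and
#' observed patterns by golden-section search. No indexing and no structural
#' model are involved.
#'
#' @param p a background-corrected `powder_pattern`
#' @param peaks data.frame from [extract_peaks()]
#' @param shape peak-shape kind: `"pseudo_voigt"`, `"gaussian"` or
#'   `"lorentzian"`
#' @param eta pseudo-Voigt mixing fraction
#' @param l_small narrow neighbouring range for the comparison, degrees
#' @param interval search interval for the FWHM, degrees
#' @return estimated FWHM in degrees
#' @export
estimate_fwhm <- function(p, peaks, shape = "pseudo_voigt", eta = 0.5,
                          l_small = 0.1, interval = c(0.01, 2)) {
  stopifnot(inherits(p, "powder_pattern"), l_small > 0)
  if (nrow(peaks) == 0L) stop("estimate_fwhm needs at least one peak")
  n <- length(p$intensities)
  score <- function(fwhm) {
    sim <- powder_pattern(p$start, p$step,
                          cpp_render(peaks$position, peaks$intensity, fwhm,
                                     .shape_kind(shape), eta,
                                     p$start, p$step, n, 6),
                          wavelength = p$wavelength,
                          background_corrected = TRUE)
    s12(p, sim, l = l_small)$value
  }
  opt <- stats::optimize(score, interval = interval, maximum = TRUE,
                         tol = 1e-4)
  opt$maximum
}

.shape_kind <- function(shape) {
  switch(shape, gaussian = 0L, lorentzian = 1L, pseudo_voigt = 2L,
         stop("unknown peak shape: ", shape))
}
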