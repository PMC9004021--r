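#' Free-parameter vector of a structure model
#'
#' Packs the parameters not fixed by symmetry into a named numeric vector in
#' canonical order: free cell parameters, free anchor coordinates, free
#' orientation angles, free internal coordinates, optionally the profile
#' FWHM. Each parameter carries a class used for step sizes and
#' finite-difference deltas: `length` (Angstrom), `cell_angle` (degrees),
#' `fraction`, `rotation` (degrees), `tau_length`, `tau_angle`.
#'
#' @param model a `structure_model`
#' @param fit_fwhm include the profile FWHM as an extra fitted scalar?
#' @return data.frame with columns `name`, `value`, `class`
#' @export
model_parameters <- function(model, fit_fwhm = FALSE) {
  sg <- model$sg
  cellpar <- switch(sg$system,
                    triclinic = c("a", "b", "c", "alpha", "beta", "gamma"),
                    monoclinic = c("a", "b", "c", "beta"),
                    orthorhombic = c("a", "b", "c"))
  m_free <- switch(sg$site_symmetry,
                   "1" = setdiff(1:3, sg$floating),
                   "-1" = integer(0), "2/m" = integer(0),
                   "2" = 2L, "m" = c(1L, 3L))
  phi_free <- if (sg$site_symmetry %in% c("1", "-1")) 1:3 else 2L
  xyz <- c("x", "y", "z")
  name <- c(cellpar, paste0("m_", xyz[m_free], recycle0 = TRUE),
            paste0("phi_", xyz[phi_free], recycle0 = TRUE),
            if (length(model$tau)) paste0("tau_", seq_along(model$tau)),
            if (fit_fwhm) "fwhm")
  value <- c(unlist(model$cell[cellpar], use.names = FALSE),
             model$m[m_free], model$phi[phi_free], model$tau,
             if (fit_fwhm) model$fwhm %||% 0.3)
  class <- c(ifelse(cellpar %in% c("a", "b", "c"), "length", "cell_angle"),
             rep("fraction", length(m_free)),
             rep("rotation", length(phi_free)),
             if (length(model$tau)) .tau_classes(model$zm),
             if (fit_fwhm) "length")
  data.frame(name = name, value = value, class = class)
}

.tau_classes <- function(zm) {
  cls <- character(0)
  for (i in seq_len(nrow(zm))) {
    if (isTRUE(zm$free_bond[i])) cls <- c(cls, "tau_length")
    if (isTRUE(zm$free_angle[i])) cls <- c(cls, "tau_angle")
    if (isTRUE(zm$free_dihedral[i])) cls <- c(cls, "tau_angle")
  }
  cls
}

#' Rebuild a structure model from a free-parameter vector
#'
#' Inverse of [model_parameters()]. Anchor fractions are wrapped into
#' `[0, 1)`; angles are taken as given (fits work on unwrapped angles).
#'
#' @param model template `structure_model`
#' @param values named numeric vector in the order of [model_parameters()]
#' @param fit_fwhm whether `values` carries a trailing FWHM entry
#' @param info optional pre-computed [model_parameters()] table (avoids
#'   recomputation in optimizer loops)
#' @return updated `structure_model`, or `NULL` if the values describe an
#'   invalid cell
#' @export
set_model_parameters <- function(model, values, fit_fwhm = FALSE,
                                 info = NULL) {
  if (is.null(info)) info <- model_parameters(model, fit_fwhm = fit_fwhm)
  stopifnot(length(values) == nrow(info))
  cell <- model$cell; m <- model$m; phi <- model$phi; tau <- model$tau
  fwhm <- model$fwhm
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]; v <- values[i]
    if (nm %in% c("a", "b", "c", "alpha", "beta", "gamma")) cell[[nm]] <- v
    else if (startsWith(nm, "m_"))
      m[match(sub("m_", "", nm), c("x", "y", "z"))] <- v %% 1
    else if (startsWith(nm, "phi_"))
      phi[match(sub("phi_", "", nm), c("x", "y", "z"))] <- v
    else if (startsWith(nm, "tau_")) tau[as.integer(sub("tau_", "", nm))] <- v
    else if (nm == "fwhm") fwhm <- max(v, 0.02)
  }
  if (cell$a <= 0 || cell$b <= 0 || cell$c <= 0 ||
      any(c(cell$alpha, cell$beta, cell$gamma) <= 5) ||
      any(c(cell$alpha, cell$beta, cell$gamma) >= 175))
    return(NULL)
  disc <- .cell_discriminant(cell)
  if (!is.finite(disc) || disc <= 1e-6) return(NULL)
  structure_model(unit_cell(cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                            cell$gamma),
                  model$sg, model$zm, m = m, phi = phi, tau = tau, fwhm = fwhm)
}

# default coordinate-wise step sizes per parameter class
.default_steps <- c(length = 0.03, cell_angle = 0.3, fraction = 0.01,
                    rotation = 3, tau_length = 0.03, tau_angle = 3)

#' Similarity cost of a structure model against an experimental pattern
#'
#' Simulates the model's pattern and returns its similarity to the
#' (background-corrected) experimental pattern, optionally multiplied by a
#' smooth restraint factor `exp(-(excess/width)^2)` for every parameter that
#' has strayed outside its search range (width = 10% of the range span).
#' Restraints never clip a trajectory; they only damp the score.
#'
#' @param model a `structure_model`
#' @param exp experimental `powder_pattern` (background-corrected)
#' @param l neighbouring range in degrees; `0` gives the pointwise limit
#' @param range optional 2-theta comparison window
#' @param cfg a [sim_config()]
#' @param space optional `search_space` providing the restraint ranges
#' @param placed optional pre-computed [place_in_cell()] result
#' @return similarity value (possibly restraint-damped), or `-1` for models
#'   whose cell is invalid
#' @export
cost <- function(model, exp, l = 1, range = NULL, cfg = sim_config(),
                 space = NULL, placed = NULL) {
  if (is.null(model)) return(-1)
  sim <- try(simulate_pattern(model, cfg, placed = placed), silent = TRUE)
  if (inherits(sim, "try-error")) return(-1)
  if (all(sim$intensities == 0)) return(0)
  val <- .s12_value(exp, sim, l = l, range = range)
  if (!is.null(space)) val <- val * .restraint_factor(model, space)
  val
}

# weight vectors for the discrete triangular window, cached on (l, step, K)
.weight_cache <- new.env(parent = emptyenv())

.triangle_weights <- function(l, step) {
  K <- floor(l / step)
  key <- sprintf("%.9g|%.9g", l, step)
  w <- get0(key, envir = .weight_cache, inherits = FALSE)
  if (is.null(w)) {
    w <- weight_triangular((0:K) * step, l)
    assign(key, w, envir = .weight_cache)
  }
  w
}

# fast scoring path: both patterns already on the same grid, or the
# simulated pattern a leading sub-grid of the experimental one (restricted
# comparison range)
.s12_value <- function(exp, sim, l, range = NULL) {
  n_exp <- length(exp$intensities)
  n_sim <- length(sim$intensities)
  aligned <- abs(exp$start - sim$start) < 1e-9 &&
    abs(exp$step - sim$step) < 1e-9 && n_sim <= n_exp
  if (!aligned)
    return(if (l <= 0)
             s12(exp, sim, zero_limit = TRUE, range_2theta = range)$value
           else s12(exp, sim, l = l, range_2theta = range)$value)
  I1 <- if (n_sim < n_exp) exp$intensities[seq_len(n_sim)] else exp$intensities
  I2 <- sim$intensities
  if (!is.null(range)) {
    tt <- two_theta(exp)
    keep <- tt >= range[1] & tt <= range[2]
    I1 <- I1[keep]; I2 <- I2[keep]
  }
  if (all(I2 == 0) || all(I1 == 0)) return(0)
  if (l <= 0) return(sum(I1 * I2) / sqrt(sum(I1^2) * sum(I2^2)))
  w <- .triangle_weights(l, exp$step)
  sums <- cpp_s12_sums(I1, I2, length(w) - 1L, w)
  sums[1] / sqrt(sums[2] * sums[3])
}

.restraint_factor <- function(model, space) {
  info <- model_parameters(model)
  b <- .restraint_bounds(info, space)
  .restraint_values(info$value, b$lo, b$hi)
}

# match search-space ranges onto a parameter-info table once per fit
.restraint_bounds <- function(info, space) {
  j <- match(info$name, space$params$name)
  list(lo = space$params$lo[j], hi = space$params$hi[j])
}

# vectorized smooth out-of-range penalty; NA bounds are unrestrained
.restraint_values <- function(v, lo, hi) {
  ok <- !is.na(lo)
  if (!any(ok)) return(1)
  width <- 0.1 * (hi[ok] - lo[ok])
  excess <- pmax(lo[ok] - v[ok], v[ok] - hi[ok], 0)
  if (all(excess == 0)) return(1)
  prod(exp(-(excess / width)^2))
}

#' Coordinate-wise hill-climb maximization of the similarity
#'
#' Trial moves of +/- one step per free parameter; the best improving move is
#' accepted; when no move improves, all steps are halved. Stops when the
#' improvement of a full sweep falls below `min_improvement`, the steps have
#' been halved `max_halvings` times, or `max_iterations` accepted moves have
#' been made. The most robust (and most expensive) of the local optimizers.
#'
#' @param model starting `structure_model`
#' @param exp experimental pattern
#' @param l neighbouring range, degrees
#' @param cfg a [sim_config()]
#' @param space optional `search_space` for boundary restraints
#' @param range optional 2-theta comparison window
#' @param step_sizes named per-class steps (see [model_parameters()])
#' @param max_iterations cap on accepted moves
#' @param min_improvement sweep-improvement convergence threshold
#' @param max_halvings number of step-halving rounds before stopping
#' @param fit_fwhm also fit the profile FWHM?
#' @return a `fit_result`: list with `model`, `value` (final cost),
#'   `trace` (data.frame of accepted values), `n_evals`
#' @export
hill_climb <- function(model, exp, l = 1, cfg = sim_config(), space = NULL,
                       range = NULL, step_sizes = .default_steps,
                       max_iterations = 200, min_improvement = 1e-4,
                       max_halvings = 4, fit_fwhm = FALSE) {
  info <- model_parameters(model, fit_fwhm = fit_fwhm)
  par <- info$value
  steps <- unname(step_sizes[info$class])
  steps[is.na(steps)] <- 0.03
  if (fit_fwhm) steps[info$name == "fwhm"] <- 0.05
  bounds <- if (!is.null(space)) .restraint_bounds(info, space)
  evals <- 0L
  f <- function(v) {
    evals <<- evals + 1L
    val <- cost(set_model_parameters(model, v, fit_fwhm = fit_fwhm,
                                     info = info),
                exp, l = l, range = range, cfg = cfg)
    if (!is.null(bounds)) val <- val * .restraint_values(v, bounds$lo, bounds$hi)
    val
  }
  cur <- f(par)
  trace <- data.frame(iteration = 0L, value = cur)
  halvings <- 0L
  accepted <- 0L
  repeat {
    sweep_start <- cur
    improved <- TRUE
    while (improved && accepted < max_iterations) {
      improved <- FALSE
      best_v <- cur; best_par <- NULL
      for (i in seq_along(par)) {
        for (s in c(1, -1)) {
          cand <- par
          cand[i] <- cand[i] + s * steps[i]
          v <- f(cand)
          if (v > best_v) { best_v <- v; best_par <- cand }
        }
      }
      if (!is.null(best_par) && best_v > cur + .Machine$double.eps) {
        par <- best_par; cur <- best_v
        accepted <- accepted + 1L
        trace <- rbind(trace, data.frame(iteration = accepted, value = cur))
        improved <- TRUE
      }
    }
    if (accepted >= max_iterations) break
    if (cur - sweep_start < min_improvement && halvings >= 1L) break
    if (halvings >= max_halvings) break
    steps <- steps / 2
    halvings <- halvings + 1L
  }
  final <- set_model_parameters(model, par, fit_fwhm = fit_fwhm)
  structure(list(model = final, value = cur, trace = trace, n_evals = evals),
            class = "fit_result")
}

#' Conjugate-gradient maximization of the similarity
#'
#' Numerical-gradient conjugate-gradient ascent (the fast "raw fit"
#' optimizer). The cost surface is rescaled per parameter class so that
#' lengths, angles and fractions move on comparable scales.
#'
#' @inheritParams hill_climb
#' @param maxit iteration cap for the optimizer
#' @param reltol relative convergence tolerance
#' @return a `fit_result` (trace records the improving evaluations)
#' @export
gradient_fit <- function(model, exp, l = 1, cfg = sim_config(), space = NULL,
                         range = NULL, step_sizes = .default_steps,
                         maxit = 40, reltol = 1e-5, fit_fwhm = FALSE) {
  info <- model_parameters(model, fit_fwhm = fit_fwhm)
  par <- info$value
  scales <- unname(step_sizes[info$class])
  scales[is.na(scales)] <- 0.03
  bounds <- if (!is.null(space)) .restraint_bounds(info, space)
  state <- new.env(parent = emptyenv())
  state$best <- -Inf; state$best_par <- par
  state$evals <- 0L
  state$trace <- list()
  f <- function(v) {
    state$evals <- state$evals + 1L
    val <- cost(set_model_parameters(model, v, fit_fwhm = fit_fwhm,
                                     info = info), exp,
                l = l, range = range, cfg = cfg)
    if (!is.null(bounds)) val <- val * .restraint_values(v, bounds$lo, bounds$hi)
    if (val > state$best) {
      state$best <- val; state$best_par <- v
      state$trace[[length(state$trace) + 1L]] <-
        data.frame(iteration = state$evals, value = val)
    }
    val
  }
  # finite-difference deltas of roughly one third of a coordinate step:
  # large enough to see over the grid discretization of the pattern
  ndeps <- pmax(scales / 3, 1e-4) / scales
  res <- try(stats::optim(par, f, method = "CG",
                          control = list(fnscale = -1, maxit = maxit,
                                         reltol = reltol,
                                         parscale = scales, ndeps = ndeps)),
             silent = TRUE)
  par_out <- if (inherits(res, "try-error")) state$best_par
             else if (res$value >= state$best) res$par else state$best_par
  final <- set_model_parameters(model, par_out, fit_fwhm = fit_fwhm)
  value <- max(state$best, if (!inherits(res, "try-error")) res$value else -Inf)
  trace <- if (length(state$trace)) do.call(rbind, state$trace)
           else data.frame(iteration = integer(0), value = numeric(0))
  structure(list(model = final, value = value, trace = trace,
                 n_evals = state$evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit result: value %.4f after %d evaluations\n",
              x$value, x$n_evals))
  invisible(x)
}

#' Staged fitting schedule
#'
#' An ordered list of local-fit stages with non-increasing neighbouring
#' range: a broad window first smooths the similarity surface for large
#' corrections, narrower windows then sharpen the fit.
#'
#' @param l per-stage neighbouring ranges, degrees (non-increasing)
#' @param algorithm per-stage optimizer, `"conjugate_gradient"` or
#'   `"hill_climb"` (recycled)
#' @param max_iterations per-stage iteration caps (recycled)
#' @param min_improvement per-stage convergence thresholds (recycled)
#' @param range optional per-stage 2-theta windows (list, recycled)
#' @param fit_fwhm fit the FWHM in the final stage?
#' @return a `fit_schedule`
#' @export
fit_schedule <- function(l, algorithm = "hill_climb",
                         max_iterations = 200, min_improvement = 1e-4,
                         range = list(NULL), fit_fwhm = FALSE) {
  if (any(diff(l) > 1e-12)) stop("stage l values must be non-increasing")
  n <- length(l)
  stages <- lapply(seq_len(n), function(i) list(
    l = l[i],
    algorithm = rep_len(algorithm, n)[i],
    max_iterations = rep_len(max_iterations, n)[i],
    min_improvement = rep_len(min_improvement, n)[i],
    range = rep_len(range, n)[[i]],
    fit_fwhm = fit_fwhm && i == n))
  structure(list(stages = stages), class = "fit_schedule")
}

#' Run a multi-stage local fit
#'
#' Executes the schedule's stages in order, passing the best model forward.
#' The final stage may additionally treat the profile FWHM as one extra
#' fitted scalar (the standard move of a fine fit). The reference similarity
#' of the final model is reported alongside the per-stage costs.
#'
#' @param model starting `structure_model`
#' @param exp experimental pattern
#' @param schedule a [fit_schedule()]
#' @param cfg a [sim_config()]
#' @param space optional `search_space` for boundary restraints
#' @return a `fit_result` with extra fields `stage_values` and `ref_sim`;
#'   the trace gains a `stage` column
#' @export
staged_fit <- function(model, exp, schedule, cfg = sim_config(),
                       space = NULL) {
  stopifnot(inherits(schedule, "fit_schedule"))
  cur <- model
  traces <- list()
  stage_values <- numeric(0)
  n_evals <- 0L
  for (si in seq_along(schedule$stages)) {
    st <- schedule$stages[[si]]
    fit <- if (st$algorithm == "conjugate_gradient")
      gradient_fit(cur, exp, l = st$l, cfg = cfg, space = space,
                   range = st$range, maxit = st$max_iterations,
                   reltol = st$min_improvement, fit_fwhm = st$fit_fwhm)
    else
      hill_climb(cur, exp, l = st$l, cfg = cfg, space = space,
                 range = st$range, max_iterations = st$max_iterations,
                 min_improvement = st$min_improvement,
                 fit_fwhm = st$fit_fwhm)
    cur <- fit$model %||% cur
    n_evals <- n_evals + fit$n_evals
    stage_values <- c(stage_values, fit$value)
    if (nrow(fit$trace)) traces[[si]] <- cbind(stage = si, fit$trace)
  }
  sim <- simulate_pattern(cur, cfg)
  refs <- reference_similarity(exp, sim)$value
  structure(list(model = cur, value = stage_values[length(stage_values)],
                 stage_values = stage_values,
                 trace = if (length(traces)) do.call(rbind, traces)
                         else data.frame(stage = integer(0),
                                         iteration = integer(0),
                                         value = numeric(0)),
                 ref_sim = refs, n_evals = n_evals),
            class = "fit_result")
}
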