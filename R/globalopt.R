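#' Search spaces
#'
#' Per-parameter sampling ranges plus a molar-volume window for a given
#' crystal symmetry. Ranges apply to the random starting structures only;
#' local-fit trajectories may leave them (subject to the smooth boundary
#' restraint) and the auto-focusing mechanism may later narrow, shift or
#' widen them.
#'
#' @param params data.frame with columns `name`, `lo`, `hi`, `class`
#' @param volume molar-volume window `c(lo, hi)` in Angstrom^3 per molecule
#' @param limits optional physical clip bounds per parameter (data.frame like
#'   `params`); defaults to the initial ranges widened by 50%
#' @return a `search_space`
#' @export
search_space <- function(params, volume, limits = NULL) {
  stopifnot(all(c("name", "lo", "hi", "class") %in% names(params)),
            all(params$lo < params$hi), volume[1] < volume[2])
  if (is.null(limits)) {
    span <- params$hi - params$lo
    limits <- params
    limits$lo <- params$lo - 0.5 * span
    limits$hi <- params$hi + 0.5 * span
  }
  structure(list(params = params, volume = volume, limits = limits),
            class = "search_space")
}

#' Build the default search space for a molecule and symmetry
#'
#' Cell-length ranges are derived from the spatial dimensions of the
#' molecule, the molar-volume window from atomic volume increments, free
#' cell angles span 60-120 degrees, anchor fractions the unit interval and
#' orientation angles the full circle. Ranges of free internal coordinates
#' default to +/-10% (bonds), +/-20 degrees (angles) and the full circle
#' (dihedrals) around their z-matrix values.
#'
#' @param zm a `zmatrix`
#' @param sg a `space_group_setting`
#' @param volume_tolerance half-width of the molar-volume band (fraction)
#' @param packing_factor multiplier on the increment volume estimate
#' @param length_margin added to the molecular diameter for the upper cell
#'   length bound, Angstrom
#' @return a `search_space`
#' @export
make_search_space <- function(zm, sg, volume_tolerance = 0.1,
                              packing_factor = 1, length_margin = 6) {
  loc <- build_cartesian(zm)
  xyz <- loc$xyz[!loc$dummy, , drop = FALSE]
  D <- if (nrow(xyz) > 1) max(stats::dist(xyz)) else 2
  vr <- estimate_volume_range(zm, tolerance = volume_tolerance,
                              packing_factor = packing_factor)
  tmp_cell <- unit_cell(5, 5, 5)
  tmpl <- structure_model(tmp_cell, sg, zm)
  info <- model_parameters(tmpl)
  lo <- numeric(nrow(info)); hi <- numeric(nrow(info))
  tau_cls <- .tau_classes(zm)
  tau_val <- free_tau_values(zm)
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    # 3.2 A lower bound: the shortest axes of molecular crystals are the
    # pi-stacking distances, and shorter axes would put their first
    # reflection outside a typical measurement window
    if (nm %in% c("a", "b", "c")) { lo[i] <- 3.2; hi[i] <- D + length_margin }
    else if (nm %in% c("alpha", "beta", "gamma")) { lo[i] <- 60; hi[i] <- 120 }
    else if (startsWith(nm, "m_")) { lo[i] <- 0; hi[i] <- 1 }
    else if (startsWith(nm, "phi_")) { lo[i] <- -180; hi[i] <- 180 }
    else if (startsWith(nm, "tau_")) {
      j <- as.integer(sub("tau_", "", nm))
      if (tau_cls[j] == "tau_length") {
        lo[i] <- 0.9 * tau_val[j]; hi[i] <- 1.1 * tau_val[j]
      } else {
        # angles get +/-20 deg, dihedrals the full circle
        is_dihedral <- .tau_is_dihedral(zm)[j]
        if (is_dihedral) { lo[i] <- -180; hi[i] <- 180 }
        else { lo[i] <- tau_val[j] - 20; hi[i] <- tau_val[j] + 20 }
      }
    }
  }
  search_space(data.frame(name = info$name, lo = lo, hi = hi,
                          class = info$class),
               volume = c(vr$lo, vr$hi))
}

.tau_is_dihedral <- function(zm) {
  out <- logical(0)
  for (i in seq_len(nrow(zm))) {
    if (isTRUE(zm$free_bond[i])) out <- c(out, FALSE)
    if (isTRUE(zm$free_angle[i])) out <- c(out, FALSE)
    if (isTRUE(zm$free_dihedral[i])) out <- c(out, TRUE)
  }
  out
}

#' Draw a random trial structure from a search space
#'
#' Free cell parameters are drawn uniformly with rejection until the molar
#' volume V/Z falls inside the volume window; anchor fractions and internal
#' coordinates uniformly in range; the orientation uniformly over rotations
#' (random unit quaternion, decomposed into the model's Euler angles). Uses
#' the current R random number stream; seed control is the caller's.
#'
#' @param space a `search_space`
#' @param sg a `space_group_setting`
#' @param zm a `zmatrix`
#' @param fwhm profile FWHM to attach to the model (optional)
#' @return a `structure_model`
#' @export
sample_trial <- function(space, sg, zm, fwhm = NULL) {
  p <- space$params
  cell_idx <- which(p$name %in% c("a", "b", "c", "alpha", "beta", "gamma"))
  tmpl <- structure_model(unit_cell(5, 5, 5), sg, zm)
  for (attempt in seq_len(1e5)) {
    vals <- stats::runif(length(cell_idx), p$lo[cell_idx], p$hi[cell_idx])
    cell <- list(a = 5, b = 5, c = 5, alpha = 90, beta = 90, gamma = 90)
    for (j in seq_along(cell_idx)) cell[[p$name[cell_idx[j]]]] <- vals[j]
    disc <- .cell_discriminant(cell)
    if (!is.finite(disc) || disc <= 1e-6) next
    V <- cell$a * cell$b * cell$c * sqrt(disc)
    vz <- V / sg$Z
    if (vz >= space$volume[1] && vz <= space$volume[2]) {
      cellobj <- unit_cell(cell$a, cell$b, cell$c, cell$alpha, cell$beta,
                           cell$gamma)
      m <- c(0, 0, 0); phi <- c(0, 0, 0); tau <- free_tau_values(zm)
      for (i in seq_len(nrow(p))) {
        nm <- p$name[i]
        if (startsWith(nm, "m_"))
          m[match(sub("m_", "", nm), c("x", "y", "z"))] <-
            stats::runif(1, p$lo[i], p$hi[i])
        else if (startsWith(nm, "tau_"))
          tau[as.integer(sub("tau_", "", nm))] <- stats::runif(1, p$lo[i], p$hi[i])
      }
      phi_free <- p$name[startsWith(p$name, "phi_")]
      if (length(phi_free) == 3L) {
        q <- stats::rnorm(4)
        q <- q / sqrt(sum(q^2))
        R <- .quat_to_matrix(q)
        phi <- .euler_zyx(R)
      } else if (length(phi_free) >= 1L) {
        for (nm in phi_free) {
          i <- which(p$name == nm)
          phi[match(sub("phi_", "", nm), c("x", "y", "z"))] <-
            stats::runif(1, p$lo[i], p$hi[i])
        }
      }
      return(structure_model(cellobj, sg, zm, m = m, phi = phi, tau = tau,
                             fwhm = fwhm))
    }
  }
  stop("could not sample a cell inside the volume window after 1e5 draws; ",
       "cell and volume ranges appear inconsistent")
}

.quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

#' Dynamic stage thresholds for the hierarchical search
#'
#' @param S_sel pre-selection threshold on the broad-window similarity
#' @param S_opt post-raw-fit threshold gating the accurate-fit cycle
#' @param l_broad broad neighbouring range for pre-selection, degrees
#' @param targets target computing-cost fractions for the three stage groups
#'   (trial generation + pre-selection, raw fits, accurate fits)
#' @param warmup number of trials evaluated before adaptation starts
#' @return a `go_thresholds`
#' @export
go_thresholds <- function(S_sel = 0.55, S_opt = 0.80, l_broad = 1.5,
                          targets = c(0.4, 0.3, 0.3), warmup = 100) {
  stopifnot(S_sel > 0, S_sel <= S_opt, S_opt < 1,
            length(targets) == 3, abs(sum(targets) - 1) < 1e-9)
  structure(list(S_sel = S_sel, S_opt = S_opt, l_broad = l_broad,
                 targets = targets, warmup = warmup),
            class = "go_thresholds")
}

#' Adapt the stage thresholds to balance stage costs
#'
#' A setpoint controller on the gate pass rates. From the moving-average
#' cost of one trial, one raw fit and one accurate-fit cycle (in
#' deterministic pattern-simulation units), the pass rates that would split
#' the computing cost according to the stage targets are computed directly,
#' and each gate is set to the empirical quantile of its recent score stream
#' that realizes that rate. Gates already balanced within the deadband are
#' left alone.
#'
#' @param t a `go_thresholds`
#' @param stats list with `frac` (observed cost fractions of the three stage
#'   groups), `cost_per` (named averages: `trial`, `go3`, `go4`),
#'   `recent_sel` (recent pre-selection scores), `recent_opt` (recent
#'   post-raw-fit scores)
#' @param deadband relative cost-imbalance tolerated without adjustment
#' @return updated `go_thresholds`
#' @export
adapt_thresholds <- function(t, stats, deadband = 0.1) {
  frac <- stats$frac
  cp <- stats$cost_per
  balanced <- function(i) abs(frac[i] - t$targets[i]) <= deadband * t$targets[i]
  if (length(stats$recent_sel) >= 20 && !(balanced(2))) {
    # pass rate that makes raw-fit cost = (target3/target12) x trial cost
    r_sel <- t$targets[2] / t$targets[1] * cp[["trial"]] / max(cp[["go3"]], 1)
    r_sel <- min(max(r_sel, 1e-4), 0.5)
    newt <- stats::quantile(stats$recent_sel, probs = 1 - r_sel,
                            names = FALSE, type = 7)
    t$S_sel <- min(max(newt, 0.2), 0.995)
  }
  if (length(stats$recent_opt) >= 20 && !(balanced(3))) {
    r_opt <- t$targets[3] / t$targets[2] * cp[["go3"]] / max(cp[["go4"]], 1)
    r_opt <- min(max(r_opt, 0.01), 0.9)
    newt <- stats::quantile(stats$recent_opt, probs = 1 - r_opt,
                            names = FALSE, type = 7)
    t$S_opt <- min(max(newt, t$S_sel), 0.999)
  }
  t
}

#' Evaluate one trial structure through the staged filter hierarchy
#'
#' Stage 1 checks the molar volume and intermolecular contacts without any
#' pattern simulation; stage 2 simulates and compares with a broad
#' neighbouring range; stage 3 runs the fast conjugate-gradient raw fit;
#' stage 4 a cycle of hill-climb refits with a narrowing window. Survivors
#' become candidates whose integer weight counts the levels passed.
#'
#' @param model trial `structure_model`
#' @param exp background-corrected experimental pattern
#' @param thr a `go_thresholds`
#' @param cfg a [sim_config()]
#' @param space a `search_space`
#' @param control list of stage controls: `go3_maxit`, `go3_algorithm`,
#'   `go4_cycles` (l multipliers), `go4_maxit`, `contact_scale`,
#'   `fit_cfg` (a [sim_config()] for the comparison range used by the
#'   search stages; the candidate's reference similarity always uses the
#'   full experimental range)
#' @return list with `disposition` (`"rejected_GO1"`, `"rejected_GO2"`,
#'   `"rejected_GO3"` or `"candidate"`), `candidate` (or `NULL`), `cost`
#'   (simulation cost units spent in the three stage groups), `score_sel`,
#'   `score_fit`
#' @export
go_step <- function(model, exp, thr, cfg, space,
                    control = list()) {
  ctl <- utils::modifyList(list(go3_maxit = 25, go3_algorithm = "hill_climb",
                                go4_cycles = c(0.72, 0.58, 0.43),
                                go4_maxit = 10, contact_scale = 0.7,
                                fit_cfg = NULL), control)
  # the search stages may compare on a restricted (low-angle) range where
  # the few dominant reflections make the similarity surface smooth
  fit_cfg <- ctl$fit_cfg %||% cfg
  out <- list(disposition = "rejected_GO1", candidate = NULL,
              cost = c(1, 0, 0), score_sel = NA_real_, score_fit = NA_real_)
  vz <- cell_volume(model$cell) / model$sg$Z
  if (vz < space$volume[1] || vz > space$volume[2]) return(out)
  placed <- try(place_in_cell(model), silent = TRUE)
  if (inherits(placed, "try-error")) return(out)
  ct <- try(check_contacts(model, scale = ctl$contact_scale, placed = placed,
                           early_exit = TRUE),
            silent = TRUE)
  if (inherits(ct, "try-error") || !ct$pass) return(out)
  # GO2: broad-window pre-selection
  ssel <- cost(model, exp, l = thr$l_broad, cfg = fit_cfg, placed = placed)
  out$score_sel <- ssel
  if (ssel < thr$S_sel) { out$disposition <- "rejected_GO2"; return(out) }
  # GO3: fast raw fit (coordinate search by default; it beats the
  # conjugate gradient on this rugged surface at equal evaluation budget)
  fit3 <- if (ctl$go3_algorithm == "conjugate_gradient")
    gradient_fit(model, exp, l = thr$l_broad, cfg = fit_cfg, space = space,
                 maxit = ctl$go3_maxit)
  else
    hill_climb(model, exp, l = thr$l_broad, cfg = fit_cfg, space = space,
               max_iterations = ctl$go3_maxit, min_improvement = 1e-4,
               max_halvings = 2)
  out$cost[2] <- fit3$n_evals
  out$score_fit <- fit3$value
  if (fit3$value < thr$S_opt) { out$disposition <- "rejected_GO3"; return(out) }
  # GO4: accurate hill-climb cycles with narrowing window
  cur <- fit3$model
  weight <- 3L
  evals4 <- 0L
  tol <- 1e-4
  for (mult in ctl$go4_cycles) {
    fit4 <- hill_climb(cur, exp, l = thr$l_broad * mult, cfg = fit_cfg,
                       space = space, max_iterations = ctl$go4_maxit,
                       min_improvement = tol, max_halvings = 3)
    evals4 <- evals4 + fit4$n_evals
    cur <- fit4$model %||% cur
    weight <- weight + 1L
    tol <- max(tol / 3, 1e-5)
  }
  out$cost[3] <- evals4
  sim <- simulate_pattern(cur, cfg)
  out$disposition <- "candidate"
  out$candidate <- list(model = cur, pattern = sim,
                        score_sel = ssel, score_fit = fit3$value,
                        ref_sim = reference_similarity(exp, sim)$value,
                        weight = weight,
                        vz = cell_volume(cur$cell) / cur$sg$Z)
  out
}

#' Auto-focus a search space on the qualified-candidate population
#'
#' For every free parameter with at least `min_population` qualified
#' candidates: if the candidate distribution is monomodal (interquartile
#' range small relative to the populated range), the range is narrowed to
#' median +/- `k` IQR, clipped to the physical limits; if at least 10% of
#' the population sits in the outer 5% at a range edge, that edge is pushed
#' out by 20% of the span. Flat or multimodal distributions leave the range
#' unchanged. The volume window is never adapted.
#'
#' @param space a `search_space`
#' @param candidates list of candidates (see [go_step()])
#' @param min_population minimum number of candidates before adapting
#' @param k IQR multiplier for the narrowed range
#' @return updated `search_space`
#' @export
adapt_search_space <- function(space, candidates, min_population = 25,
                               k = 2.5) {
  if (length(candidates) < min_population) return(space)
  vals <- lapply(candidates, function(cand) {
    info <- model_parameters(cand$model)
    stats::setNames(info$value, info$name)
  })
  p <- space$params
  for (i in seq_len(nrow(p))) {
    v <- vapply(vals, function(x) x[[p$name[i]]] %||% NA_real_, numeric(1))
    v <- v[!is.na(v)]
    if (length(v) < min_population) next
    span <- p$hi[i] - p$lo[i]
    # edge extension first: population piling up at a boundary
    if (mean(v > p$hi[i] - 0.05 * span) >= 0.10)
      p$hi[i] <- min(p$hi[i] + 0.2 * span, space$limits$hi[i])
    if (mean(v < p$lo[i] + 0.05 * span) >= 0.10)
      p$lo[i] <- max(p$lo[i] - 0.2 * span, space$limits$lo[i])
    iqr <- stats::IQR(v)
    vrange <- diff(range(v))
    if (vrange <= 0) next
    if (iqr / vrange < 0.5) {  # monomodal concentration signal
      med <- stats::median(v)
      eps <- max(k * iqr, 0.01 * span)
      lo_new <- max(med - eps, space$limits$lo[i])
      hi_new <- min(med + eps, space$limits$hi[i])
      if (hi_new - lo_new > 1e-9 &&
          hi_new - lo_new < p$hi[i] - p$lo[i]) {
        p$lo[i] <- lo_new; p$hi[i] <- hi_new
      }
    }
  }
  space$params <- p
  space
}

#' Configuration of a global-optimization run
#'
#' @param sg a `space_group_setting`
#' @param zm a `zmatrix`
#' @param space a `search_space` (default [make_search_space()])
#' @param cfg a [sim_config()]
#' @param thresholds a [go_thresholds()]
#' @param n_trials trial budget
#' @param it_every run the iteration step (filter + cluster + cell
#'   transformation, then search-space and window adaptation) every this many
#'   trials
#' @param adapt_every threshold-controller cadence in trials
#' @param ce_fraction fraction of the budget reserved for re-exploration of
#'   the neighbourhoods of top candidates (0 disables)
#' @param ce_top how many top candidates seed the re-exploration
#' @param control stage controls passed to [go_step()]
#' @param l_min floor for the narrowing broad window, degrees
#' @return a `go_config`
#' @export
go_config <- function(sg, zm, space = NULL, cfg = sim_config(),
                      thresholds = go_thresholds(), n_trials = 2000,
                      it_every = 5000, adapt_every = 100,
                      ce_fraction = 0.1, ce_top = 10,
                      control = list(), l_min = 0.5) {
  if (is.null(space)) space <- make_search_space(zm, sg)
  structure(list(sg = sg, zm = zm, space = space, cfg = cfg,
                 thresholds = thresholds, n_trials = n_trials,
                 it_every = it_every, adapt_every = adapt_every,
                 ce_fraction = ce_fraction, ce_top = ce_top,
                 control = control, l_min = l_min),
            class = "go_config")
}

#' Run a global optimization in one crystal symmetry
#'
#' The Monte-Carlo loop: random trial structures pass through the staged
#' filter hierarchy; gate thresholds are adapted to balance stage costs;
#' at the iteration points the candidate list is clustered and
#' cell-transformed (reduced) and the search space auto-focused while the
#' pre-selection window narrows; an optional final phase re-explores tight
#' neighbourhoods of the best candidates. Fully reproducible from the master
#' seed.
#'
#' @param config a [go_config()]
#' @param exp background-corrected experimental `powder_pattern`
#' @param seed master seed for the run
#' @param progress print stage counters every 1000 trials?
#' @return a `candidate_set`: candidates sorted by reference similarity,
#'   stage counters, final thresholds and search space
#' @export
run_go <- function(config, exp, seed = 1, progress = FALSE) {
  stopifnot(inherits(config, "go_config"), inherits(exp, "powder_pattern"))
  set.seed(seed)
  sim_cache_clear()
  thr <- config$thresholds
  space <- config$space
  counters <- c(trials = 0L, GO1 = 0L, GO2 = 0L, GO3 = 0L, GO4 = 0L)
  cands <- list()
  recent_sel <- numeric(0)
  recent_opt <- numeric(0)
  costs <- c(0, 0, 0)
  # windowed accounting between adaptation points: reacts faster than the
  # cumulative totals when a gate lets too much through early on
  win <- c(0, 0, 0)
  win_cnt <- c(go1 = 0L, go2 = 0L, go3 = 0L, go4 = 0L)
  n_main <- floor(config$n_trials * (1 - config$ce_fraction))
  cand_id <- 0L
  eval_trial <- function(model, thr_local = thr) {
    step <- go_step(model, exp, thr_local, config$cfg, space, config$control)
    counters["trials"] <<- counters["trials"] + 1L
    costs <<- costs + step$cost
    win <<- win + step$cost
    if (!is.na(step$score_sel)) {
      counters["GO1"] <<- counters["GO1"] + 1L
      win_cnt["go1"] <<- win_cnt["go1"] + 1L
      recent_sel <<- c(utils::tail(recent_sel, 1999), step$score_sel)
    }
    if (step$disposition %in% c("rejected_GO3", "candidate")) {
      counters["GO2"] <<- counters["GO2"] + 1L
      win_cnt["go2"] <<- win_cnt["go2"] + 1L
      recent_opt <<- c(utils::tail(recent_opt, 499), step$score_fit)
    }
    if (step$disposition == "candidate") {
      counters["GO3"] <<- counters["GO3"] + 1L
      counters["GO4"] <<- counters["GO4"] + 1L
      win_cnt["go4"] <<- win_cnt["go4"] + 1L
      cand_id <<- cand_id + 1L
      cand <- step$candidate
      cand$id <- cand_id
      cand$provenance <- "go"
      cands[[length(cands) + 1L]] <<- cand
    }
  }
  for (trial in seq_len(n_main)) {
    eval_trial(sample_trial(space, config$sg, config$zm,
                            fwhm = config$cfg$fwhm))
    if (trial >= thr$warmup && trial %% config$adapt_every == 0L) {
      # moving-average stage costs in simulation units; priors cover the
      # stretch before the first fit has been observed
      cost_per <- c(trial = costs[1] / counters[["trials"]],
                    go3 = if (counters[["GO2"]] > 0)
                      costs[2] / counters[["GO2"]] else 250,
                    go4 = if (counters[["GO4"]] > 0)
                      costs[3] / counters[["GO4"]] else 500)
      thr <- adapt_thresholds(thr, list(
        frac = costs / max(sum(costs), 1),
        cost_per = cost_per,
        recent_sel = recent_sel, recent_opt = recent_opt))
      win <- c(0, 0, 0)
      win_cnt[] <- 0L
    }
    if (trial %% config$it_every == 0L && length(cands) > 1L) {
      # IT1: cluster duplicates and reduce cells
      cands <- cluster_candidates(cands)
      cands <- lapply(cands, function(cand) {
        cand$model <- reduce_cell(cand$model)
        cand
      })
      # IT2: focus the search space, narrow the pre-selection window
      space <- adapt_search_space(space, cands)
      thr$l_broad <- max(config$l_min, thr$l_broad * 0.8)
    }
    if (progress && trial %% 1000L == 0L)
      message(sprintf("trial %d: GO1 %d GO2 %d GO4 %d (S_sel %.2f S_opt %.2f)",
                      trial, counters["GO1"], counters["GO2"],
                      counters["GO4"], thr$S_sel, thr$S_opt))
  }
  # CE: re-explore neighbourhoods of the best candidates found so far
  n_ce <- config$n_trials - n_main
  if (n_ce > 0L && length(cands) > 0L) {
    ord <- order(-vapply(cands, function(cand) cand$ref_sim, numeric(1)))
    tops <- cands[ord[seq_len(min(config$ce_top, length(cands)))]]
    per <- max(1L, floor(n_ce / length(tops)))
    for (top in tops) {
      local_space <- .neighbourhood_space(space, top$model, frac = 0.05)
      # re-exploration only invests in trials that beat the seed candidate's
      # own broad-window score; everything else is rejected cheaply
      thr_ce <- thr
      seed_cfg <- config$control$fit_cfg %||% config$cfg
      thr_ce$S_sel <- max(thr$S_sel,
                          cost(top$model, exp, l = thr$l_broad,
                               cfg = seed_cfg))
      for (i in seq_len(per)) {
        model <- try(sample_trial(local_space, config$sg, config$zm,
                                  fwhm = config$cfg$fwhm), silent = TRUE)
        if (!inherits(model, "try-error")) eval_trial(model, thr_ce)
      }
    }
  }
  ord <- order(-vapply(cands, function(cand) cand$ref_sim, numeric(1)))
  structure(list(candidates = cands[ord], sg = config$sg,
                 counters = counters, thresholds = thr, space = space,
                 seed = seed),
            class = "candidate_set")
}

# a search space of +/- frac * span around a model, volume window inherited
.neighbourhood_space <- function(space, model, frac = 0.05) {
  info <- model_parameters(model)
  p <- space$params
  for (i in seq_len(nrow(p))) {
    j <- match(p$name[i], info$name)
    if (is.na(j)) next
    half <- frac * (p$hi[i] - p$lo[i])
    p$lo[i] <- info$value[j] - half
    p$hi[i] <- info$value[j] + half
    if (p$class[i] == "length") p$lo[i] <- max(p$lo[i], 1)
  }
  sp <- space
  sp$params <- p
  # the window must cover the seed model's own molar volume, or the
  # rejection sampler would spin on an empty acceptance region
  vz <- cell_volume(model$cell) / model$sg$Z
  sp$volume <- range(space$volume[1] * 0.95, space$volume[2] * 1.05,
                     vz * 0.93, vz * 1.07)
  sp
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set (%s): %d candidates from %d trials [GO1 %d, GO2 %d, GO4 %d]\n",
              x$sg$symbol, length(x$candidates), x$counters["trials"],
              x$counters["GO1"], x$counters["GO2"], x$counters["GO4"]))
  if (length(x$candidates)) {
    top <- x$candidates[[1]]
    cat(sprintf("  best: ref similarity %.4f, V/Z %.1f A^3, weight %d\n",
                top$ref_sim, top$vz, top$weight))
  }
  invisible(x)
}

#' Re-evaluate and rank candidates across symmetry runs
#'
#' Stage RE1 merges the candidate sets, filters by a reference-similarity
#' floor, the molar-volume window and a top-N cap. Stage RE2 then re-fits
#' the survivors with a fine schedule (narrow window, optional wider
#' comparison range, optional FWHM refinement), keeping the better of the
#' original and the re-fitted model, and clusters the results. Candidates
#' are ranked by reference similarity with the cluster weight as tie-breaker.
#'
#' @param sets list of `candidate_set` objects (or a single one)
#' @param exp experimental pattern
#' @param cfg a [sim_config()]
#' @param ref_floor RE1 reference-similarity floor
#' @param volume RE1 molar-volume window `c(lo, hi)` or `NULL` to skip
#' @param top_n RE1 cap on the number of candidates (default 400)
#' @param re2_n how many top candidates receive the fine fit
#' @param fine_l fine-fit neighbouring ranges, degrees
#' @param fine_range optional wider 2-theta window for the fine fit
#' @param fit_fwhm refine the FWHM during the fine fit?
#' @param cluster_l,cluster_threshold final clustering settings
#' @return a `candidate_set` with merged, re-fitted, clustered candidates
#' @export
reevaluate <- function(sets, exp, cfg = sim_config(), ref_floor = 0.8,
                       volume = NULL, top_n = 400, re2_n = 20,
                       fine_l = c(0.2, 0.1), fine_range = NULL,
                       fit_fwhm = FALSE, cluster_l = 0.3,
                       cluster_threshold = 0.995) {
  if (inherits(sets, "candidate_set")) sets <- list(sets)
  cands <- do.call(c, lapply(sets, function(s) s$candidates))
  if (length(cands) == 0L)
    return(structure(list(candidates = list(), sg = sets[[1]]$sg,
                          counters = c(), thresholds = NULL, space = NULL),
                     class = "candidate_set"))
  # RE1: filter and cap
  keep <- vapply(cands, function(cand) {
    cand$ref_sim >= ref_floor &&
      (is.null(volume) || (cand$vz >= volume[1] && cand$vz <= volume[2]))
  }, logical(1))
  cands <- cands[keep]
  ord <- order(-vapply(cands, function(cand) cand$ref_sim, numeric(1)))
  cands <- cands[ord][seq_len(min(top_n, length(cands)))]
  # RE2: fine fit of the top candidates; keep the better model
  sched <- fit_schedule(fine_l, algorithm = "hill_climb",
                        max_iterations = 60, min_improvement = 1e-5,
                        range = list(fine_range), fit_fwhm = fit_fwhm)
  n_fine <- min(re2_n, length(cands))
  for (i in seq_len(n_fine)) {
    fit <- staged_fit(cands[[i]]$model, exp, sched, cfg = cfg)
    if (fit$ref_sim > cands[[i]]$ref_sim) {
      cands[[i]]$model <- fit$model
      cands[[i]]$ref_sim <- fit$ref_sim
      cands[[i]]$pattern <- simulate_pattern(fit$model, cfg)
      cands[[i]]$vz <- cell_volume(fit$model$cell) / fit$model$sg$Z
    }
    cands[[i]]$provenance <- paste0(cands[[i]]$provenance %||% "go", "+re2")
  }
  cands <- cluster_candidates(cands, l_narrow = cluster_l,
                              threshold = cluster_threshold)
  ref <- vapply(cands, function(cand) cand$ref_sim, numeric(1))
  wc <- vapply(cands, function(cand) cand$weight, numeric(1))
  cands <- cands[order(-ref, -wc)]
  structure(list(candidates = cands, sg = sets[[1]]$sg,
                 counters = Reduce(`+`, lapply(sets, `[[`, "counters")),
                 thresholds = NULL, space = NULL),
            class = "candidate_set")
}

#' Screen a list of structure models against an experimental pattern
#'
#' Replaces the random trial generation by user-supplied models (e.g. from a
#' crystal structure prediction or a set of possibly isotypical structures):
#' each model is scored with the broad window and then locally fitted; the
#' result is a ranked table.
#'
#' @param models list of `structure_model` objects
#' @param exp experimental pattern
#' @param cfg a [sim_config()]
#' @param l_broad broad pre-selection window, degrees
#' @param schedule fit schedule applied to each model (default a raw +
#'   fine combination)
#' @return data.frame ranked by reference similarity with columns `rank`,
#'   `space_group`, `Z`, `ref_sim`, `score_broad`, `vz`, `a, b, c, alpha,
#'   beta, gamma`, plus the fitted models as attribute `"models"`
#' @export
screen_models <- function(models, exp, cfg = sim_config(), l_broad = 1.0,
                          schedule = NULL) {
  if (is.null(schedule))
    schedule <- fit_schedule(c(l_broad, 0.43 * l_broad, 0.15),
                             algorithm = c("conjugate_gradient", "hill_climb",
                                           "hill_climb"),
                             max_iterations = c(40, 40, 40))
  rows <- list()
  fitted <- list()
  for (i in seq_along(models)) {
    model <- models[[i]]
    res <- try({
      broad <- cost(model, exp, l = l_broad, cfg = cfg)
      fit <- staged_fit(model, exp, schedule, cfg = cfg)
      list(broad = broad, fit = fit)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      message("screen_models: model ", i, " skipped: ",
              attr(res, "condition")$message)
      next
    }
    mdl <- res$fit$model
    rows[[length(rows) + 1L]] <- data.frame(
      space_group = mdl$sg$symbol, Z = mdl$sg$Z,
      ref_sim = res$fit$ref_sim, score_broad = res$broad,
      vz = cell_volume(mdl$cell) / mdl$sg$Z,
      a = mdl$cell$a, b = mdl$cell$b, c = mdl$cell$c,
      alpha = mdl$cell$alpha, beta = mdl$cell$beta, gamma = mdl$cell$gamma)
    fitted[[length(fitted) + 1L]] <- mdl
  }
  if (length(rows) == 0L) {
    out <- data.frame(rank = integer(0), space_group = character(0),
                      Z = numeric(0), ref_sim = numeric(0),
                      score_broad = numeric(0), vz = numeric(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      alpha = numeric(0), beta = numeric(0),
                      gamma = numeric(0))
    attr(out, "models") <- list()
    return(out)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$ref_sim)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "models") <- fitted[ord]
  tab
}

#' Downscaled application-mode presets for the search space
#'
#' The "less global" application modes are pure configuration presets over
#' the same machinery: `solution_fit` shrinks the cell ranges to a narrow
#' band around known cell parameters; `regional` centres every parameter
#' range around a start model; `reduced` overrides selected cell-parameter
#' ranges and keeps the rest global.
#'
#' @param space base `search_space`
#' @param mode `"solution_fit"`, `"regional"` or `"reduced"`
#' @param cell known `unit_cell` (solution_fit)
#' @param model start `structure_model` (regional)
#' @param overrides named list `name -> c(lo, hi)` (reduced)
#' @param frac half-width fraction for the narrowed ranges
#' @return modified `search_space`
#' @export
preset_space <- function(space, mode = c("solution_fit", "regional", "reduced"),
                         cell = NULL, model = NULL, overrides = NULL,
                         frac = 0.02) {
  mode <- match.arg(mode)
  p <- space$params
  if (mode == "solution_fit") {
    stopifnot(inherits(cell, "unit_cell"))
    for (i in seq_len(nrow(p))) {
      nm <- p$name[i]
      if (nm %in% c("a", "b", "c", "alpha", "beta", "gamma")) {
        v <- cell[[nm]]
        half <- max(frac * abs(v), 1e-3)
        p$lo[i] <- v - half; p$hi[i] <- v + half
      }
    }
  } else if (mode == "regional") {
    stopifnot(inherits(model, "structure_model"))
    return(.neighbourhood_space(space, model, frac = frac))
  } else {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      i <- match(nm, p$name)
      if (is.na(i)) stop("unknown parameter in overrides: ", nm)
      p$lo[i] <- overrides[[nm]][1]; p$hi[i] <- overrides[[nm]][2]
    }
  }
  space$params <- p
  space
}
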