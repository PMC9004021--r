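#' Validate and normalize a run configuration
#'
#' A single configuration (YAML file or list) drives the whole workbench.
#' Unknown keys are rejected so typos fail loudly before any computation.
#'
#' @param config list or path to a YAML file
#' @return validated config list (class `run_config`)
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("mode", "pattern", "molecule", "space_group", "Zprime",
             "site_symmetry", "wavelength", "two_theta_range", "step",
             "fwhm", "shape", "eta", "two_theta_m", "B",
             "background_window", "min_prominence",
             "volume_tolerance", "packing_factor",
             "n_trials", "seed", "l_broad", "S_sel", "S_opt",
             "it_every", "adapt_every", "ce_fraction", "ce_top",
             "ref_floor", "top_n", "re2_n", "candidates", "out_dir",
             "snr_levels", "exclude_h")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  modes <- c("go", "screen", "fit", "simulate", "compare", "fixtures")
  if (is.null(config$mode) || !config$mode %in% modes)
    stop("config$mode must be one of: ", paste(modes, collapse = ", "))
  defaults <- list(wavelength = 1.5406, two_theta_range = c(5, 40),
                   step = 0.02, fwhm = 0.3, shape = "pseudo_voigt",
                   eta = 0.5, two_theta_m = 27.26, B = 3,
                   background_window = 2, min_prominence = 0.02,
                   volume_tolerance = 0.1, packing_factor = 1,
                   n_trials = 2000, seed = 1, l_broad = 1.5,
                   S_sel = 0.55, S_opt = 0.80, it_every = 5000,
                   adapt_every = 250, ce_fraction = 0.1, ce_top = 10,
                   ref_floor = 0.8, top_n = 400, re2_n = 20,
                   Zprime = 1, site_symmetry = "1", out_dir = "powsolve_run",
                   exclude_h = FALSE)
  config <- utils::modifyList(defaults, config)
  structure(config, class = "run_config")
}

.config_sim <- function(config) {
  sim_config(two_theta_range = as.numeric(config$two_theta_range),
             step = config$step, wavelength = config$wavelength,
             fwhm = config$fwhm, shape = config$shape, eta = config$eta,
             two_theta_m = config$two_theta_m, B = config$B,
             exclude_h = isTRUE(config$exclude_h))
}

#' Run the workbench
#'
#' Executes the configured mode and writes its artifacts (results JSON, CSV
#' summary, CIFs, log) into the run directory. Modes: `go` (global
#' optimization + re-evaluation), `screen` (rank supplied CIF candidates),
#' `fit` (local fit of one CIF model), `simulate` (pattern of one CIF
#' model), `compare` (similarity of two xy patterns), `fixtures` (write the
#' toy suite).
#'
#' @param config list or YAML path accepted by [run_config()]
#' @return invisible list with `status` (0 = candidates found, 2 = empty
#'   result) and `out_dir`
#' @export
run_workbench <- function(config) {
  config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run.log")
  cat(sprintf("mode: %s\nseed: %d\n", config$mode, config$seed), file = log)
  status <- 0L
  if (config$mode == "fixtures") {
    write_toy_suite(out_dir)
    return(invisible(list(status = 0L, out_dir = out_dir)))
  }
  cfg <- .config_sim(config)
  if (config$mode == "compare") {
    p1 <- read_pattern(config$pattern[[1]])
    p2 <- read_pattern(config$pattern[[2]])
    res <- list(s12 = s12(p1, p2, l = config$l_broad)$value,
                s12_pointwise = s12(p1, p2, zero_limit = TRUE)$value)
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(status = 0L, out_dir = out_dir)))
  }
  exp <- read_pattern(config$pattern, wavelength = config$wavelength)
  if (!exp$background_corrected)
    exp <- subtract_background(exp, window_deg = config$background_window)$pattern
  zm <- read_zmatrix(config$molecule)
  sg <- space_group(config$space_group, Zprime = config$Zprime,
                    site_symmetry = config$site_symmetry)
  if (config$mode == "simulate") {
    model <- cif_to_model(read_cif(config$candidates[[1]]), zm, sg)
    write_pattern(simulate_pattern(model, cfg),
                  file.path(out_dir, "simulated.xy"))
    return(invisible(list(status = 0L, out_dir = out_dir)))
  }
  if (config$mode == "fit") {
    model <- cif_to_model(read_cif(config$candidates[[1]]), zm, sg)
    sched <- fit_schedule(c(config$l_broad, 0.43 * config$l_broad, 0.15),
                          algorithm = c("conjugate_gradient", "hill_climb",
                                        "hill_climb"))
    fit <- staged_fit(model, exp, sched, cfg = cfg)
    write_cif(fit$model, file.path(out_dir, "fitted.cif"))
    utils::write.csv(fit$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(ref_sim = fit$ref_sim,
                              stage_values = fit$stage_values),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(status = 0L, out_dir = out_dir)))
  }
  if (config$mode == "screen") {
    models <- lapply(config$candidates,
                     function(p) cif_to_model(read_cif(p), zm, sg))
    tab <- screen_models(models, exp, cfg = cfg, l_broad = config$l_broad)
    utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    status <- if (nrow(tab)) 0L else 2L
    return(invisible(list(status = status, out_dir = out_dir)))
  }
  # mode "go"
  space <- make_search_space(zm, sg,
                             volume_tolerance = config$volume_tolerance,
                             packing_factor = config$packing_factor)
  gc <- go_config(sg, zm, space = space, cfg = cfg,
                  thresholds = go_thresholds(S_sel = config$S_sel,
                                             S_opt = config$S_opt,
                                             l_broad = config$l_broad),
                  n_trials = config$n_trials, it_every = config$it_every,
                  adapt_every = config$adapt_every,
                  ce_fraction = config$ce_fraction, ce_top = config$ce_top)
  set_result <- run_go(gc, exp, seed = config$seed)
  final <- reevaluate(set_result, exp, cfg = cfg,
                      ref_floor = config$ref_floor,
                      top_n = config$top_n, re2_n = config$re2_n)
  tab <- report_candidates(final)
  utils::write.csv(tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(counters = as.list(set_result$counters),
         n_final = length(final$candidates),
         candidates = lapply(final$candidates, function(cand) list(
           ref_sim = cand$ref_sim, weight = cand$weight, vz = cand$vz,
           cell = unclass(cand$model$cell)[c("a", "b", "c", "alpha",
                                             "beta", "gamma")]))),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(final$candidates))
    write_cif(final$candidates[[i]]$model,
              file.path(out_dir, sprintf("candidate_%02d.cif", i)))
  cat(sprintf("trials: %d\ncandidates: %d\n",
              set_result$counters["trials"], length(final$candidates)),
      file = log, append = TRUE)
  status <- if (length(final$candidates)) 0L else 2L
  invisible(list(status = status, out_dir = out_dir))
}

#' Summary table of a candidate set
#'
#' The standard report layout: rank, space group, Z, candidate weight,
#' reference similarity, molar volume and cell parameters.
#'
#' @param set a `candidate_set`
#' @return data.frame (zero rows for an empty set)
#' @export
report_candidates <- function(set) {
  cands <- set$candidates
  if (length(cands) == 0L)
    return(data.frame(rank = integer(0), space_group = character(0),
                      Z = numeric(0), W_C = integer(0), ref_sim = numeric(0),
                      vz = numeric(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), alpha = numeric(0), beta = numeric(0),
                      gamma = numeric(0)))
  do.call(rbind, lapply(seq_along(cands), function(i) {
    cand <- cands[[i]]
    cell <- cand$model$cell
    data.frame(rank = i, space_group = cand$model$sg$symbol,
               Z = cand$model$sg$Z, W_C = cand$weight,
               ref_sim = cand$ref_sim, vz = cand$vz,
               a = cell$a, b = cell$b, c = cell$c,
               alpha = cell$alpha, beta = cell$beta, gamma = cell$gamma)
  }))
}
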