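small_problem <- function(snr = Inf, seed = 202) {
  zm <- make_toy_molecule("planar_rigid")
  sg <- space_group("P-1", Zprime = 0.5, site_symmetry = "-1")
  cfg <- toy_cfg()
  truth <- make_toy_structure(zm, sg, seed = seed)
  truth$fwhm <- cfg$fwhm
  exp <- if (is.finite(snr)) {
    raw <- make_noisy_pattern(truth, cfg, snr = snr, seed = seed)
    subtract_background(raw)$pattern
  } else simulate_pattern(truth, cfg)
  list(zm = zm, sg = sg, cfg = cfg, truth = truth, exp = exp,
       space = make_search_space(zm, sg))
}

test_that("trial sampling respects ranges, volume window and the seed", {
  prob <- small_problem()
  set.seed(123)
  vals <- replicate(300, {
    m <- sample_trial(prob$space, prob$sg, prob$zm)
    info <- model_parameters(m)
    vz <- cell_volume(m$cell) / prob$sg$Z
    c(info$value, vz)
  })
  p <- prob$space$params
  for (i in seq_len(nrow(p))) {
    if (startsWith(p$name[i], "phi_")) next  # rotations drawn uniformly on SO(3)
    expect_true(all(vals[i, ] >= p$lo[i] - 1e-9 & vals[i, ] <= p$hi[i] + 1e-9),
                label = p$name[i])
  }
  vz <- vals[nrow(vals), ]
  expect_true(all(vz >= prob$space$volume[1] & vz <= prob$space$volume[2]))

  # seed determinism
  set.seed(77); m1 <- sample_trial(prob$space, prob$sg, prob$zm)
  set.seed(77); m2 <- sample_trial(prob$space, prob$sg, prob$zm)
  expect_equal(model_parameters(m1)$value, model_parameters(m2)$value)

  # impossible volume window errors out with a diagnosis
  bad <- prob$space
  bad$volume <- c(1e6, 2e6)
  expect_error(suppressWarnings(sample_trial(bad, prob$sg, prob$zm)),
               "inconsistent")
})

test_that("orientation sampling is uniform over rotations", {
  prob <- small_problem()
  set.seed(42)
  n <- 2000
  acc <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    m <- sample_trial(prob$space, prob$sg, prob$zm)
    acc <- acc + powsolve:::.rotation_matrix(m$phi)
  }
  # mean of uniformly random rotation matrices tends to 0; each entry has
  # sd ~ sqrt(1/3) / sqrt(n); allow 4 sigma
  expect_true(all(abs(acc / n) < 4 * sqrt(1 / 3) / sqrt(n)))
})

test_that("the staged filter hierarchy rejects cheaply and promotes the truth", {
  prob <- small_problem()
  thr <- go_thresholds()
  # volume failure: no simulation performed (cost stays at the GO1 unit)
  shrunk <- structure_model(unit_cell(3, 3, 3, 80, 85, 95), prob$sg, prob$zm)
  sp <- prob$space
  st <- go_step(shrunk, prob$exp, thr, prob$cfg, sp)
  expect_equal(st$disposition, "rejected_GO1")
  expect_true(is.na(st$score_sel))
  expect_equal(st$cost, c(1, 0, 0))

  # the true structure injected as a trial ends as a top candidate
  st2 <- go_step(prob$truth, prob$exp, thr, prob$cfg, sp,
                 control = list(go3_maxit = 5, go4_maxit = 5))
  expect_equal(st2$disposition, "candidate")
  expect_gt(st2$candidate$ref_sim, 0.99)
  expect_gte(st2$candidate$weight, 3)

  # an exact-match gate at the boundary rejects everything imperfect
  thr_hard <- go_thresholds(S_sel = 0.999999, S_opt = 0.9999995)
  st3 <- go_step(perturbed <- structure_model(
    unit_cell(prob$truth$cell$a * 1.2, prob$truth$cell$b,
              prob$truth$cell$c, prob$truth$cell$alpha,
              prob$truth$cell$beta, prob$truth$cell$gamma),
    prob$sg, prob$zm, phi = prob$truth$phi), prob$exp, thr_hard,
    prob$cfg, sp)
  expect_true(st3$disposition %in% c("rejected_GO1", "rejected_GO2"))
})

test_that("threshold adaptation targets cost-balancing pass rates", {
  t0 <- go_thresholds(S_sel = 0.55, S_opt = 0.8)
  set.seed(8)
  recent <- runif(2000)
  base <- list(frac = c(0.4, 0.3, 0.3),
               cost_per = c(trial = 1, go3 = 250, go4 = 500),
               recent_sel = recent,
               recent_opt = runif(200, 0.6, 0.95))
  # cost split already on target: both gates unchanged (deadband)
  expect_equal(adapt_thresholds(t0, base)$S_sel, t0$S_sel)
  expect_equal(adapt_thresholds(t0, base)$S_opt, t0$S_opt)

  # raw fits eating 90% of the cost: the pre-selection gate rises to the
  # quantile that implies the cost-balancing pass rate (0.75 x 1/250 here)
  heavy <- base; heavy$frac <- c(0.05, 0.9, 0.05)
  t1 <- adapt_thresholds(t0, heavy)
  expect_gt(t1$S_sel, t0$S_sel)
  expected <- min(stats::quantile(recent, 1 - 0.75 / 250, names = FALSE),
                  0.995)
  expect_equal(t1$S_sel, expected, tolerance = 1e-9)

  # a starved accurate stage opens its gate (cheap accurate fits -> high
  # admission), never below the pre-selection gate
  starved <- base
  starved$frac <- c(0.65, 0.3, 0.05)
  starved$cost_per <- c(trial = 1, go3 = 250, go4 = 260)
  t2 <- adapt_thresholds(t0, starved)
  expect_lt(t2$S_opt, t0$S_opt)
  expect_gte(t2$S_opt, t2$S_sel)

  # short score streams leave the thresholds alone
  thin <- heavy; thin$recent_sel <- runif(5)
  expect_equal(adapt_thresholds(t0, thin)$S_sel, t0$S_sel)
})

test_that("auto-focusing narrows monomodal, spares flat and bimodal spreads", {
  prob <- small_problem()
  sp <- prob$space
  mk_cand <- function(a_val) {
    cell <- prob$truth$cell
    m <- structure_model(unit_cell(a_val, cell$b, cell$c, cell$alpha,
                                   cell$beta, cell$gamma),
                         prob$sg, prob$zm, phi = prob$truth$phi)
    list(model = m, ref_sim = 0.9, weight = 1L, id = a_val)
  }
  ia <- which(sp$params$name == "a")
  # degenerate population at one value: range collapses around it
  set.seed(2)
  cands <- lapply(rep(4.2, 30) + rnorm(30, 0, 0.01), mk_cand)
  sp1 <- adapt_search_space(sp, cands)
  expect_lt(sp1$params$hi[ia] - sp1$params$lo[ia],
            sp$params$hi[ia] - sp$params$lo[ia])
  expect_true(sp1$params$lo[ia] < 4.2 && sp1$params$hi[ia] > 4.2)

  # uniform population: no focus signal, range unchanged
  lo <- sp$params$lo[ia]; hi <- sp$params$hi[ia]
  inner <- lo + 0.06 * (hi - lo) + (0.88 * (hi - lo)) * (0:29) / 29
  sp2 <- adapt_search_space(sp, lapply(inner, mk_cand))
  expect_equal(sp2$params$lo[ia], lo, tolerance = 1e-9)
  expect_equal(sp2$params$hi[ia], hi, tolerance = 1e-9)

  # bimodal population: the multimodality guard leaves the range alone
  bim <- c(lo + 0.1 * (hi - lo) + rnorm(15, 0, 0.01 * (hi - lo)),
           lo + 0.9 * (hi - lo) + rnorm(15, 0, 0.01 * (hi - lo)))
  sp3 <- adapt_search_space(sp, lapply(bim, mk_cand))
  expect_equal(sp3$params$lo[ia], lo, tolerance = 1e-6)
  expect_equal(sp3$params$hi[ia], hi, tolerance = 1e-6)

  # below the minimum population nothing happens
  sp4 <- adapt_search_space(sp, lapply(rep(4.2, 5), mk_cand))
  expect_equal(sp4$params$hi[ia], sp$params$hi[ia])
})

test_that("short global runs keep their counters nested and are reproducible", {
  prob <- small_problem()
  gc <- go_config(prob$sg, prob$zm, space = prob$space, cfg = prob$cfg,
                  n_trials = 300, it_every = 150, adapt_every = 100,
                  ce_fraction = 0.1,
                  thresholds = go_thresholds(warmup = 100),
                  control = list(go3_maxit = 5, go4_maxit = 5))
  res <- run_go(gc, prob$exp, seed = 4)
  cnt <- res$counters
  expect_lte(cnt["GO4"], cnt["GO3"])
  expect_lte(cnt["GO3"], cnt["GO2"])
  expect_lte(cnt["GO2"], cnt["GO1"])
  expect_lte(cnt["GO1"], cnt["trials"])

  res2 <- run_go(gc, prob$exp, seed = 4)
  expect_equal(res2$counters, res$counters)
  expect_equal(length(res2$candidates), length(res$candidates))
  if (length(res$candidates)) {
    expect_equal(model_parameters(res2$candidates[[1]]$model)$value,
                 model_parameters(res$candidates[[1]]$model)$value)
  }

  empty <- run_go(go_config(prob$sg, prob$zm, space = prob$space,
                            cfg = prob$cfg, n_trials = 0), prob$exp, seed = 1)
  expect_length(empty$candidates, 0L)
})

test_that("re-evaluation filters, refines and keeps the best-so-far model", {
  prob <- small_problem()
  mk <- function(model, ref, w, id) {
    list(model = model, pattern = simulate_pattern(model, prob$cfg),
         ref_sim = ref, weight = w, id = id,
         vz = cell_volume(model$cell) / model$sg$Z)
  }
  perfect <- mk(prob$truth, 1.0, 5L, 1)
  worse <- mk(structure_model(unit_cell(prob$truth$cell$a * 1.15,
                                        prob$truth$cell$b * 1.1,
                                        prob$truth$cell$c,
                                        prob$truth$cell$alpha,
                                        prob$truth$cell$beta,
                                        prob$truth$cell$gamma),
                              prob$sg, prob$zm, phi = prob$truth$phi),
              0.6, 1L, 2)
  set0 <- structure(list(candidates = list(perfect, worse), sg = prob$sg,
                         counters = c(trials = 2L, GO1 = 2L, GO2 = 2L,
                                      GO3 = 2L, GO4 = 2L)),
                    class = "candidate_set")
  out <- reevaluate(set0, prob$exp, cfg = prob$cfg, ref_floor = 0.5,
                    re2_n = 2)
  expect_equal(out$candidates[[1]]$ref_sim, 1.0, tolerance = 1e-9)

  # duplicates entering the final clustering merge with summed weights
  dup_set <- structure(list(candidates = list(mk(prob$truth, 0.999, 2L, 1),
                                              mk(prob$truth, 0.998, 3L, 2)),
                            sg = prob$sg, counters = set0$counters),
                       class = "candidate_set")
  out2 <- reevaluate(dup_set, prob$exp, cfg = prob$cfg, ref_floor = 0.5,
                     re2_n = 0)
  expect_length(out2$candidates, 1L)
  expect_equal(out2$candidates[[1]]$weight, 5)

  # the fine fit never worsens a kept candidate
  for (cand in out$candidates)
    expect_gte(cand$ref_sim + 1e-9,
               if (cand$id == 1) 1.0 else 0.6)
})

test_that("screening ranks a supplied structure list against the pattern", {
  prob <- small_problem()
  set.seed(55)
  decoys <- replicate(4, sample_trial(prob$space, prob$sg, prob$zm),
                      simplify = FALSE)
  tab <- screen_models(c(list(prob$truth), decoys), prob$exp,
                       cfg = prob$cfg, l_broad = 1.0,
                       schedule = fit_schedule(c(1, 0.3),
                                               algorithm = "hill_climb",
                                               max_iterations = 10))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$rank, 1:5)
  expect_gt(tab$ref_sim[1], 0.99)
  # the true structure wins
  expect_equal(tab$a[1], prob$truth$cell$a, tolerance = 1e-6)

  empty <- screen_models(list(), prob$exp, cfg = prob$cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("application modes are pure search-space presets", {
  prob <- small_problem()
  sp <- prob$space
  # solution fit: narrow bands around known cell parameters
  sf <- preset_space(sp, "solution_fit", cell = prob$truth$cell)
  ia <- which(sf$params$name == "a")
  expect_lte(sf$params$hi[ia] - sf$params$lo[ia],
             2 * 0.02 * prob$truth$cell$a + 1e-9)
  expect_true(sf$params$lo[ia] < prob$truth$cell$a &&
                sf$params$hi[ia] > prob$truth$cell$a)
  # regional: every range centred on the start model
  rf <- preset_space(sp, "regional", model = prob$truth)
  info <- model_parameters(prob$truth)
  for (i in seq_len(nrow(rf$params))) {
    j <- match(rf$params$name[i], info$name)
    expect_true(rf$params$lo[i] <= info$value[j] &&
                  rf$params$hi[i] >= info$value[j])
  }
  # reduced: explicit overrides for selected parameters only
  rg <- preset_space(sp, "reduced", overrides = list(a = c(4, 5)))
  expect_equal(rg$params$lo[ia], 4)
  expect_equal(rg$params$hi[ia], 5)
  ib <- which(rg$params$name == "b")
  expect_equal(rg$params$lo[ib], sp$params$lo[ib])
  expect_error(preset_space(sp, "reduced", overrides = list(zz = c(0, 1))),
               "unknown parameter")
})
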