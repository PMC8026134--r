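# Synthetic-data generator: determinism, planted statistical structure,
# layout bookkeeping, validation errors.

test_that("fixed seed gives bit-identical ratings, choices and patterns", {
  cfg <- tiny_cfg()
  r1 <- generate_ratings(cfg); r2 <- generate_ratings(cfg)
  expect_identical(r1, r2)
  c1 <- generate_choices(r1, cfg); c2 <- generate_choices(r2, cfg)
  expect_identical(c1, c2)
  p1 <- generate_beta_patterns(r1, cfg); p2 <- generate_beta_patterns(r1, cfg)
  expect_identical(p1[[1]]$patterns, p2[[1]]$patterns)
  expect_identical(p1[[2]]$residuals, p2[[2]]$residuals)
})

test_that("material compositions lie exactly on the 4-simplex", {
  r <- generate_ratings(tiny_cfg(n_subjects = 1))
  comp <- unique(r[, c("item", "wood", "metal", "plastic", "fabric")])
  expect_equal(nrow(comp), 24)
  expect_true(all(comp[, -1] >= 0))
  expect_equal(unname(rowSums(comp[, -1])), rep(1, nrow(comp)),
               tolerance = 1e-12)
})

test_that("planted cross-goal correlation is hit (r = 0 and r = 0.12)", {
  for (target in c(0, 0.12)) {
    cfg <- sim_config(n_subjects = 200, cross_goal_r = target, seed = 7)
    r <- generate_ratings(cfg)
    rs <- vapply(seq_len(200), function(s) {
      lk <- goalrsa:::ratings_lookup(r, s, cfg$goals)
      stats::cor(lk$U[, 1], lk$U[, 2])
    }, 0)
    expect_lt(abs(mean(rs) - target), 0.03)
  }
})

test_that("confidence follows the planted quadratic law", {
  cfg <- sim_config(n_subjects = 30, seed = 13)
  q <- fit_confidence_quadratic(generate_ratings(cfg))
  expect_lt(abs(q$beta - cfg$conf_quadratic_beta), 0.001)
  expect_lt(q$p, 0.001)
})

test_that("invalid correlation targets and zero-voxel regions are rejected", {
  expect_error(sim_config(cross_goal_r = 1), "inside")
  expect_error(sim_config(cross_goal_r = -1.2), "inside")
  expect_error(region_spec("r", n_voxels = 0), "zero voxels")
  expect_error(region_spec("r", codes = "nonsense"), "unknown codes")
})

test_that("an overwhelming congruent-usefulness weight forces the choice", {
  cfg <- tiny_cfg(choice_betas = c(cong_dU = 1e6), choice_ranef_sd = 0)
  r <- generate_ratings(cfg)
  ch <- generate_choices(r, cfg)
  d <- build_choice_design(ch, r, goals = cfg$goals)
  expect_true(all(d$chose_right == (d$cong_dU > 0)))
})

test_that("all-zero planted coefficients give symmetric choices", {
  cfg <- sim_config(n_subjects = 12, seed = 23,
                    choice_betas = c(cong_dU = 0), choice_ranef_sd = 0)
  ch <- generate_choices(generate_ratings(cfg), cfg)
  expect_gt(nrow(ch), 1000)
  expect_lt(abs(mean(ch$chosen_side == "right") - 0.5), 0.05)
})

test_that("choice pairs come from the recent imagination window", {
  cfg <- tiny_cfg()
  ch <- generate_choices(generate_ratings(cfg), cfg)
  expect_true(all(ch$left_item != ch$right_item))
  expect_true(all(ch$chosen_side %in% c("left", "right")))
  # every goal's items are all shown: each (item, goal) exactly once overall
  expect_equal(sort(unique(ch$session)), 1:2)
})

test_that("noiseless identity-only patterns give the Kronecker-delta RDM", {
  cfg <- tiny_cfg(noise_sd_pattern = 0)
  cfg$region_specs <- list(region_spec("roi", n_voxels = 30,
                                       codes = "identity"))
  ps <- generate_beta_patterns(generate_ratings(cfg), cfg)[[1]]
  b <- brain_rdm(ps, voxels = ps$regions$roi)
  same <- outer(ps$conditions$item, ps$conditions$item, "==")
  expect_equal(max(abs(b$d[same])), 0, tolerance = 1e-10)
  off <- !same
  expect_gt(min(b$d[off]), 0.3)   # random item patterns are dissimilar
  expect_equal(diag(b$d), rep(0, nrow(b$d)))
})

test_that("shared_population_fraction = 1 reuses usefulness weights for confidence", {
  cfg <- tiny_cfg(noise_sd_pattern = 0)
  cfg$region_specs <- list(region_spec(
    "roi", n_voxels = 30,
    codes = c("usefulness_goal_general", "confidence"),
    shared_population_fraction = 1))
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg)[[1]]
  lk <- goalrsa:::ratings_lookup(r, 1, cfg$goals)
  gi <- match(ps$conditions$goal, cfg$goals)
  pv <- participation_vectors(ps$patterns[, ps$regions$roi],
                              lk$U[cbind(ps$conditions$item, gi)],
                              lk$C[cbind(ps$conditions$item, gi)])
  expect_gt(stats::cor(pv$B_U, pv$B_C, method = "spearman"), 0.95)
})

test_that("design summary reproduces the session layout arithmetic", {
  ds <- design_summary(sim_config())
  expect_equal(ds$trials_per_session, 84)
  expect_equal(ds$imagination_pct, 71.4)
  expect_equal(ds$choice_pct, 28.6)
  expect_equal(ds$session_duration_min, 12.6)
  expect_equal(ds$n_conditions, 240)
  expect_equal(ds$total_trials, 336)
})

test_that("BOLD generation lays out sessions and recovers amplitudes", {
  cfg <- tiny_cfg(n_subjects = 1, bold_noise_sd = 0, bold_drift_sd = 0)
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg)[[1]]
  run <- generate_bold(ps, cfg)
  expect_length(run$sessions, 2)
  expect_equal(nrow(run$sessions[[1]]$events),
               cfg$imagination_per_session + cfg$choice_per_session)
  est <- fit_condition_betas(run)
  m <- match(paste(ps$conditions$item, ps$conditions$goal),
             paste(est$conditions$item, est$conditions$goal))
  expect_lt(max(abs(ps$patterns - est$patterns[m, ])), 1e-6)
  # too few volumes for the layout
  bad <- tiny_cfg(n_subjects = 1, n_volumes = 10)
  expect_error(generate_bold(ps, bad), "too small")
})

test_that("noisy BOLD still recovers the planted patterns faithfully", {
  cfg <- tiny_cfg(n_subjects = 1)
  r <- generate_ratings(cfg)
  ps <- generate_beta_patterns(r, cfg)[[1]]
  est <- fit_condition_betas(generate_bold(ps, cfg))
  m <- match(paste(ps$conditions$item, ps$conditions$goal),
             paste(est$conditions$item, est$conditions$goal))
  cc <- vapply(seq_len(ncol(ps$patterns)), function(v)
    stats::cor(ps$patterns[, v], est$patterns[m, v]), 0)
  expect_gt(mean(cc), 0.9)
})
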