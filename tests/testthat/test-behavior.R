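# Choice-model design and fitting, exclusion rule, descriptive statistics.

make_ratings <- function(U, C = U * 0 + 50, monetary = NULL, goals) {
  n <- nrow(U)
  if (is.null(monetary)) monetary <- rep(10, n)
  data.frame(subject = 1, item = rep(seq_len(n), 2),
             goal = rep(goals, each = n),
             usefulness = c(U[, 1], U[, 2]),
             confidence = c(C[, 1], C[, 2]),
             monetary = rep(monetary, 2),
             familiarity = 50)
}

test_that("design predictors are the right-minus-left rating differences", {
  goals <- c("burning", "anchoring")
  U <- cbind(c(30, 80, 10), c(55, 20, 90))
  C <- cbind(c(40, 70, 20), c(60, 10, 30))
  r <- make_ratings(U, C, monetary = c(5, 25, 80), goals = goals)
  ch <- data.frame(subject = 1, session = 1, trial = 1:2,
                   goal = c("burning", "anchoring"),
                   left_item = c(1, 3), right_item = c(2, 1),
                   chosen_side = c("right", "left"), rt = 1)
  d <- build_choice_design(ch, r, goals = goals)
  expect_equal(d$cong_dU, c((80 - 30), (55 - 90)) / 100)
  expect_equal(d$incong_dU, c((20 - 55), (30 - 10)) / 100)
  expect_equal(d$cong_dC, c((70 - 40), (60 - 30)) / 100)
  expect_equal(d$cong_dUdC, d$cong_dU * d$cong_dC)
  expect_equal(d$d_monetary, c(25 - 5, 5 - 80))
  expect_equal(d$x_goal, c(-0.5, 0.5))
  expect_equal(d$chose_right, c(1L, 0L))
  # raw slider units behind the flag
  draw <- build_choice_design(ch, r, goals = goals, scale_predictors = FALSE)
  expect_equal(draw$cong_dU, c(50, -35))
})

test_that("identical ratings give all-zero differences", {
  goals <- c("burning", "anchoring")
  U <- cbind(rep(42, 4), rep(42, 4))
  r <- make_ratings(U, U, goals = goals)
  ch <- data.frame(subject = 1, session = 1, trial = 1,
                   goal = "burning", left_item = 1, right_item = 2,
                   chosen_side = "left", rt = 1)
  d <- build_choice_design(ch, r, goals = goals)
  expect_equal(unlist(d[, c("cong_dU", "incong_dU", "cong_dC", "incong_dC",
                            "cong_dUdC", "incong_dUdC")]),
               stats::setNames(rep(0, 6), c("cong_dU", "incong_dU", "cong_dC",
                                            "incong_dC", "cong_dUdC",
                                            "incong_dUdC")))
})

test_that("design equals independent recomputation on random tables", {
  cfg <- tiny_cfg(seed = 31)
  r <- generate_ratings(cfg)
  ch <- generate_choices(r, cfg)
  d <- build_choice_design(ch, r, goals = cfg$goals)
  expect_equal(nrow(d), nrow(ch))
  # independent recomputation via direct row lookups in the long table
  for (i in sample(nrow(ch), 20)) {
    tr <- ch[i, ]
    og <- setdiff(cfg$goals, tr$goal)
    look <- function(it, g, col)
      r[r$subject == tr$subject & r$item == it & r$goal == g, col]
    expect_equal(d$cong_dU[i],
                 (look(tr$right_item, tr$goal, "usefulness") -
                    look(tr$left_item, tr$goal, "usefulness")) / 100)
    expect_equal(d$incong_dC[i],
                 (look(tr$right_item, og, "confidence") -
                    look(tr$left_item, og, "confidence")) / 100)
  }
})

test_that("left/right swap flips difference signs and the response", {
  cfg <- tiny_cfg(seed = 37)
  r <- generate_ratings(cfg)
  ch <- generate_choices(r, cfg)
  sw <- ch
  sw$left_item <- ch$right_item; sw$right_item <- ch$left_item
  sw$chosen_side <- ifelse(ch$chosen_side == "left", "right", "left")
  d1 <- build_choice_design(ch, r, goals = cfg$goals)
  d2 <- build_choice_design(sw, r, goals = cfg$goals)
  for (v in c("cong_dU", "incong_dU", "cong_dC", "incong_dC", "d_monetary"))
    expect_equal(d2[[v]], -d1[[v]])
  expect_equal(d2$cong_dUdC, d1$cong_dUdC)   # product of two sign flips
  expect_equal(d2$chose_right, 1L - d1$chose_right)
  expect_equal(d2$x_goal, d1$x_goal)
})

test_that("missing ratings are reported with the offending item", {
  goals <- c("burning", "anchoring")
  r <- make_ratings(cbind(1:4 * 10, 1:4 * 10), goals = goals)
  ch <- data.frame(subject = 1, session = 1, trial = 1, goal = "burning",
                   left_item = 1, right_item = 99, chosen_side = "left",
                   rt = 1)
  expect_error(build_choice_design(ch, r, goals = goals), "99")
})

test_that("a deterministic congruent-usefulness chooser is flagged as separated", {
  cfg <- tiny_cfg(n_subjects = 2, choice_betas = c(cong_dU = 500),
                  choice_ranef_sd = 0, seed = 41)
  r <- generate_ratings(cfg)
  d <- build_choice_design(generate_choices(r, cfg), r, goals = cfg$goals)
  expect_warning(fit <- fit_choice_model(d), "separated")
  expect_true(all(fit$separated))
})

test_that("group coefficients recover planted signs at study scale", {
  cfg <- sim_config(n_subjects = 20, seed = 43)
  r <- generate_ratings(cfg)
  d <- build_choice_design(generate_choices(r, cfg), r, goals = cfg$goals)
  fit <- fit_choice_model(d)
  expect_gt(fit$coefficients["cong_dU"], 0)
  expect_lt(fit$p_value["cong_dU"], 0.001)
  expect_lt(fit$coefficients["cong_dC"], 0)
  s <- summary(fit)
  expect_true(all(c("ci_lo", "ci_hi") %in% names(s)))
})

test_that("null planted effects are not rejected too often", {
  # group p for the incongruent-confidence coefficient (planted 0) across
  # replicates behaves like a null test
  rej <- 0; n_rep <- 25
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_subjects = 10, seed = 5000 + i,
                      choice_betas = c(cong_dU = 1), choice_ranef_sd = 0.2)
    r <- generate_ratings(cfg)
    d <- build_choice_design(generate_choices(r, cfg), r, goals = cfg$goals)
    fit <- suppressWarnings(fit_choice_model(d))
    rej <- rej + (fit$p_value["incong_dC"] < 0.05)
  }
  expect_lte(rej, 5)   # binomial(25, .05) upper band
})

test_that("the exclusion threshold is applied to per-subject slopes", {
  fit <- structure(list(
    per_subject = matrix(c(2.4, 2.6, 10, NA), 4, 1,
                         dimnames = list(1:4, "cong_dU")),
    separated = c(FALSE, FALSE, FALSE, TRUE)), class = "choice_fit")
  ex <- exclude_inconsistent(fit, threshold = 0.025, slider_width = 100)
  expect_equal(ex$excluded, c("1", "4"))   # 0.024 < 0.025 <= 0.026
  expect_equal(ex$included, c("2", "3"))
})

test_that("pure random responders are excluded in most simulations", {
  excl <- 0; n_rep <- 20
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_subjects = 1, choice_betas = c(cong_dU = 0),
                      choice_ranef_sd = 0, seed = 6000 + i)
    r <- generate_ratings(cfg)
    d <- build_choice_design(generate_choices(r, cfg), r, goals = cfg$goals)
    d2 <- rbind(d, d)                     # two pseudo-subjects for the fitter
    d2$subject <- rep(1:2, each = nrow(d))
    fit <- suppressWarnings(fit_choice_model(d2))
    ex <- exclude_inconsistent(fit, slider_width = 100)
    excl <- excl + ("1" %in% ex$excluded)
  }
  expect_gte(excl, 0.95 * n_rep - 2)  # >= 95% with binomial slack
})

test_that("shared variance matches the printed identities", {
  expect_equal(shared_variance(0.12), 1.44)
  expect_equal(shared_variance(-0.06), 0.36)
  expect_equal(shared_variance(0), 0)
  expect_error(shared_variance(1.2), "exceed")
  # monotone in |r| and sign-symmetric
  rs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(shared_variance(rs)) >= 0))
  expect_equal(shared_variance(-rs), shared_variance(rs))
})

test_that("quadratic confidence fit is exact on a noiseless parabola", {
  goals <- c("burning", "anchoring")
  U <- cbind(seq(0, 100, length.out = 21), seq(0, 100, length.out = 21))
  C <- (U - 50)^2
  r <- make_ratings(U, C, goals = goals)
  U2 <- cbind(seq(2, 98, length.out = 25), seq(2, 98, length.out = 25))
  r2 <- make_ratings(U2, (U2 - 50)^2, goals = goals); r2$subject <- 2
  q <- fit_confidence_quadratic(rbind(r, r2))
  expect_equal(q$beta, 1, tolerance = 1e-8)
})

test_that("quadratic term is null-calibrated on linear data", {
  rej <- 0; n_rep <- 30
  for (i in seq_len(n_rep)) {
    set.seed(7000 + i)
    goals <- c("burning", "anchoring")
    rr <- lapply(1:6, function(s) {
      U <- matrix(runif(80, 0, 100), 40, 2)
      C <- 10 + 0.5 * U + matrix(rnorm(80, sd = 5), 40, 2)
      d <- make_ratings(U, C, goals = goals); d$subject <- s; d
    })
    q <- fit_confidence_quadratic(do.call(rbind, rr))
    rej <- rej + (q$p < 0.05)
  }
  expect_lte(rej / n_rep, 0.1 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("degenerate usefulness variance raises an error", {
  goals <- c("burning", "anchoring")
  r <- make_ratings(cbind(rep(50, 5), rep(50, 5)), goals = goals)
  expect_error(fit_confidence_quadratic(r), "degenerate")
})

test_that("rating correlation table has exact self- and antithetic entries", {
  goals <- c("burning", "anchoring")
  U <- cbind(1:10 * 10, 110 - 1:10 * 10)     # antithetic across goals
  r <- make_ratings(U, U, monetary = 1:10, goals = goals)
  ct <- rating_correlation_table(r, goals = goals)
  expect_equal(unname(diag(ct$mean)), rep(1, 5))
  expect_equal(ct$mean["U_burning", "U_anchoring"], -1)
  expect_equal(ct$mean["U_burning", "V_monetary"], 1)
  expect_equal(ct$n["U_burning", "U_anchoring"], 1)
})

test_that("reaction times admit a paired goal comparison", {
  cfg <- tiny_cfg(seed = 47)
  ch <- generate_choices(generate_ratings(cfg), cfg)
  ht <- rt_goal_test(ch, goals = cfg$goals)
  expect_s3_class(ht, "htest")
  expect_gt(ht$p.value, 0.001)   # no goal effect is planted
})

test_that("Firth logistic stays finite under complete separation", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)          # perfectly separated: ML diverges
  b <- firth_logistic(cbind(1, x = x), y)
  expect_true(all(is.finite(b)))
  expect_gt(b["x"], 0)
  expect_lt(abs(b["x"]), 10)
})

test_that("Firth logistic agrees with ML when the sample is large", {
  set.seed(71)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  bf <- firth_logistic(cbind(1, x = x), y)
  bm <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(bf), unname(bm), tolerance = 1e-3)
})

test_that("Firth slopes are shrunk relative to small-sample ML", {
  set.seed(73)
  shr <- 0
  for (i in 1:20) {
    x <- rnorm(25)
    y <- rbinom(25, 1, plogis(1.5 * x))
    bf <- firth_logistic(cbind(1, x = x), y)["x"]
    bm <- coef(suppressWarnings(glm(y ~ x, family = binomial())))["x"]
    shr <- shr + (abs(bf) < abs(bm))
  }
  expect_gte(shr, 18)   # bias reduction pulls the slope toward zero
})

test_that("the firth estimator never flags separation and recovers signs", {
  cfg <- sim_config(n_subjects = 8, seed = 79)
  r <- generate_ratings(cfg)
  d <- build_choice_design(generate_choices(r, cfg), r, goals = cfg$goals)
  fit <- fit_choice_model(d, estimator = "firth")
  expect_false(any(fit$separated))
  expect_gt(fit$coefficients["cong_dU"], 0)
  expect_lt(fit$p_value["cong_dU"], 0.01)
  # group slope below the per-subject ML mean: small-sample bias removed
  ml <- fit_choice_model(d, estimator = "summary")
  expect_lt(fit$coefficients["cong_dU"], ml$coefficients["cong_dU"])
})

test_that("Firth logistic marks aliased columns NA like glm", {
  set.seed(83)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(x))
  X <- cbind("(Intercept)" = 1, a = x, b = 2 * x)   # b aliased with a
  b <- firth_logistic(X, y)
  expect_true(is.na(b["b"]))
  expect_true(all(is.finite(b[c("(Intercept)", "a")])))
})
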