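# Rating, choice and design-layout generation for the synthetic study.

# Evaluate expr under a deterministic RNG stream derived from (seed, stream),
# restoring the caller's RNG state afterwards. Streams keep the different
# generator stages statistically independent under one config seed.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 99991L * as.integer(stream)) %%
             .Machine$integer.max)
  force(expr)
}

# Latent normal correlation giving Pearson r between uniform margins of a
# Gaussian copula: r_uniform = (6/pi) asin(rho/2)  =>  rho = 2 sin(pi r / 6).
latent_gauss_r <- function(r_uniform) 2 * sin(pi * r_uniform / 6)

#' Generate subjective ratings with planted correlation structure
#'
#' Draws, for every subject, usefulness ratings of `n_items` items under each
#' of the two goals, the associated confidence ratings, a monetary estimate
#' and a familiarity rating, plus one material composition per item.
#'
#' Usefulness under the two goals and monetary value are generated from a
#' trivariate Gaussian copula whose latent correlations are chosen
#' analytically so the uniform margins hit the target Pearson correlations
#' (`cross_goal_r` between the goals' usefulness; `monetary_r` between
#' monetary value and each goal's usefulness), then rescaled to the slider
#' interval. Confidence under each goal is a quadratic function of that
#' goal's centred usefulness with planted coefficient `conf_quadratic_beta`
#' plus Gaussian noise, truncated to the slider interval. Material
#' compositions are item-level Dirichlet(1,1,1,1) draws (exactly on the
#' 4-simplex) shared by all subjects.
#'
#' @param cfg a [sim_config()].
#' @return A data.frame with one row per subject x item x goal and columns
#'   `subject`, `item`, `goal`, `usefulness`, `confidence`, `monetary`,
#'   `familiarity`, `wood`, `metal`, `plastic`, `fabric`.
#' @export
generate_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lo <- cfg$rating_scale[1]; width <- diff(cfg$rating_scale)
  r_lat <- c(ug = latent_gauss_r(cfg$cross_goal_r),
             m1 = latent_gauss_r(cfg$monetary_r[1]),
             m2 = latent_gauss_r(cfg$monetary_r[2]))
  R <- matrix(c(1, r_lat["ug"], r_lat["m1"],
                r_lat["ug"], 1, r_lat["m2"],
                r_lat["m1"], r_lat["m2"], 1), 3, 3)
  ch <- tryCatch(chol(R), error = function(e)
    stop("target correlations are jointly infeasible (latent matrix not PD)"))
  with_stream(cfg$seed, 1L, {
    comp <- matrix(stats::rexp(cfg$n_items * 4), cfg$n_items, 4)
    comp <- comp / rowSums(comp)
    colnames(comp) <- c("wood", "metal", "plastic", "fabric")
    out <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      z <- matrix(stats::rnorm(cfg$n_items * 3), cfg$n_items, 3) %*% ch
      u <- stats::pnorm(z)                 # uniform margins, planted Pearson r
      U <- lo + width * u[, 1:2]           # usefulness goal 1, goal 2
      monetary <- cfg$monetary_range[1] +
        diff(cfg$monetary_range) * u[, 3]
      conf <- matrix(NA_real_, cfg$n_items, 2)
      for (g in 1:2) {
        # centred on the scale midpoint: keeps the curve inside the slider
        # bounds; the quadratic coefficient is invariant to the centring shift
        uc <- U[, g] - (lo + width / 2)
        mu <- 0.12 * width + 0.05 * uc + cfg$conf_quadratic_beta * uc^2
        conf[, g] <- pmin(cfg$rating_scale[2],
                          pmax(lo, mu + stats::rnorm(cfg$n_items,
                                                     sd = cfg$conf_noise_sd)))
      }
      fam <- lo + width * stats::runif(cfg$n_items)
      out[[s]] <- data.frame(
        subject = s,
        item = rep(seq_len(cfg$n_items), 2),
        goal = rep(cfg$goals, each = cfg$n_items),
        usefulness = c(U[, 1], U[, 2]),
        confidence = c(conf[, 1], conf[, 2]),
        monetary = rep(monetary, 2),
        familiarity = rep(fam, 2),
        comp[rep(seq_len(cfg$n_items), 2), , drop = FALSE],
        row.names = NULL)
    }
    do.call(rbind, out)
  })
}

# wide per-subject lookup: item -> (U, C) per goal plus monetary
ratings_lookup <- function(ratings, subject, goals) {
  rs <- ratings[ratings$subject == subject, ]
  g1 <- rs[rs$goal == goals[1], ]
  g2 <- rs[rs$goal == goals[2], ]
  g1 <- g1[order(g1$item), ]; g2 <- g2[order(g2$item), ]
  if (!identical(g1$item, g2$item))
    stop("subject ", subject, ": items differ across goals")
  list(item = g1$item,
       U = cbind(g1$usefulness, g2$usefulness),
       C = cbind(g1$confidence, g2$confidence),
       monetary = g1$monetary)
}

# Session trial sequence: 'I'/'C' slots such that every choice trial is
# preceded by at least `window` imagination trials within the session.
session_slots <- function(n_imag, n_choice, window) {
  slots <- sample(c(rep("I", n_imag), rep("C", n_choice)))
  repeat {
    n_i <- cumsum(slots == "I")
    bad <- which(slots == "C" & n_i < window)
    if (!length(bad)) break
    b <- bad[1]
    nxt <- which(slots == "I" & seq_along(slots) > b)[1]
    if (is.na(nxt)) stop("session layout cannot satisfy the choice window")
    slots[c(b, nxt)] <- slots[c(nxt, b)]
  }
  slots
}

#' Generate two-alternative choices from a planted logistic model
#'
#' Lays out the scanning sessions (goals alternate across sessions; each
#' goal's items are split over its two sessions), draws choice-trial item
#' pairs from the `choice_window` most recent imagination trials of the
#' session, and samples each choice from a logistic model with the planted
#' group coefficients `cfg$choice_betas` plus subject-level random slopes
#' drawn from N(0, `choice_ranef_sd`^2). Rating-based predictors enter on the
#' unit (rescaled slider) scale, matching [build_choice_design()].
#'
#' @param ratings output of [generate_ratings()].
#' @param cfg the same [sim_config()].
#' @return A data.frame of choice trials: `subject`, `session`, `trial`
#'   (position within session), `goal`, `left_item`, `right_item`,
#'   `chosen_side` ("left"/"right"), `rt` seconds.
#' @export
generate_choices <- function(ratings, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!nrow(ratings)) stop("empty ratings table")
  n_goal_sessions <- cfg$n_sessions / 2
  if (cfg$n_sessions %% 2 != 0)
    stop("n_sessions must be even (goals alternate)")
  items_per_session <- cfg$n_items / n_goal_sessions
  if (cfg$imagination_per_session != items_per_session)
    stop("imagination_per_session must equal n_items / sessions-per-goal so ",
         "each item appears exactly once per goal")
  width <- diff(cfg$rating_scale)
  b <- cfg$choice_betas
  with_stream(cfg$seed, 2L, {
    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      lk <- ratings_lookup(ratings, s, cfg$goals)
      # random slopes scale with each predictor's natural range so that the
      # raw-currency monetary difference does not dominate the linear
      # predictor (its coefficient lives on a 1/width_monetary scale)
      ranef_scale <- rep(1, length(b))
      ranef_scale[names(b) == "d_monetary"] <- 1 / diff(cfg$monetary_range)
      ranef <- stats::rnorm(length(b), sd = cfg$choice_ranef_sd) * ranef_scale
      bs <- b + ranef
      # per-goal item order, split across that goal's sessions
      order_g <- lapply(1:2, function(g) sample(lk$item))
      for (sess in seq_len(cfg$n_sessions)) {
        g <- if (sess %% 2 == 1) 1L else 2L
        g_sess <- ceiling(sess / 2)          # which session of this goal
        idx <- ((g_sess - 1) * items_per_session + 1):(g_sess * items_per_session)
        imag_items <- order_g[[g]][idx]
        slots <- session_slots(cfg$imagination_per_session,
                               cfg$choice_per_session, cfg$choice_window)
        seen <- integer(0); k <- 0L
        for (t in seq_along(slots)) {
          if (slots[t] == "I") {
            k <- k + 1L
            seen <- c(seen, imag_items[k])
          } else {
            pool <- utils::tail(seen, cfg$choice_window)
            pair <- sample(pool, 2)
            li <- pair[1]; ri <- pair[2]
            il <- match(li, lk$item); ir <- match(ri, lk$item)
            og <- 3L - g
            dU  <- (lk$U[ir, g]  - lk$U[il, g])  / width
            dUi <- (lk$U[ir, og] - lk$U[il, og]) / width
            dC  <- (lk$C[ir, g]  - lk$C[il, g])  / width
            dCi <- (lk$C[ir, og] - lk$C[il, og]) / width
            dM  <- lk$monetary[ir] - lk$monetary[il]
            xg <- if (g == 2L) 0.5 else -0.5
            eta <- bs["intercept"] + bs["goal"] * xg +
              bs["cong_dU"] * dU + bs["incong_dU"] * dUi +
              bs["cong_dC"] * dC + bs["incong_dC"] * dCi +
              bs["cong_dUdC"] * dU * dC + bs["incong_dUdC"] * dUi * dCi +
              bs["d_monetary"] * dM
            p_right <- 1 / (1 + exp(-eta))
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s, session = sess, trial = t, goal = cfg$goals[g],
              left_item = li, right_item = ri,
              chosen_side = if (stats::runif(1) < p_right) "right" else "left",
              rt = stats::rlnorm(1, log(1.4), 0.25))
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Summarise the scanning-session layout
#'
#' @param cfg a [sim_config()].
#' @return A list: per-session and total trial counts, imagination and choice
#'   trial percentages (rounded to 1 decimal, as conventionally reported),
#'   session duration in seconds and minutes, and the condition count
#'   (items x goals).
#' @export
design_summary <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  per <- cfg$imagination_per_session + cfg$choice_per_session
  list(
    trials_per_session = per,
    imagination_per_session = cfg$imagination_per_session,
    choice_per_session = cfg$choice_per_session,
    n_sessions = cfg$n_sessions,
    total_trials = per * cfg$n_sessions,
    imagination_pct = round(100 * cfg$imagination_per_session / per, 1),
    choice_pct = round(100 * cfg$choice_per_session / per, 1),
    session_duration_s = cfg$n_volumes * cfg$tr_seconds,
    session_duration_min = cfg$n_volumes * cfg$tr_seconds / 60,
    n_conditions = cfg$n_items * length(cfg$goals))
}
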