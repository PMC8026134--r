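# Planted multivoxel codes: condition beta patterns and BOLD time series.

# n_voxels grid voxels nearest to `center` (voxel coords); ties broken by
# linear index so region membership is deterministic.
region_voxels <- function(grid_dim, center, n_voxels) {
  if (n_voxels > prod(grid_dim)) stop("region larger than the grid")
  if (is.null(center)) center <- ceiling(grid_dim / 2)
  co <- as.matrix(expand.grid(x = seq_len(grid_dim[1]),
                              y = seq_len(grid_dim[2]),
                              z = seq_len(grid_dim[3])))
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  order(d2, seq_len(nrow(co)))[seq_len(n_voxels)]
}

# centred unit-scale rating vector (slider -> [-0.5, 0.5]-ish, mean 0)
unit_centre <- function(x, scale) {
  u <- (x - scale[1]) / diff(scale)
  u - mean(u)
}

#' Generate condition beta patterns with planted representational codes
#'
#' For every subject, builds one multivoxel pattern per condition (item x
#' goal) as a weighted sum of the codes planted by the config's
#' [region_spec()]s, plus i.i.d. Gaussian voxel noise of SD
#' `cfg$noise_sd_pattern`. Code maps have unit per-voxel variance and ratings
#' enter centred on the unit slider scale, so a code weight is the per-voxel
#' signal SD contributed by one unit of centred rating.
#'
#' Codes: `identity` (item-specific random pattern shared across goals),
#' `material` (linear readout of the centred material composition),
#' `usefulness_goal_general` (one linear map of the congruent usefulness,
#' shared by both goals), `usefulness_goal_specific` / `usefulness_congruent`
#' (two independent per-goal maps of the congruent usefulness), `confidence`
#' (linear map of the congruent confidence; a fraction
#' `shared_population_fraction` of voxels reuse their usefulness weights).
#'
#' A set of pure-noise residual samples with the same voxel covariance as the
#' pattern noise is attached for prewhitening.
#'
#' @param ratings output of [generate_ratings()].
#' @param cfg the same [sim_config()]; `cfg$region_specs` must be nonempty.
#' @param mask `"regions"` (default) restricts the grid mask to the union of
#'   the planted regions; `"grid"` keeps the whole grid, with pure-noise
#'   voxels outside the regions (use this for searchlight runs).
#' @param n_residuals residual noise samples to attach per subject.
#' @param subjects subset of subject ids to generate (default all).
#' @return A list of [pattern_set()] objects, one per subject.
#' @export
generate_beta_patterns <- function(ratings, cfg, mask = c("regions", "grid"),
                                   n_residuals = 120, subjects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  mask <- match.arg(mask)
  if (!length(cfg$region_specs)) stop("cfg$region_specs must be defined")
  if (is.null(subjects)) subjects <- seq_len(cfg$n_subjects)
  grid_dim <- cfg$grid_dim
  reg_idx <- lapply(cfg$region_specs, function(rs)
    region_voxels(grid_dim, rs$center, rs$n_voxels))
  names(reg_idx) <- vapply(cfg$region_specs, `[[`, "", "name")
  msk <- array(FALSE, grid_dim)
  if (mask == "grid") msk[] <- TRUE else msk[unlist(reg_idx)] <- TRUE
  in_mask <- which(msk)
  V <- length(in_mask)
  reg_cols <- lapply(reg_idx, function(ix) match(ix, in_mask))
  n_cond <- cfg$n_items * 2
  conditions <- data.frame(item = rep(seq_len(cfg$n_items), 2),
                           goal = rep(cfg$goals, each = cfg$n_items))
  # item-level material composition (same stream as generate_ratings)
  comp <- with_stream(cfg$seed, 1L, {
    m <- matrix(stats::rexp(cfg$n_items * 4), cfg$n_items, 4)
    m / rowSums(m)
  })
  comp_c <- sweep(comp, 2, colMeans(comp))
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    lk <- ratings_lookup(ratings, s, cfg$goals)
    u <- apply(lk$U, 2, unit_centre, scale = cfg$rating_scale)
    cc <- apply(lk$C, 2, unit_centre, scale = cfg$rating_scale)
    out[[si]] <- with_stream(cfg$seed, 100L + s, {
      P <- matrix(stats::rnorm(n_cond * V, sd = cfg$noise_sd_pattern),
                  n_cond, V)
      for (ri in seq_along(cfg$region_specs)) {
        rs <- cfg$region_specs[[ri]]
        cols <- reg_cols[[ri]]
        nv <- length(cols)
        w <- rs$code_weights
        u_map <- NULL                     # map reused by the confidence code
        for (code in rs$codes) {
          if (code == "identity") {
            M <- matrix(stats::rnorm(cfg$n_items * nv), cfg$n_items, nv)
            P[, cols] <- P[, cols] + w[code] * M[conditions$item, ]
          } else if (code == "material") {
            M <- matrix(stats::rnorm(4 * nv), 4, nv)
            P[, cols] <- P[, cols] + w[code] * (comp_c %*% M)[conditions$item, ]
          } else if (code == "usefulness_goal_general") {
            a <- stats::rnorm(nv)
            u_map <- w[code] * a
            sig <- c(u[, 1], u[, 2])       # congruent U regardless of goal
            P[, cols] <- P[, cols] + outer(sig, u_map)
          } else if (code %in% c("usefulness_goal_specific",
                                 "usefulness_congruent")) {
            a1 <- stats::rnorm(nv); a2 <- stats::rnorm(nv)
            u_map <- w[code] * a1
            P[, cols] <- P[, cols] +
              outer(c(u[, 1], rep(0, cfg$n_items)), w[code] * a1) +
              outer(c(rep(0, cfg$n_items), u[, 2]), w[code] * a2)
          } else if (code == "confidence") {
            b <- w[code] * stats::rnorm(nv)
            if (!is.null(u_map) && rs$shared_population_fraction > 0) {
              n_sh <- round(rs$shared_population_fraction * nv)
              if (n_sh > 0) {
                sh <- sample.int(nv, n_sh)
                b[sh] <- u_map[sh]         # identical weights on shared voxels
              }
            }
            sig <- c(cc[, 1], cc[, 2])
            P[, cols] <- P[, cols] + outer(sig, b)
          }
        }
      }
      resid <- matrix(stats::rnorm(n_residuals * V,
                                   sd = max(cfg$noise_sd_pattern, 1e-8)),
                      n_residuals, V)
      ps <- pattern_set(P, conditions, msk, voxel_mm = cfg$voxel_mm,
                        residuals = resid, regions = reg_cols)
      ps
    })
    out[[si]]$subject <- s
  }
  out
}

#' Generate BOLD time series from condition patterns
#'
#' Lays the imagination events of each condition out over the scanning
#' sessions (goals alternate; each goal's items split over its sessions),
#' sets every event's amplitude to the condition's planted voxel pattern,
#' convolves with the canonical double-gamma HRF, and adds a slow cosine
#' drift, a small motion-coupled component and white noise. Choice trials
#' appear in the events table (amplitude zero on the planted codes).
#'
#' @param ps a [pattern_set()] for one subject (from
#'   [generate_beta_patterns()]).
#' @param cfg the [sim_config()].
#' @param subject subject id used for the RNG stream (defaults to
#'   `ps$subject`).
#' @return A list with `sessions` (each: `bold` volumes x voxels matrix,
#'   `events` data.frame with onset/duration/trial_type/item/goal, `motion`
#'   volumes x 6 matrix), plus `mask`, `voxel_mm`, `tr`.
#' @export
generate_bold <- function(ps, cfg, subject = NULL) {
  stopifnot(inherits(ps, "pattern_set"), inherits(cfg, "sim_config"))
  if (is.null(subject)) subject <- if (!is.null(ps$subject)) ps$subject else 1L
  soa <- cfg$n_volumes * cfg$tr_seconds /
    (cfg$imagination_per_session + cfg$choice_per_session)
  n_goal_sessions <- cfg$n_sessions / 2
  items_per_session <- cfg$n_items / n_goal_sessions
  if (items_per_session != cfg$imagination_per_session)
    stop("n_volumes/session layout inconsistent with the condition count")
  dur_imag <- 5; dur_choice <- 3.5
  if ((cfg$imagination_per_session + cfg$choice_per_session - 1) * soa +
      dur_imag > cfg$n_volumes * cfg$tr_seconds + 1e-9)
    stop("n_volumes too small for the session layout")
  V <- ncol(ps$patterns)
  with_stream(cfg$seed, 500L + subject, {
    order_g <- lapply(1:2, function(g) sample(seq_len(cfg$n_items)))
    sessions <- vector("list", cfg$n_sessions)
    for (sess in seq_len(cfg$n_sessions)) {
      g <- if (sess %% 2 == 1) 1L else 2L
      g_sess <- ceiling(sess / 2)
      idx <- ((g_sess - 1) * items_per_session + 1):(g_sess * items_per_session)
      imag_items <- order_g[[g]][idx]
      slots <- session_slots(cfg$imagination_per_session,
                             cfg$choice_per_session, cfg$choice_window)
      onset <- (seq_along(slots) - 1) * soa
      events <- data.frame(onset = onset,
                           duration = ifelse(slots == "I", dur_imag, dur_choice),
                           trial_type = ifelse(slots == "I", "imagination",
                                               "choice"),
                           item = NA_integer_, goal = cfg$goals[g])
      events$item[slots == "I"] <- imag_items
      # neural amplitude per event per voxel; choice events are zero here
      amp <- matrix(0, nrow(events), V)
      ii <- which(slots == "I")
      cond_row <- match(paste(imag_items, cfg$goals[g]),
                        paste(ps$conditions$item, ps$conditions$goal))
      amp[ii, ] <- ps$patterns[cond_row, , drop = FALSE]
      X1 <- convolve_events(events$onset, events$duration, cfg$tr_seconds,
                            cfg$n_volumes)          # volumes x events
      bold <- X1 %*% amp
      # slow cosine drift (below the 1/128 Hz cutoff) + motion + white noise
      t_sec <- (seq_len(cfg$n_volumes) - 1) * cfg$tr_seconds
      T_tot <- cfg$n_volumes * cfg$tr_seconds
      drift_basis <- sapply(1:3, function(k) cos(pi * k * t_sec / T_tot))
      drift_amp <- matrix(stats::rnorm(3 * V, sd = cfg$bold_drift_sd), 3, V)
      motion <- apply(matrix(stats::rnorm(cfg$n_volumes * 6, sd = 0.02),
                             cfg$n_volumes, 6), 2, cumsum)
      motion <- pmin(pmax(motion, -2), 2)
      G <- matrix(stats::rnorm(6 * V, sd = 0.05), 6, V)
      bold <- bold + drift_basis %*% drift_amp + motion %*% G +
        matrix(stats::rnorm(cfg$n_volumes * V, sd = cfg$bold_noise_sd),
               cfg$n_volumes, V)
      sessions[[sess]] <- list(bold = bold, events = events, motion = motion)
    }
    list(sessions = sessions, mask = ps$mask, voxel_mm = ps$voxel_mm,
         tr = cfg$tr_seconds, conditions = ps$conditions)
  })
}
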