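#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: the rating task (items,
#' goals, slider scale, planted correlation structure), the two-alternative
#' choice task (planted logistic coefficients and random-effect spread), the
#' voxel grid and region specifications for the planted multivoxel codes, and
#' the scanning layout (TR, volumes, trials per session).
#'
#' Defaults reproduce the study conditions of the survival-goals paradigm:
#' 120 everyday items rated for usefulness and confidence under a "burning"
#' and an "anchoring" goal on unnumbered continuous sliders (stored here on a
#' 0-100 scale), weak cross-goal usefulness correlation (Pearson r = 0.12), a
#' quadratic confidence-usefulness relationship (coefficient 0.03 in slider
#' units), four scanning sessions of 84 trials each (60 imagination + 24
#' choice), TR = 3.36 s, 225 volumes per session.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_items number of items rated under each goal.
#' @param goals character vector of two goal labels.
#' @param rating_scale numeric length-2, closed slider interval.
#' @param cross_goal_r target Pearson correlation between the two goals'
#'   usefulness ratings (must lie in (-1, 1)).
#' @param monetary_r length-2: target Pearson correlation of monetary value
#'   with usefulness under goal 1 and goal 2.
#' @param monetary_range price range (currency units) for monetary estimates.
#' @param conf_quadratic_beta planted quadratic coefficient of confidence on
#'   centred usefulness, in slider units.
#' @param conf_noise_sd residual SD of confidence around the quadratic curve.
#' @param choice_betas named numeric vector of planted logistic coefficients
#'   on the 8 choice predictors (see [build_choice_design()]); rating-based
#'   predictors are on the unit (rescaled slider) scale.
#' @param choice_ranef_sd SD of the subject-level random slopes added to each
#'   planted coefficient.
#' @param noise_sd_pattern SD of i.i.d. Gaussian voxel noise added to the
#'   condition beta patterns, in the same arbitrary units as the planted code
#'   weights (maps have unit per-voxel variance, ratings enter centred on the
#'   unit scale).
#' @param grid_dim integer length-3, voxel grid extents.
#' @param voxel_mm isotropic voxel size in mm.
#' @param region_specs list of [region_spec()] objects placing planted codes.
#' @param tr_seconds repetition time in seconds.
#' @param n_volumes volumes acquired per session.
#' @param n_sessions number of scanning sessions.
#' @param imagination_per_session,choice_per_session trial counts per session.
#' @param choice_window choice options are drawn from the items shown in this
#'   many most recent imagination trials.
#' @param bold_noise_sd white-noise SD of the simulated BOLD time series.
#' @param bold_drift_sd SD of the slow cosine drift added per session.
#' @param seed integer seed; a fixed seed makes every generated object
#'   bit-identical across runs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [region_spec()], [generate_ratings()], [generate_choices()],
#'   [generate_beta_patterns()], [generate_bold()], [design_summary()]
#' @export
sim_config <- function(n_subjects = 30,
                       n_items = 120,
                       goals = c("burning", "anchoring"),
                       rating_scale = c(0, 100),
                       cross_goal_r = 0.12,
                       monetary_r = c(-0.06, 0.17),
                       monetary_range = c(1, 200),
                       conf_quadratic_beta = 0.03,
                       conf_noise_sd = 3,
                       choice_betas = c(intercept = 0, goal = 0,
                                        cong_dU = 4.71, incong_dU = -0.11,
                                        cong_dC = -0.64, incong_dC = 0,
                                        cong_dUdC = 0, incong_dUdC = 0,
                                        d_monetary = 0),
                       choice_ranef_sd = 0.5,
                       noise_sd_pattern = 2,
                       grid_dim = c(20L, 20L, 20L),
                       voxel_mm = 3,
                       region_specs = list(),
                       tr_seconds = 3.36,
                       n_volumes = 225,
                       n_sessions = 4,
                       imagination_per_session = 60,
                       choice_per_session = 24,
                       choice_window = 10,
                       bold_noise_sd = 1,
                       bold_drift_sd = 1,
                       seed = 1L) {
  stopifnot(length(rating_scale) == 2, all(is.finite(rating_scale)))
  if (rating_scale[1] >= rating_scale[2])
    stop("rating_scale bounds must be ordered (lower < upper)")
  if (!is.finite(cross_goal_r) || cross_goal_r <= -1 || cross_goal_r >= 1)
    stop("cross_goal_r must lie strictly inside (-1, 1)")
  if (any(abs(monetary_r) >= 1))
    stop("monetary_r entries must lie strictly inside (-1, 1)")
  counts <- c(n_subjects = n_subjects, n_items = n_items,
              n_volumes = n_volumes, n_sessions = n_sessions,
              imagination_per_session = imagination_per_session,
              choice_per_session = choice_per_session,
              choice_window = choice_window)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (length(goals) != 2 || anyDuplicated(goals))
    stop("exactly two distinct goal labels are required")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (noise_sd_pattern < 0 || conf_noise_sd < 0 || choice_ranef_sd < 0 ||
      bold_noise_sd < 0 || bold_drift_sd < 0)
    stop("noise SDs must be nonnegative")
  beta_names <- c("intercept", "goal", "cong_dU", "incong_dU", "cong_dC",
                  "incong_dC", "cong_dUdC", "incong_dUdC", "d_monetary")
  full <- stats::setNames(numeric(length(beta_names)), beta_names)
  if (is.null(names(choice_betas)))
    stop("choice_betas must be a named vector")
  unknown <- setdiff(names(choice_betas), beta_names)
  if (length(unknown))
    stop("unknown choice_betas entries: ", paste(unknown, collapse = ", "))
  full[names(choice_betas)] <- choice_betas
  for (rs in region_specs)
    if (!inherits(rs, "region_spec")) stop("region_specs must hold region_spec objects")
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_items = as.integer(n_items),
    goals = as.character(goals), rating_scale = as.numeric(rating_scale),
    cross_goal_r = cross_goal_r, monetary_r = monetary_r,
    monetary_range = monetary_range,
    conf_quadratic_beta = conf_quadratic_beta, conf_noise_sd = conf_noise_sd,
    choice_betas = full, choice_ranef_sd = choice_ranef_sd,
    noise_sd_pattern = noise_sd_pattern,
    grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
    region_specs = region_specs,
    tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
    n_sessions = as.integer(n_sessions),
    imagination_per_session = as.integer(imagination_per_session),
    choice_per_session = as.integer(choice_per_session),
    choice_window = as.integer(choice_window),
    bold_noise_sd = bold_noise_sd, bold_drift_sd = bold_drift_sd,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Planted-code region specification
#'
#' Describes one region of the simulated volume and the representational
#' codes planted in it. A region is the set of `n_voxels` voxels closest (in
#' voxel space) to `center`, so it is spatially compact, as a cortical region
#' of interest would be.
#'
#' Available codes:
#' \describe{
#'   \item{identity}{item-specific random pattern shared across goals.}
#'   \item{material}{linear readout of the item's 4-component material
#'     composition (wood, metal, plastic, fabric), centred on the simplex.}
#'   \item{usefulness_goal_general}{one random linear map applied to the
#'     congruent (current-goal) usefulness regardless of goal — a
#'     "common-currency" value code.}
#'   \item{usefulness_goal_specific}{two independent maps, one per goal, each
#'     applied to its own goal's usefulness. `usefulness_congruent` is
#'     accepted as a synonym.}
#'   \item{confidence}{linear map of the congruent confidence rating;
#'     `shared_population_fraction` of the usefulness-carrying voxels reuse
#'     their usefulness weights for confidence (identical weights), the rest
#'     of the confidence support gets independent weights.}
#' }
#'
#' @param name region label.
#' @param center integer length-3 voxel coordinate of the region centre;
#'   `NULL` places it at the grid centre.
#' @param n_voxels number of voxels in the region (must be positive).
#' @param codes character vector of code descriptors (see Details).
#' @param code_weights named nonnegative weights, one per code; unnamed
#'   scalar recycles to all codes. A weight is the SD (per voxel, before
#'   noise) contributed by one unit of the centred unit-scale rating.
#' @param shared_population_fraction fraction in [0,1] of usefulness-carrying
#'   voxels that also carry the confidence code with identical weights.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, center = NULL, n_voxels = 137,
                        codes = "usefulness_goal_general",
                        code_weights = 1,
                        shared_population_fraction = 0.5) {
  valid <- c("identity", "material", "usefulness_congruent",
             "usefulness_goal_general", "usefulness_goal_specific",
             "confidence")
  bad <- setdiff(codes, valid)
  if (length(bad)) stop("unknown codes: ", paste(bad, collapse = ", "))
  if (n_voxels <= 0) stop("region '", name, "' has zero voxels")
  if (shared_population_fraction < 0 || shared_population_fraction > 1)
    stop("shared_population_fraction must lie in [0, 1]")
  if (is.null(names(code_weights))) {
    if (length(code_weights) == 1)
      code_weights <- stats::setNames(rep(code_weights, length(codes)), codes)
    else stop("code_weights must be named or a single scalar")
  }
  if (any(code_weights < 0)) stop("code weights must be nonnegative")
  missing_w <- setdiff(codes, names(code_weights))
  if (length(missing_w))
    stop("no weight for codes: ", paste(missing_w, collapse = ", "))
  structure(list(name = name, center = center,
                 n_voxels = as.integer(n_voxels),
                 codes = codes, code_weights = code_weights,
                 shared_population_fraction = shared_population_fraction),
            class = "region_spec")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_subjects, "subjects,", x$n_items,
      "items x", length(x$goals), "goals (",
      paste(x$goals, collapse = ", "), ")\n")
  cat("  sliders on [", x$rating_scale[1], ",", x$rating_scale[2],
      "], cross-goal r =", x$cross_goal_r,
      ", quadratic confidence beta =", x$conf_quadratic_beta, "\n")
  cat("  grid", paste(x$grid_dim, collapse = "x"), "at", x$voxel_mm,
      "mm,", length(x$region_specs), "region(s), pattern noise SD",
      x$noise_sd_pattern, "\n")
  cat("  sessions:", x$n_sessions, "x (", x$imagination_per_session,
      "imagination +", x$choice_per_session, "choice ), TR",
      x$tr_seconds, "s,", x$n_volumes, "volumes\n")
  invisible(x)
}
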