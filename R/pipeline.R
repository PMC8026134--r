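# I/O and orchestration: NIfTI/TSV/JSON serialisation of every analysis
# object and a seeded end-to-end run over synthetic data.

#' Write / read a table as TSV
#'
#' Plain tab-separated serialisation with header, used for ratings, choices,
#' events, condition labels and cluster tables.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a pattern set to disk
#'
#' Beta patterns go to a 4-D NIfTI volume (one 3-D volume per condition, NA
#' outside the mask stored as 0), the mask to a 3-D NIfTI, condition labels
#' to TSV, residuals (if any) to a second 4-D NIfTI, and a JSON sidecar
#' records the geometry.
#'
#' @param ps a [pattern_set()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default "patterns").
#' @return The directory, invisibly.
#' @export
write_pattern_set <- function(ps, dir, prefix = "patterns") {
  stopifnot(inherits(ps, "pattern_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(ps$mask)
  n <- nrow(ps$patterns)
  arr <- array(0, c(dims, n))
  lin <- which(ps$mask)
  for (i in seq_len(n)) {
    v <- array(0, dims); v[lin] <- ps$patterns[i, ]
    arr[, , , i] <- v
  }
  pd <- rep(ps$voxel_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = pd),
                     file.path(dir, paste0(prefix, "_beta.nii")))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(ps$mask), dims),
                                     pixdim = pd),
                     file.path(dir, paste0(prefix, "_mask.nii")))
  write_tsv_table(ps$conditions, file.path(dir, paste0(prefix, "_labels.tsv")))
  if (!is.null(ps$residuals)) {
    nr <- nrow(ps$residuals)
    ra <- array(0, c(dims, nr))
    for (i in seq_len(nr)) {
      v <- array(0, dims); v[lin] <- ps$residuals[i, ]
      ra[, , , i] <- v
    }
    RNifti::writeNifti(RNifti::asNifti(ra, pixdim = pd),
                       file.path(dir, paste0(prefix, "_resid.nii")))
  }
  jsonlite::write_json(list(voxel_mm = ps$voxel_mm, n_conditions = n,
                            grid_dim = dims),
                       file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pattern set written by [write_pattern_set()]
#'
#' Validates the label/volume correspondence and finiteness of the in-mask
#' voxels.
#'
#' @param dir directory containing the files.
#' @param prefix file name prefix.
#' @return A [pattern_set()].
#' @export
read_pattern_set <- function(dir, prefix = "patterns") {
  lab_path <- file.path(dir, paste0(prefix, "_labels.tsv"))
  if (!file.exists(lab_path)) stop("missing label file: ", lab_path)
  labels <- read_tsv_table(lab_path)
  if (anyNA(labels$item) || anyNA(labels$goal))
    stop("missing label row in ", lab_path)
  beta <- RNifti::readNifti(file.path(dir, paste0(prefix, "_beta.nii")))
  maskv <- RNifti::readNifti(file.path(dir, paste0(prefix, "_mask.nii")))
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  mask <- array(maskv > 0.5, dim(maskv))
  n <- dim(beta)[4]
  if (n != nrow(labels))
    stop("label/volume count mismatch: ", nrow(labels), " labels vs ",
         n, " volumes in ", prefix, "_beta.nii")
  lin <- which(mask)
  P <- matrix(NA_real_, n, length(lin))
  for (i in seq_len(n)) P[i, ] <- beta[, , , i][lin]
  if (!all(is.finite(P))) {
    bad <- which(!is.finite(P), arr.ind = TRUE)
    stop("non-finite voxels in volumes: ",
         paste(unique(bad[, 1]), collapse = ", "))
  }
  res <- NULL
  rp <- file.path(dir, paste0(prefix, "_resid.nii"))
  if (file.exists(rp)) {
    ra <- RNifti::readNifti(rp)
    nr <- dim(ra)[4]
    res <- matrix(NA_real_, nr, length(lin))
    for (i in seq_len(nr)) res[i, ] <- ra[, , , i][lin]
  }
  pattern_set(P, labels, mask, voxel_mm = side$voxel_mm, residuals = res)
}

#' Write / read a statistic map as NIfTI
#' @param map a [stat_map()].
#' @param path output `.nii` path.
#' @return `read_stat_map` returns a [stat_map()].
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  arr <- map$values
  arr[!map$mask] <- 0
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(map$voxel_mm, 3)), path)
  mp <- sub("\\.nii(\\.gz)?$", "_mask.nii", path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(map$mask),
                                           dim(map$mask)),
                                     pixdim = rep(map$voxel_mm, 3)), mp)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  v <- RNifti::readNifti(path)
  mp <- sub("\\.nii(\\.gz)?$", "_mask.nii", path)
  m <- RNifti::readNifti(mp)
  vx <- RNifti::pixdim(v)[1]
  stat_map(array(as.numeric(v), dim(v)), array(m > 0.5, dim(m)), vx)
}

#' Read a run configuration (YAML or JSON)
#'
#' Accepts a YAML or JSON file of [sim_config()] arguments plus optional
#' stage parameters, and returns the validated config. Unknown top-level
#' keys under `analysis` are carried through untouched.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`).
#' @return List with `sim` (a [sim_config()]) and `analysis` (list).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$region_specs)) {
    rs_list <- sim_args$region_specs
    if (is.data.frame(rs_list))          # jsonlite simplifies to a data.frame
      rs_list <- lapply(seq_len(nrow(rs_list)), function(i)
        as.list(rs_list[i, , drop = FALSE]))
    sim_args$region_specs <- lapply(rs_list, function(rs)
      do.call(region_spec, rs[!vapply(rs, is.null, TRUE)]))
  }
  if (!is.null(sim_args$choice_betas))
    sim_args$choice_betas <- unlist(sim_args$choice_betas)
  list(sim = do.call(sim_config, sim_args), analysis = raw$analysis %||% list())
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, in dependency order: rating/choice simulation, the behavioural
#' analyses (choice model, exclusion rule, shared variance, quadratic
#' confidence fit), beta-pattern generation, ROI RSA of the planted
#' confidence code, the participation-vector overlap test, and within/cross
#' goal classification. Writes a JSON report (plus TSV tables) with every
#' statistic, seed and parameter, and returns the report as a list.
#'
#' Stage toggles and parameters come from `analysis`: `run_rsa`,
#' `run_overlap`, `run_xclass` (all default TRUE), `n_perm_overlap`
#' (default 500), `cv_folds` (default 10), `choice_estimator` (default
#' `"firth"`: separation-proof and unbiased on small per-subject designs).
#'
#' @param cfg a [sim_config()], or the list returned by [read_run_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param analysis optional analysis-parameter list (overrides the config's).
#' @return The report list, invisibly when writing.
#' @export
run_all <- function(cfg, out_dir = NULL, analysis = list()) {
  if (!inherits(cfg, "sim_config") && !is.null(cfg$sim)) {
    analysis <- utils::modifyList(cfg$analysis %||% list(), analysis)
    cfg <- cfg$sim
  }
  stopifnot(inherits(cfg, "sim_config"))
  an <- utils::modifyList(list(run_rsa = TRUE, run_overlap = TRUE,
                               run_xclass = TRUE, n_perm_overlap = 500,
                               cv_folds = 10, choice_estimator = "firth"),
                          analysis)
  report <- list(seed = cfg$seed,
                 design = design_summary(cfg),
                 parameters = list(cross_goal_r = cfg$cross_goal_r,
                                   conf_quadratic_beta = cfg$conf_quadratic_beta,
                                   choice_betas = as.list(cfg$choice_betas),
                                   noise_sd_pattern = cfg$noise_sd_pattern))
  ratings <- generate_ratings(cfg)
  choices <- generate_choices(ratings, cfg)
  design <- build_choice_design(choices, ratings, goals = cfg$goals,
                                rating_scale = cfg$rating_scale)
  fit <- fit_choice_model(design, estimator = an$choice_estimator)
  excl <- exclude_inconsistent(fit, slider_width = diff(cfg$rating_scale))
  ctab <- rating_correlation_table(ratings, goals = cfg$goals)
  quad <- fit_confidence_quadratic(ratings)
  r_cross <- ctab$mean[1, 2]
  report$behavior <- list(
    choice_coefficients = as.list(fit$coefficients),
    choice_p = as.list(fit$p_value),
    n_excluded = length(excl$excluded),
    cross_goal_r_mean = r_cross,
    cross_goal_shared_variance_pct = shared_variance(r_cross),
    confidence_quadratic = quad[c("beta", "t", "p")])
  have_regions <- length(cfg$region_specs) > 0
  pats <- if (have_regions) generate_beta_patterns(ratings, cfg) else NULL
  if (have_regions && an$run_rsa) {
    rsa <- list()
    for (ri in seq_along(cfg$region_specs)) {
      rs <- cfg$region_specs[[ri]]
      conf_vals <- function(ps, s) {
        lk <- ratings_lookup(ratings, s, cfg$goals)
        gi <- match(ps$conditions$goal, cfg$goals)
        lk$C[cbind(ps$conditions$item, gi)]
      }
      rho <- numeric(length(pats))
      for (s in seq_along(pats)) {
        mdl <- model_value(conf_vals(pats[[s]], s), pats[[s]]$conditions)
        cols_s <- pats[[s]]$regions[[rs$name]]
        P <- prewhiten(pats[[s]]$patterns[, cols_s, drop = FALSE],
                       residuals = pats[[s]]$residuals[, cols_s, drop = FALSE])
        rho[s] <- compare_rdms(brain_rdm(P, conditions = pats[[s]]$conditions),
                               mdl)
      }
      wt <- stats::wilcox.test(rho, mu = 0, alternative = "greater",
                               exact = FALSE, correct = FALSE)
      rsa[[rs$name]] <- list(mean_rho = mean(rho), p = wt$p.value)
    }
    report$roi_rsa_confidence <- rsa
  }
  if (have_regions && an$run_overlap) {
    rs1 <- cfg$region_specs[[1]]
    act <- lapply(pats, function(ps) ps$patterns[, ps$regions[[rs1$name]],
                                                 drop = FALSE])
    uc <- lapply(seq_along(pats), function(s) {
      lk <- ratings_lookup(ratings, s, cfg$goals)
      gi <- match(pats[[s]]$conditions$goal, cfg$goals)
      list(u = lk$U[cbind(pats[[s]]$conditions$item, gi)],
           c = lk$C[cbind(pats[[s]]$conditions$item, gi)])
    })
    ov <- overlap_test(act, lapply(uc, `[[`, "u"), lapply(uc, `[[`, "c"),
                       n_perm = an$n_perm_overlap, seed = cfg$seed)
    report$overlap <- list(region = rs1$name, mean_rho = mean(ov$rho),
                           z = ov$z_obs, p = ov$p, n_perm = ov$n_perm)
  }
  if (have_regions && an$run_xclass) {
    rows <- list()
    for (s in seq_along(pats)) for (rn in names(pats[[s]]$regions)) {
      r <- xclass_subject(pats[[s]], ratings, pats[[s]]$regions[[rn]],
                          goals = cfg$goals, k = an$cv_folds, seed = cfg$seed + s)
      r$region <- rn
      rows[[length(rows) + 1L]] <- r
    }
    outc <- do.call(rbind, rows)
    report$xclass <- list(group = xclass_group_stats(outc))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_table(ratings, file.path(out_dir, "ratings.tsv"))
    write_tsv_table(choices, file.path(out_dir, "choices.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
    ln <- c(paste("seed:", cfg$seed),
            paste("subjects:", cfg$n_subjects),
            paste("imagination %:", report$design$imagination_pct),
            paste("cross-goal r:", signif(r_cross, 3)),
            paste("quadratic beta:", signif(quad$beta, 3)))
    writeLines(ln, file.path(out_dir, "summary.txt"))
  }
  invisible(report)
}
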