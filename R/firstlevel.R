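# Simplified univariate GLM: canonical HRF, design construction with
# parametric modulators, per-voxel OLS, condition-wise (LSA) beta patterns.

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking near 6 s minus an
#' undershoot gamma peaking near 16 s at 1/6 amplitude, truncated at 32 s and
#' normalised to unit peak.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @return Numeric vector: the kernel sampled at `0, tr, 2*tr, ...`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  stopifnot(tr > 0)
  h <- function(t) stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  peak <- max(h(seq(0, duration, by = 0.01)))
  t <- seq(0, duration, by = tr)
  h(t) / peak
}

# Volumes x events matrix of HRF-convolved event regressors. Each event is a
# boxcar of its duration convolved with the canonical HRF on a microtime grid
# (dt), then sampled at the volume acquisition times.
convolve_events <- function(onsets, durations, tr, n_volumes, dt = tr / 16) {
  T_scan <- n_volumes * tr
  if (any(onsets < 0) || any(onsets >= T_scan))
    stop("event onset outside the scan (0 <= onset < ", T_scan, " s)")
  vol_t <- (seq_len(n_volumes) - 1) * tr
  hrf_len <- 32
  h <- canonical_hrf(dt, hrf_len)
  X <- matrix(0, n_volumes, length(onsets))
  templ <- new.env()
  for (e in seq_along(onsets)) {
    key <- format(durations[e], digits = 10)
    if (is.null(templ[[key]])) {
      n_u <- ceiling(durations[e] / dt)
      u <- rep(1, max(n_u, 1L))
      v <- dt * stats::convolve(u, rev(h), type = "open")
      templ[[key]] <- list(t = (seq_along(v) - 1) * dt, v = v)
    }
    tp <- templ[[key]]
    rel <- vol_t - onsets[e]
    inside <- rel >= 0 & rel <= max(tp$t)
    if (any(inside))
      X[inside, e] <- stats::approx(tp$t, tp$v, rel[inside], rule = 2)$y
  }
  X
}

#' Discrete-cosine drift basis
#'
#' High-pass drift regressors: the DCT basis functions with period longer
#' than `cutoff` seconds, excluding the constant. The column count equals
#' `floor(2 * n_volumes * tr / cutoff)`.
#'
#' @param n_volumes scan length in volumes.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @return Matrix `n_volumes` x K (K possibly 0).
#' @export
dct_basis <- function(n_volumes, tr, cutoff = 128) {
  K <- floor(2 * n_volumes * tr / cutoff)
  n <- n_volumes
  if (K < 1) return(matrix(0, n, 0))
  sapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)))
}

#' Build a first-level design matrix
#'
#' One HRF-convolved indicator regressor per event type; each parametric
#' modulator is mean-centred within its event type, multiplied into the
#' event amplitudes, then convolved (regressors are not orthogonalised and
#' compete for variance). Motion covariates are appended unconvolved,
#' followed by DCT drift regressors up to the high-pass cutoff and an
#' intercept.
#'
#' @param events data.frame with `onset`, `duration`, `trial_type`.
#' @param modulators optional named list: for each trial type, a data.frame /
#'   matrix of per-event modulator values (rows matching that type's events,
#'   in event order).
#' @param motion optional volumes x k matrix of motion covariates.
#' @param tr repetition time (s).
#' @param n_volumes scan length in volumes.
#' @param hp_cutoff high-pass cutoff period in seconds (default 128).
#' @return List of class `fl_design`: `X` (volumes x regressors), `labels`,
#'   `tr`, and `rank_deficient` flag.
#' @export
build_design_matrix <- function(events, modulators = NULL, motion = NULL,
                                tr, n_volumes, hp_cutoff = 128) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  types <- unique(events$trial_type)
  cols <- list(); labels <- character(0)
  for (ty in types) {
    ev <- events[events$trial_type == ty, ]
    Xe <- convolve_events(ev$onset, ev$duration, tr, n_volumes)
    cols[[length(cols) + 1L]] <- rowSums(Xe)
    labels <- c(labels, ty)
    mods <- modulators[[ty]]
    if (!is.null(mods)) {
      mods <- as.matrix(mods)
      if (nrow(mods) != nrow(ev))
        stop("modulator rows for '", ty, "' != event count")
      for (j in seq_len(ncol(mods))) {
        m <- mods[, j] - mean(mods[, j])
        cols[[length(cols) + 1L]] <- as.vector(Xe %*% m)
        labels <- c(labels, paste0(ty, ":", colnames(mods)[j] %||% paste0("mod", j)))
      }
    }
  }
  X <- do.call(cbind, cols)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) stop("motion rows != n_volumes")
    X <- cbind(X, motion)
    labels <- c(labels, paste0("motion", seq_len(ncol(motion))))
  }
  D <- dct_basis(n_volumes, tr, hp_cutoff)
  if (ncol(D)) {
    X <- cbind(X, D)
    labels <- c(labels, paste0("dct", seq_len(ncol(D))))
  }
  X <- cbind(X, 1)
  labels <- c(labels, "intercept")
  colnames(X) <- labels
  rk <- qr(X)$rank
  structure(list(X = X, labels = labels, tr = tr,
                 rank_deficient = rk < ncol(X)),
            class = "fl_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a mass-univariate OLS GLM
#'
#' @param bold numeric matrix, volumes x voxels.
#' @param design an `fl_design` (or a plain design matrix).
#' @param mask optional logical 3-D array matching the voxel columns (carried
#'   through to [contrast_map()] output geometry).
#' @param voxel_mm voxel size for the carried geometry.
#' @return List of class `glm_result`: `betas` (regressors x voxels),
#'   `residuals` (volumes x voxels), `sigma2`, `dof`, `XtXinv`, `labels`.
#' @export
fit_glm <- function(bold, design, mask = NULL, voxel_mm = 3) {
  X <- if (inherits(design, "fl_design")) design$X else as.matrix(design)
  labels <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(X)) stop("bold rows != design rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  betas <- qr.coef(qrX, bold)
  resid <- bold - X %*% betas
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  structure(list(betas = betas, residuals = resid, sigma2 = sigma2,
                 dof = dof, XtXinv = chol2inv(qr.R(qrX)), labels = labels,
                 mask = mask, voxel_mm = voxel_mm),
            class = "glm_result")
}

#' Per-voxel t-statistic for a contrast
#'
#' `t = c'b / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel.
#'
#' @param glm a `glm_result` from [fit_glm()].
#' @param weights contrast vector, length = regressor count.
#' @return A [stat_map()] when the GLM carries a mask, else a numeric vector.
#' @export
contrast_map <- function(glm, weights) {
  stopifnot(inherits(glm, "glm_result"))
  if (length(weights) != nrow(glm$betas))
    stop("contrast length != regressor count")
  cb <- as.vector(crossprod(weights, glm$betas))
  vc <- as.numeric(t(weights) %*% glm$XtXinv %*% weights)
  tv <- if (vc == 0) rep(0, length(cb)) else cb / sqrt(glm$sigma2 * vc)
  tv[cb == 0 & vc == 0] <- 0
  if (!is.null(glm$mask)) stat_map(tv, glm$mask, glm$voxel_mm) else tv
}

#' Condition-wise beta patterns (least-squares-all)
#'
#' Fits one GLM over the concatenated sessions with a dedicated HRF-convolved
#' regressor per (item, goal) condition — exact here because every condition
#' occurs once — plus per-session choice indicator, motion, DCT drift and
#' intercept nuisances. Returns the condition betas as a [pattern_set()] with
#' the GLM residuals attached for prewhitening.
#'
#' @param bold_run output of [generate_bold()] (or a list with the same
#'   `sessions`/`mask`/`tr` layout).
#' @param hp_cutoff high-pass cutoff in seconds.
#' @return A [pattern_set()]; conditions ordered item-within-goal.
#' @export
fit_condition_betas <- function(bold_run, hp_cutoff = 128) {
  sess <- bold_run$sessions
  tr <- bold_run$tr
  conds <- NULL
  Xs <- list(); Ys <- list(); Ns <- list()
  for (si in seq_along(sess)) {
    ev <- sess[[si]]$events
    imag <- ev[ev$trial_type == "imagination", ]
    key <- paste(imag$item, imag$goal)
    if (anyDuplicated(key))
      stop("duplicated condition labels in session ", si)
    n_vol <- nrow(sess[[si]]$bold)
    Xe <- convolve_events(imag$onset, imag$duration, tr, n_vol)
    colnames(Xe) <- key
    ch <- ev[ev$trial_type == "choice", ]
    nuis <- cbind(
      choice = if (nrow(ch)) rowSums(convolve_events(ch$onset, ch$duration,
                                                     tr, n_vol)) else NULL,
      sess[[si]]$motion, dct_basis(n_vol, tr, hp_cutoff), 1)
    Xs[[si]] <- Xe; Ns[[si]] <- nuis; Ys[[si]] <- sess[[si]]$bold
    conds <- rbind(conds, data.frame(item = imag$item, goal = imag$goal,
                                     stringsAsFactors = FALSE))
  }
  n_tot <- sum(vapply(Ys, nrow, 0L))
  all_keys <- unlist(lapply(Xs, colnames))
  if (anyDuplicated(all_keys))
    stop("condition repeated across sessions: LSA expects one event each")
  # block-assemble: condition columns + per-session nuisance blocks
  p_cond <- length(all_keys)
  p_nuis <- sum(vapply(Ns, ncol, 0L))
  X <- matrix(0, n_tot, p_cond + p_nuis)
  Y <- do.call(rbind, Ys)
  row0 <- 0L; c_cond <- 0L; c_nuis <- p_cond
  for (si in seq_along(Ys)) {
    nr <- nrow(Ys[[si]])
    X[row0 + seq_len(nr), c_cond + seq_len(ncol(Xs[[si]]))] <- Xs[[si]]
    X[row0 + seq_len(nr), c_nuis + seq_len(ncol(Ns[[si]]))] <- Ns[[si]]
    row0 <- row0 + nr; c_cond <- c_cond + ncol(Xs[[si]])
    c_nuis <- c_nuis + ncol(Ns[[si]])
  }
  colnames(X) <- c(all_keys, paste0("nuis", seq_len(p_nuis)))
  fit <- fit_glm(Y, X)
  ord <- order(match(conds$goal, unique(conds$goal)), conds$item)
  pattern_set(fit$betas[seq_len(p_cond), , drop = FALSE][ord, , drop = FALSE],
              conds[ord, ], bold_run$mask, voxel_mm = bold_run$voxel_mm,
              residuals = fit$residuals)
}
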