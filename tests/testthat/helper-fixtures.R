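# Shared fixtures and independent brute-force oracles.

# small, fast study config: 24 items over 2 sessions (12 imagination + 6
# choice per session), one planted region
tiny_cfg <- function(..., n_subjects = 3, n_items = 24, seed = 101,
                     n_volumes = 70) {
  sim_config(n_subjects = n_subjects, n_items = n_items,
             n_sessions = 2, imagination_per_session = n_items,
             choice_per_session = 6, choice_window = 5,
             n_volumes = n_volumes, grid_dim = c(10L, 10L, 10L),
             region_specs = list(region_spec("roi", n_voxels = 30)),
             seed = seed, ...)
}

# --- independent oracles -------------------------------------------------

# Pearson dissimilarity by the explicit double loop over the textbook formula
oracle_pearson_rdm <- function(P) {
  n <- nrow(P)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- P[i, ]; y <- P[j, ]
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    d[i, j] <- 1 - num / den
  }
  diag(d) <- 0
  d
}

# Spearman rho from first principles: Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# enumeration of integer offsets in a mm-radius ball
oracle_sphere_count <- function(radius_mm, voxel_mm) {
  r <- ceiling(radius_mm / voxel_mm) + 1
  cnt <- 0L
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if ((x^2 + y^2 + z^2) * voxel_mm^2 <= radius_mm^2 + 1e-9) cnt <- cnt + 1L
  cnt
}

# per-voxel GLM t statistic via the two-step residual form, one voxel at a
# time with plain lm()
oracle_contrast_t <- function(Y, X, w) {
  vapply(seq_len(ncol(Y)), function(v) {
    fit <- stats::lm(Y[, v] ~ X - 1)
    b <- stats::coef(fit)
    s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
    as.numeric(crossprod(w, b)) /
      sqrt(s2 * as.numeric(t(w) %*% solve(crossprod(X)) %*% w))
  }, 0)
}

# brute-force DCT basis: all cosines with frequency below the cutoff
oracle_dct_count <- function(n_volumes, tr, cutoff) {
  T_total <- n_volumes * tr
  k <- 1L; cnt <- 0L
  repeat {
    # basis function k has period 2*T/k; keep while period > cutoff... i.e.
    # frequency k/(2T) <= 1/cutoff
    if (k / (2 * T_total) <= 1 / cutoff) cnt <- cnt + 1L else break
    k <- k + 1L
  }
  cnt
}

# condition labels for n items x 2 goals
cond_df <- function(n_items, goals = c("burning", "anchoring")) {
  data.frame(item = rep(seq_len(n_items), 2),
             goal = rep(goals, each = n_items))
}
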