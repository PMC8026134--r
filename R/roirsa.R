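# ROI-based RSA and the usefulness/confidence participation-vector overlap.

#' Spherical region-of-interest specification
#'
#' @param name ROI label.
#' @param center_mm numeric length-3 centre in millimetres (grid coordinates:
#'   voxel (1,1,1) sits at 0 mm on each axis).
#' @param radius_mm sphere radius (default 10 mm).
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(name, center_mm, radius_mm = 10) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm), class = "roi_spec")
}

#' Resolve an ROI to pattern-set voxel columns
#'
#' Intersects the sphere with the pattern mask and returns the column indices
#' of the in-sphere voxels.
#'
#' @param roi a [roi_spec()].
#' @param ps a [pattern_set()].
#' @return Integer vector of voxel column indices.
#' @export
resolve_roi <- function(roi, ps) {
  stopifnot(inherits(roi, "roi_spec"), inherits(ps, "pattern_set"))
  co <- mask_coords(ps$mask)
  mm <- (co - 1) * ps$voxel_mm
  d2 <- (mm[, 1] - roi$center_mm[1])^2 + (mm[, 2] - roi$center_mm[2])^2 +
    (mm[, 3] - roi$center_mm[3])^2
  cols <- which(d2 <= roi$radius_mm^2 + 1e-9)
  if (!length(cols))
    stop("ROI '", roi$name, "' is empty after mask intersection")
  cols
}

#' Group-level ROI RSA
#'
#' Per subject: prewhiten the condition patterns within the ROI, build the
#' brain RDM (1 - Pearson) and compute its Spearman correlation with the
#' model RDM. The subject rho values are tested against zero with a
#' one-sided Wilcoxon signed-rank test.
#'
#' @param pattern_sets list of [pattern_set()]s, one per subject.
#' @param roi a [roi_spec()], or an integer vector of voxel columns applied
#'   to every subject, or a list of per-subject column vectors.
#' @param model an [rdm()].
#' @param prewhiten whiten patterns within the ROI first (default TRUE).
#' @return List: `rho` per subject, `p` (one-sided Wilcoxon), `statistic`.
#' @export
roi_rsa_group <- function(pattern_sets, roi, model, prewhiten = TRUE) {
  n <- length(pattern_sets)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    ps <- pattern_sets[[i]]
    cols <- if (inherits(roi, "roi_spec")) resolve_roi(roi, ps)
    else if (is.list(roi)) roi[[i]] else roi
    P <- ps$patterns[, cols, drop = FALSE]
    if (prewhiten) {
      if (is.null(ps$residuals)) stop("prewhitening needs residuals")
      P <- prewhiten(P, residuals = ps$residuals[, cols, drop = FALSE])
    }
    rho[i] <- compare_rdms(brain_rdm(P, conditions = ps$conditions), model)
  }
  wt <- stats::wilcox.test(rho, mu = 0, alternative = "greater",
                           exact = FALSE, correct = FALSE)
  list(rho = rho, p = wt$p.value, statistic = unname(wt$statistic))
}

#' Voxel participation vectors
#'
#' For each voxel, the trial-by-trial activity is regressed separately
#' against the usefulness and the confidence of the presented items; the
#' absolute slopes form the usefulness and confidence participation vectors
#' B_U and B_C. `bivariate = TRUE` instead takes the two coefficients from
#' one joint regression on both predictors.
#'
#' @param activity trials x voxels matrix.
#' @param usefulness,confidence numeric per trial.
#' @param bivariate use one bivariate regression instead of two simple ones.
#' @return List with vectors `B_U` and `B_C` (entries >= 0).
#' @export
participation_vectors <- function(activity, usefulness, confidence,
                                  bivariate = FALSE) {
  activity <- as.matrix(activity)
  n <- nrow(activity)
  if (n < 3) stop("need at least 3 trials")
  if (length(usefulness) != n || length(confidence) != n)
    stop("predictor length != trial count")
  if (stats::sd(usefulness) == 0 || stats::sd(confidence) == 0)
    stop("constant predictor")
  ac <- sweep(activity, 2, colMeans(activity))
  if (!bivariate) {
    uc <- usefulness - mean(usefulness)
    cc <- confidence - mean(confidence)
    bU <- as.vector(crossprod(ac, uc)) / sum(uc^2)
    bC <- as.vector(crossprod(ac, cc)) / sum(cc^2)
  } else {
    X <- cbind(usefulness - mean(usefulness), confidence - mean(confidence))
    B <- solve(crossprod(X), crossprod(X, ac))
    bU <- B[1, ]; bC <- B[2, ]
  }
  list(B_U = abs(bU), B_C = abs(bC))
}

# Wilcoxon signed-rank z statistic of a vector against 0 (normal
# approximation, average ranks, zeros dropped)
wilcoxon_z <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(0)
  r <- rank(abs(x))
  vplus <- sum(r[x > 0])
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  (vplus - mu) / sigma
}

#' Usefulness/confidence neural-overlap permutation test
#'
#' Per subject, computes the Spearman correlation between the usefulness and
#' confidence participation vectors; the group statistic is the Wilcoxon
#' signed-rank z of the subject correlations against zero. The null is built
#' by recomputing the confidence participation vector after permuting the
#' confidence trial labels within each subject (`scheme = "trial"`, default)
#' or by permuting the voxel labels of B_C (`scheme = "voxel"`), and the
#' two-sided p-value is the +1-corrected fraction of permutations with
#' |z| at least the observed |z|.
#'
#' @param activity list of trials x voxels matrices, one per subject.
#' @param usefulness,confidence lists of per-trial predictor vectors.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param scheme permutation scheme (see above).
#' @param bivariate passed to [participation_vectors()].
#' @return List: `rho` per subject, `z_obs`, `p`, `n_perm`, `scheme`.
#' @export
overlap_test <- function(activity, usefulness, confidence, n_perm = 10000,
                         seed = 1L, scheme = c("trial", "voxel"),
                         bivariate = FALSE) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  n_sub <- length(activity)
  if (n_sub < 2) stop("need at least 2 subjects")
  pv <- vector("list", n_sub)
  for (s in seq_len(n_sub))
    pv[[s]] <- participation_vectors(activity[[s]], usefulness[[s]],
                                     confidence[[s]], bivariate = bivariate)
  rho <- vapply(pv, function(p)
    stats::cor(p$B_U, p$B_C, method = "spearman"), 0)
  z_obs <- wilcoxon_z(rho)
  with_stream(seed, 7L, {
    z_null <- numeric(n_perm)
    # precompute per-subject pieces for the trial scheme
    prep <- lapply(seq_len(n_sub), function(s) {
      A <- as.matrix(activity[[s]])
      list(ac = sweep(A, 2, colMeans(A)),
           rBU = rank(pv[[s]]$B_U),
           conf = confidence[[s]], use = usefulness[[s]])
    })
    for (p in seq_len(n_perm)) {
      rho_p <- numeric(n_sub)
      for (s in seq_len(n_sub)) {
        if (scheme == "trial") {
          cp <- sample(prep[[s]]$conf)
          if (bivariate) {
            bC <- participation_vectors(activity[[s]], prep[[s]]$use, cp,
                                        bivariate = TRUE)$B_C
          } else {
            cc <- cp - mean(cp)
            bC <- abs(as.vector(crossprod(prep[[s]]$ac, cc)) / sum(cc^2))
          }
          rho_p[s] <- stats::cor(prep[[s]]$rBU, rank(bC))
        } else {
          rho_p[s] <- stats::cor(prep[[s]]$rBU, rank(sample(pv[[s]]$B_C)))
        }
      }
      z_null[p] <- wilcoxon_z(rho_p)
    }
    p_val <- (1 + sum(abs(z_null) >= abs(z_obs))) / (n_perm + 1)
    list(rho = rho, z_obs = z_obs, p = p_val, n_perm = n_perm,
         scheme = scheme)
  })
}
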