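# Representational dissimilarity matrices: model RDMs, prewhitened brain
# RDMs (1 - Pearson), and their second-order Spearman comparison.

#' Construct an RDM
#'
#' A symmetric condition x condition dissimilarity matrix with a zero
#' diagonal, labelled by (item, goal) conditions, an optional cell validity
#' mask, and a metric tag.
#'
#' @param d symmetric numeric matrix with zero diagonal.
#' @param conditions data.frame with `item`, `goal` (one row per condition).
#' @param cell_mask symmetric logical matrix: which cells may enter
#'   comparisons (default: all).
#' @param metric character tag ("1-pearson", "abs_diff", "euclidean",
#'   "identity", ...).
#' @return An object of class `rdm`.
#' @export
rdm <- function(d, conditions, cell_mask = NULL, metric = "custom") {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("RDM must be square")
  if (nrow(conditions) != n) stop("conditions rows != RDM size")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8) stop("RDM must be symmetric")
  if (any(abs(diag(d)) > 1e-8, na.rm = TRUE)) stop("RDM diagonal must be zero")
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, n, n)
  if (!identical(dim(cell_mask), dim(d))) stop("cell_mask shape mismatch")
  if (!isTRUE(all(cell_mask == t(cell_mask)))) stop("cell_mask must be symmetric")
  structure(list(d = d, conditions = as.data.frame(conditions),
                 cell_mask = cell_mask, metric = metric), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  n <- nrow(x$d)
  lt <- lower.tri(x$d)
  cat("rdm:", n, "x", n, "conditions, metric =", x$metric, "\n")
  cat("  valid lower-triangle cells:", sum(x$cell_mask[lt]), "/", sum(lt), "\n")
  vals <- x$d[lt & x$cell_mask]
  if (length(vals))
    cat("  dissimilarity range:", format(range(vals), digits = 4), "\n")
  invisible(x)
}

#' Item-identity model RDM
#'
#' Kronecker-delta dissimilarity on items: 0 between any two presentations of
#' the same item (including across goals), 1 otherwise.
#'
#' @param conditions data.frame with `item`, `goal`.
#' @return An [rdm()] with metric `"identity"`.
#' @export
model_identity <- function(conditions) {
  if (!nrow(conditions)) stop("empty condition list")
  same <- outer(conditions$item, conditions$item, "==")
  d <- 1 - same * 1
  diag(d) <- 0
  rdm(d, conditions, metric = "identity")
}

#' Value-difference model RDM
#'
#' Dissimilarity = absolute difference of a per-condition scalar (congruent
#' usefulness by default; pass confidence or monetary values for those
#' variants).
#'
#' @param values numeric, one value per condition (no NAs).
#' @param conditions data.frame with `item`, `goal`.
#' @return An [rdm()] with metric `"abs_diff"`.
#' @export
model_value <- function(values, conditions) {
  if (length(values) != nrow(conditions)) stop("one value per condition required")
  if (anyNA(values)) stop("missing value for condition(s) ",
                          paste(which(is.na(values)), collapse = ", "))
  d <- abs(outer(values, values, "-"))
  rdm(d, conditions, metric = "abs_diff")
}

#' Material-composition model RDM
#'
#' Euclidean distance between the items' 4-component material compositions
#' (wood, metal, plastic, fabric). Cells pairing the same item across goals
#' are masked out, which approximately orthogonalises this model against the
#' item-identity model.
#'
#' @param compositions matrix/data.frame items x 4, rows on the simplex
#'   (nonnegative, sum 1), row i = item i.
#' @param conditions data.frame with `item`, `goal`.
#' @return An [rdm()] with metric `"euclidean"` and same-item cross-goal
#'   cells masked.
#' @export
model_material <- function(compositions, conditions) {
  compositions <- as.matrix(compositions)
  if (ncol(compositions) != 4) stop("compositions must have 4 components")
  if (any(compositions < -1e-9) ||
      any(abs(rowSums(compositions) - 1) > 1e-6))
    stop("compositions must lie on the 4-simplex (nonnegative, sum to 1)")
  ci <- conditions$item
  if (max(ci) > nrow(compositions)) stop("composition missing for some items")
  cm <- compositions[ci, , drop = FALSE]
  g <- rowSums(cm^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(cm)
  d <- sqrt(pmax(d2, 0))
  same_item <- outer(ci, ci, "==")
  mask <- !(same_item & !diag(nrow(d)))   # drop same-item off-diagonal cells
  d[same_item] <- 0                        # exact zeros, incl. masked cells
  rdm(d, conditions, cell_mask = mask, metric = "euclidean")
}

# Analytic shrinkage intensity toward the diagonal (Schafer-Strimmer):
# lambda* = sum Var(s_ij) / sum s_ij^2 over i != j, clamped to [0, 1].
shrinkage_cov <- function(resid) {
  n <- nrow(resid)
  xc <- sweep(resid, 2, colMeans(resid))
  S <- crossprod(xc) / (n - 1)
  # Var-hat of off-diagonal entries
  W <- array(0, dim(S))
  for (k in seq_len(n)) W <- W + (tcrossprod(xc[k, ]) - S)^2
  VarS <- W * n / ((n - 1)^3)
  off <- !diag(nrow(S))
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(VarS[off]) / denom)) else 1
  Sh <- (1 - lambda) * S
  diag(Sh) <- diag(S)
  list(sigma = Sh, lambda = lambda)
}

#' Spatially prewhiten condition patterns
#'
#' Multivariate noise normalisation: transforms patterns by the inverse
#' square root of the shrinkage-regularised residual covariance across
#' voxels, equalising and decorrelating the voxel noise. The shrinkage
#' target is the diagonal of the sample covariance with analytic intensity.
#'
#' @param ps a [pattern_set()] with residual samples attached, or a plain
#'   matrix of patterns together with `residuals`.
#' @param residuals residual matrix (samples x voxels) when `ps` is a matrix.
#' @return The same type as `ps`, with whitened patterns (and whitened
#'   residuals in the `pattern_set` case).
#' @export
prewhiten <- function(ps, residuals = NULL) {
  is_set <- inherits(ps, "pattern_set")
  P <- if (is_set) ps$patterns else as.matrix(ps)
  R <- if (is_set) ps$residuals else residuals
  if (is.null(R) || nrow(R) < 2)
    stop("prewhitening needs at least 2 residual samples")
  sc <- shrinkage_cov(R)
  eg <- eigen(sc$sigma, symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-10)
  Wm <- eg$vectors %*% (t(eg$vectors) / sqrt(ev))
  Pw <- P %*% Wm
  if (!is_set) return(Pw)
  out <- ps
  out$patterns <- Pw
  out$residuals <- R %*% Wm
  out$whitened <- TRUE
  out
}

#' Brain RDM: 1 - Pearson correlation distance
#'
#' Pairwise dissimilarity `d = 1 - r` between condition patterns over a voxel
#' subset. Conditions with constant patterns get `d = 0` on the diagonal and
#' their off-diagonal cells flagged invalid in the cell mask.
#'
#' @param ps a [pattern_set()] or a conditions x voxels matrix.
#' @param voxels optional column indices selecting the voxel subset.
#' @param conditions condition data.frame when `ps` is a matrix.
#' @return An [rdm()] with metric `"1-pearson"` (values in [0, 2]).
#' @export
brain_rdm <- function(ps, voxels = NULL, conditions = NULL) {
  if (inherits(ps, "pattern_set")) {
    P <- ps$patterns; conditions <- ps$conditions
  } else P <- as.matrix(ps)
  if (is.null(conditions))
    stop("conditions required when patterns are a plain matrix")
  if (!is.null(voxels)) P <- P[, voxels, drop = FALSE]
  if (ncol(P) < 2) stop("need at least 2 voxels")
  sds <- apply(P, 1, stats::sd)
  ok <- sds > 0
  n <- nrow(P)
  d <- matrix(0, n, n)
  if (sum(ok) >= 2) {
    r <- stats::cor(t(P[ok, , drop = FALSE]))
    d[ok, ok] <- 1 - r
  }
  mask <- outer(ok, ok, "&")
  diag(mask) <- TRUE
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rdm(d, conditions, cell_mask = mask, metric = "1-pearson")
}

#' Compare brain and model RDMs (second-order Spearman)
#'
#' Spearman rank correlation (average-rank ties) between the two RDMs'
#' dissimilarities over the strict lower triangle, restricted to the
#' intersection of both cell masks.
#'
#' @param brain,model [rdm()] objects with identical condition ordering.
#' @return Spearman's rho (scalar).
#' @export
compare_rdms <- function(brain, model) {
  stopifnot(inherits(brain, "rdm"), inherits(model, "rdm"))
  if (nrow(brain$d) != nrow(model$d) ||
      !identical(paste(brain$conditions$item, brain$conditions$goal),
                 paste(model$conditions$item, model$conditions$goal)))
    stop("condition ordering differs between the two RDMs")
  keep <- lower.tri(brain$d) & brain$cell_mask & model$cell_mask
  if (sum(keep) < 3) stop("fewer than 3 unmasked cells to compare")
  stats::cor(brain$d[keep], model$d[keep], method = "spearman")
}
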