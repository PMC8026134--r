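# Volumetric searchlight RSA and group-level sign-flip cluster permutation.

#' Construct a 3-D statistic map
#'
#' @param values numeric: either a 3-D array matching `mask`, or a vector of
#'   length `sum(mask)` (mask linear order) which is embedded into the grid
#'   with `NA` outside.
#' @param mask logical 3-D array of valid voxels.
#' @param voxel_mm isotropic voxel size (mm).
#' @return An object of class `stat_map`: `values` (3-D array, `NA` outside
#'   the validity mask), `mask`, `voxel_mm`.
#' @export
stat_map <- function(values, mask, voxel_mm = 3) {
  if (is.array(values) && length(dim(values)) == 3) {
    if (!identical(dim(values), dim(mask))) stop("values/mask shape mismatch")
    arr <- values
    arr[!mask] <- NA_real_
  } else {
    if (length(values) != sum(mask))
      stop("value count != mask voxel count")
    arr <- array(NA_real_, dim(mask))
    arr[mask] <- values
  }
  valid <- mask & !is.na(arr)
  if (any(!is.finite(arr[valid]))) stop("non-finite values inside the mask")
  structure(list(values = arr, mask = valid, voxel_mm = voxel_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map:", paste(dim(x$values), collapse = "x"), "grid,",
      sum(x$mask), "valid voxels,", x$voxel_mm, "mm\n")
  if (sum(x$mask))
    cat("  range:", format(range(x$values[x$mask]), digits = 4), "\n")
  invisible(x)
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer voxel offsets whose Euclidean norm in millimetres does not
#' exceed `radius_mm`; the centre (0,0,0) is always included.
#'
#' @param radius_mm sphere radius in mm (>= 0).
#' @param voxel_mm isotropic voxel size in mm.
#' @return Integer matrix, offsets x 3.
#' @export
sphere_offsets <- function(radius_mm, voxel_mm) {
  stopifnot(radius_mm >= 0, voxel_mm > 0)
  r <- floor(radius_mm / voxel_mm)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- (g[, 1]^2 + g[, 2]^2 + g[, 3]^2) * voxel_mm^2 <= radius_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

#' Searchlight RSA map
#'
#' For every valid voxel of the mask: take the in-mask voxels of the sphere
#' centred there, build the brain RDM (1 - Pearson) over them, and assign the
#' Spearman correlation with the model RDM to the centre. Centres whose
#' sphere retains fewer than `min_voxels` in-mask voxels are marked invalid.
#'
#' @param ps a [pattern_set()].
#' @param model an [rdm()] with the same condition ordering.
#' @param radius_mm searchlight radius (default 9 mm).
#' @param min_voxels minimum sphere size for a valid centre (default 10).
#' @param mask optional logical 3-D array restricting the analysis (e.g. a
#'   gray-matter mask); defaults to the pattern mask.
#' @return A [stat_map()] of Spearman rho values.
#' @export
searchlight_map <- function(ps, model, radius_mm = 9, min_voxels = 10,
                            mask = NULL) {
  stopifnot(inherits(ps, "pattern_set"), inherits(model, "rdm"))
  if (!identical(paste(ps$conditions$item, ps$conditions$goal),
                 paste(model$conditions$item, model$conditions$goal)))
    stop("model/pattern condition labels mismatch")
  if (is.null(mask)) mask <- ps$mask
  if (!identical(dim(mask), dim(ps$mask))) stop("mask shape mismatch")
  mask <- mask & ps$mask
  dims <- dim(mask)
  off <- sphere_offsets(radius_mm, ps$voxel_mm)
  centers <- which(mask, arr.ind = TRUE)
  lin_in_mask <- which(ps$mask)            # pattern column lookup
  col_of <- array(NA_integer_, dims)
  col_of[lin_in_mask] <- seq_along(lin_in_mask)
  lt <- lower.tri(model$d) & model$cell_mask
  model_rank <- rank(model$d[lt])
  vals <- rep(NA_real_, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] + off[, 1]
    cy <- centers[i, 2] + off[, 2]
    cz <- centers[i, 3] + off[, 3]
    ok <- cx >= 1 & cx <= dims[1] & cy >= 1 & cy <= dims[2] &
      cz >= 1 & cz <= dims[3]
    cols <- col_of[cbind(cx[ok], cy[ok], cz[ok])]
    cols <- cols[!is.na(cols)]
    if (length(cols) < min_voxels) next
    P <- ps$patterns[, cols, drop = FALSE]
    sds <- apply(P, 1, stats::sd)
    if (any(sds == 0)) {                    # fall back to masked comparison
      b <- brain_rdm(P, conditions = ps$conditions)
      vals[i] <- tryCatch(compare_rdms(b, model), error = function(e) NA_real_)
    } else {
      bd <- 1 - stats::cor(t(P))
      vals[i] <- stats::cor(rank(bd[lt]), model_rank)
    }
  }
  arr <- array(NA_real_, dims)
  arr[cbind(centers)] <- vals
  stat_map(arr, mask & !is.na(arr), ps$voxel_mm)
}

# 1-D Gaussian kernel for a given FWHM in voxels
gauss_kernel_1d <- function(fwhm_vox) {
  sd <- fwhm_vox / (2 * sqrt(2 * log(2)))
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k / sum(k)
}

# separable 1-D convolution of a 3-D array along one axis (zero padding)
conv_axis <- function(a, k, axis) {
  if (length(k) == 1) return(a * k)
  r <- (length(k) - 1) / 2
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    sh <- j - 1 - r
    idx_src <- max(1, 1 - sh):min(dim(a)[axis], dim(a)[axis] - sh)
    idx_dst <- idx_src + sh
    src <- switch(axis,
                  a[idx_src, , , drop = FALSE],
                  a[, idx_src, , drop = FALSE],
                  a[, , idx_src, drop = FALSE])
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * src
    else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * src
    else out[, , idx_dst] <- out[, , idx_dst] + k[j] * src
  }
  out
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian smoothing with the kernel width given as full width at
#' half maximum in millimetres. Invalid voxels are excluded by
#' mask-normalised convolution (smooth(values*mask) / smooth(mask)), so a
#' constant map stays constant and values never bleed across the mask edge.
#'
#' @param map a [stat_map()].
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @return A smoothed [stat_map()] on the same mask.
#' @export
smooth_map <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "stat_map"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(map)
  k <- gauss_kernel_1d(fwhm_mm / map$voxel_mm)
  v <- map$values
  v[!map$mask] <- 0
  m <- array(0, dim(v)); m[map$mask] <- 1
  for (ax in 1:3) {
    v <- conv_axis(v, k, ax)
    m <- conv_axis(m, k, ax)
  }
  out <- array(NA_real_, dim(v))
  out[map$mask] <- v[map$mask] / m[map$mask]
  stat_map(out, map$mask, map$voxel_mm)
}

# connected components (6-connectivity) of a logical 3-D array; returns a
# list of integer-vector linear indices, one per cluster
connected_clusters <- function(flag) {
  dims <- dim(flag)
  idx <- which(flag)
  if (!length(idx)) return(list())
  lab <- array(0L, dims)
  lab[idx] <- -1L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  coord <- which(flag, arr.ind = TRUE)
  rownames(coord) <- NULL
  pos <- stats::setNames(seq_along(idx), idx)
  clusters <- list(); nc <- 0L
  for (start in idx) {
    if (lab[start] != -1L) next
    nc <- nc + 1L
    queue <- start; lab[start] <- nc
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      vc <- coord[pos[[as.character(v)]], ]
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb_c <- vc; nb_c[ax] <- nb_c[ax] + s
        if (nb_c[ax] < 1 || nb_c[ax] > dims[ax]) next
        nb <- v + s * strides[ax]
        if (lab[nb] == -1L) { lab[nb] <- nc; queue <- c(queue, nb) }
      }
    }
    clusters[[nc]] <- members
  }
  clusters
}

# one-sample t values for rows-of-signs x subject-map matrix; X is
# subjects x voxels, S is n_perm x subjects (+-1). Uses the sign-flip
# identity: sum x_i^2 is flip-invariant.
sign_flip_t <- function(X, S) {
  n <- nrow(X)
  M <- (S %*% X) / n
  ss <- colSums(X^2)
  varm <- sweep(-M^2 * n, 2, ss, "+") / (n - 1)
  varm[varm < 0] <- 0
  M / sqrt(varm / n)
}

#' Group-level cluster permutation test (sign flipping)
#'
#' One-sample t test across subjects at every voxel, thresholded at the
#' cluster-defining threshold (one-sided, positive); observed suprathreshold
#' clusters (6-connectivity) are assigned family-wise-error p-values against
#' the permutation null of the maximum cluster size obtained by randomly
#' sign-flipping whole subject maps. When `2^n_subjects <= n_perm` the full
#' sign-flip set is enumerated exactly.
#'
#' @param subject_maps list of [stat_map()]s on a common grid, one per
#'   subject.
#' @param cdt_p cluster-defining threshold as an upper-tail p (default 0.001).
#' @param n_perm number of random sign flips (default 5000).
#' @param seed integer seed for the flips.
#' @return An object of class `cluster_report`: data.frame `clusters` (size,
#'   peak value, peak coordinates, FWE p), the group t [stat_map()], the
#'   threshold used, `n_perm`, `exact` flag, and `seed`.
#' @export
cluster_permutation_test <- function(subject_maps, cdt_p = 0.001,
                                     n_perm = 5000, seed = 1L) {
  n <- length(subject_maps)
  if (n < 2) stop("need at least 2 subject maps")
  if (n < 8) warning("fewer than 8 subjects: permutation null is coarse")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  dims <- dim(subject_maps[[1]]$values)
  mask <- Reduce(`&`, lapply(subject_maps, `[[`, "mask"))
  for (m in subject_maps)
    if (!identical(dim(m$values), dims)) stop("subject maps on different grids")
  X <- do.call(rbind, lapply(subject_maps, function(m) m$values[mask]))
  tcrit <- stats::qt(1 - cdt_p, df = n - 1)
  lin_idx <- which(mask)
  exact <- 2^n <= n_perm
  S <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  Tm <- sign_flip_t(X, S)
  max_null <- apply(Tm, 1, function(tv) {
    hit <- tv > tcrit
    if (!any(hit)) return(0L)
    flag <- array(FALSE, dims)
    flag[lin_idx[hit]] <- TRUE
    max(lengths(connected_clusters(flag)))
  })
  t_obs <- as.vector(sign_flip_t(X, matrix(1, 1, n)))
  flag <- array(FALSE, dims)
  flag[lin_idx[t_obs > tcrit]] <- TRUE
  cl <- connected_clusters(flag)
  t_arr <- array(NA_real_, dims); t_arr[lin_idx] <- t_obs
  rows <- lapply(cl, function(mem) {
    pk <- mem[which.max(t_arr[mem])]
    pc <- arrayInd(pk, dims)
    if (exact) p <- mean(max_null >= length(mem))
    else p <- (1 + sum(max_null >= length(mem))) / (n_perm + 1)
    data.frame(size = length(mem), peak_t = t_arr[pk],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3], p_fwe = p)
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(0), peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0), p_fwe = numeric(0))
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  structure(list(clusters = clusters, members = cl,
                 t_map = stat_map(t_arr, mask,
                                  subject_maps[[1]]$voxel_mm),
                 cdt_p = cdt_p, t_threshold = tcrit,
                 n_perm = if (exact) nrow(S) else n_perm,
                 exact = exact, seed = seed),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster permutation test: CDT p <", x$cdt_p, "(t >",
      round(x$t_threshold, 3), "),",
      if (x$exact) "exact enumeration of" else "", x$n_perm,
      "sign flips\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("  no suprathreshold clusters\n")
  invisible(x)
}
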