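# Container for per-subject condition beta patterns on a masked voxel grid.

#' Construct a condition pattern set
#'
#' Holds one multivoxel beta pattern per experimental condition (item x goal)
#' over the in-mask voxels of a 3-D grid, together with the grid geometry and
#' optional noise residual samples used for prewhitening. Voxels are ordered
#' by their linear (column-major) index within the mask.
#'
#' @param patterns numeric matrix, conditions x in-mask voxels.
#' @param conditions data.frame with columns `item` and `goal`, one row per
#'   pattern row.
#' @param mask logical 3-D array; `sum(mask)` must equal `ncol(patterns)`.
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param residuals optional matrix (samples x voxels) of noise residuals.
#' @param regions optional named list of voxel column indices (planted-region
#'   bookkeeping for synthetic data).
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(patterns, conditions, mask, voxel_mm = 3,
                        residuals = NULL, regions = NULL) {
  patterns <- as.matrix(patterns)
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("mask must be a logical 3-D array")
  if (sum(mask) != ncol(patterns))
    stop("mask voxel count (", sum(mask), ") != pattern columns (",
         ncol(patterns), ")")
  if (nrow(conditions) != nrow(patterns))
    stop("conditions rows != pattern rows")
  if (!all(c("item", "goal") %in% names(conditions)))
    stop("conditions needs 'item' and 'goal' columns")
  if (anyDuplicated(conditions[c("item", "goal")]))
    stop("duplicated (item, goal) conditions")
  if (!all(is.finite(patterns))) stop("patterns contain non-finite values")
  if (!is.null(residuals)) {
    residuals <- as.matrix(residuals)
    if (ncol(residuals) != ncol(patterns))
      stop("residual columns != pattern columns")
  }
  structure(list(patterns = patterns,
                 conditions = as.data.frame(conditions),
                 mask = mask, voxel_mm = voxel_mm,
                 residuals = residuals, regions = regions),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("pattern_set:", nrow(x$patterns), "conditions x", ncol(x$patterns),
      "voxels on a", paste(dim(x$mask), collapse = "x"), "grid (",
      x$voxel_mm, "mm )\n")
  if (!is.null(x$residuals))
    cat("  ", nrow(x$residuals), "residual samples attached\n")
  if (!is.null(x$regions))
    cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}

# integer voxel coordinates (n x 3) of the in-mask voxels, mask linear order
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# columns of the pattern matrix belonging to a set of grid linear indices
mask_columns <- function(mask, lin_idx) {
  pos <- match(lin_idx, which(mask))
  if (anyNA(pos)) stop("some voxels are outside the mask")
  pos
}
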