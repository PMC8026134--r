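# Cross-goal generalisation of the usefulness code: subject-level quartile
# split, linear SVM training, within-goal cross-validated accuracy and
# cross-goal transfer accuracy, and the group statistics.

#' Quartile split into high- and low-value items
#'
#' Retains the items in the highest and lowest value quartile and drops the
#' middle half. Items are ordered by value with item id as a stable
#' tie-break, and the bottom and top `floor(n/4)` items are taken, so the two
#' groups are always equal-sized and deterministic under ties.
#'
#' @param values numeric, one value per item.
#' @param items item ids (default `seq_along(values)`).
#' @return data.frame `item`, `value`, `label` (factor low/high) for the
#'   retained items.
#' @export
split_high_low <- function(values, items = seq_along(values)) {
  n <- length(values)
  if (n < 8) stop("need at least 8 items")
  if (length(unique(values)) == 1) stop("all values identical: no split")
  k <- floor(n / 4)
  ord <- order(values, items)
  low <- ord[seq_len(k)]
  high <- ord[(n - k + 1):n]
  out <- data.frame(item = items[c(low, high)],
                    value = values[c(low, high)],
                    label = factor(rep(c("low", "high"), each = k),
                                   levels = c("low", "high")))
  out[order(out$item), ]
}

#' Train a linear max-margin classifier
#'
#' Linear support-vector machine (cost = 1) on standardised voxel features;
#' standardisation parameters are fitted on the training data only and
#' frozen into the model, so transfer to new data reuses them.
#'
#' @param x training patterns (observations x voxels).
#' @param y class labels (2 levels).
#' @return An \pkg{e1071} `svm` model.
#' @export
train_classifier <- function(x, y) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  x <- as.matrix(x)
  keep <- apply(x, 2, stats::sd) > 0    # constant features carry no signal
  if (!any(keep)) stop("all features are constant")
  m <- e1071::svm(x[, keep, drop = FALSE], droplevels(y), kernel = "linear",
                  cost = 1, scale = TRUE, type = "C-classification")
  structure(list(svm = m, keep = keep), class = "goalrsa_svm")
}

#' @export
predict.goalrsa_svm <- function(object, newdata, ...) {
  stats::predict(object$svm, as.matrix(newdata)[, object$keep, drop = FALSE])
}

# stratified fold assignment: each class split as evenly as possible
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ix <- sample(which(y == lv))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Within-goal cross-validated accuracy
#'
#' Stratified k-fold cross-validation (default 10-fold); the classifier and
#' its feature standardisation are refit on each training fold. Returns the
#' mean fold accuracy.
#'
#' @param x patterns (observations x voxels).
#' @param y labels (2 levels).
#' @param k folds (default 10).
#' @param seed seed for the fold assignment.
#' @return Mean fold accuracy (fraction correct).
#' @export
within_accuracy <- function(x, y, k = 10, seed = 1L) {
  y <- factor(y)
  n <- length(y)
  if (k > n) stop("k exceeds the number of observations")
  if (min(table(y)) < k)
    warning("fewer than k items in a class: folds will be uneven")
  with_stream(seed, 11L, {
    fold <- stratified_folds(y, k)
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- train_classifier(x[tr, , drop = FALSE], y[tr])
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(acc)
  })
}

#' Cross-goal transfer accuracy
#'
#' Applies a frozen classifier (including its frozen standardisation) to all
#' retained items of the other goal. No folding is needed because no
#' training data leaks across goals.
#'
#' @param model classifier from [train_classifier()].
#' @param x patterns of the other goal's retained items.
#' @param y their labels.
#' @return Fraction correct.
#' @export
cross_accuracy <- function(model, x, y) {
  mean(stats::predict(model, x) == factor(y))
}

#' Within- and cross-goal classification for one subject
#'
#' For each goal: split that goal's items into high/low usefulness quartiles
#' ([split_high_low()], per subject per goal), estimate the within-goal
#' 10-fold accuracy, train on all retained items, and test the frozen model
#' on the other goal's retained items labelled by the other goal's own
#' usefulness.
#'
#' @param ps a [pattern_set()] for the subject.
#' @param ratings rating table (for this subject's usefulness).
#' @param voxels voxel column indices of the ROI.
#' @param goals the two goal labels.
#' @param k CV folds.
#' @param seed fold seed.
#' @param pooled_split split on usefulness pooled across goals instead of per
#'   goal (default FALSE).
#' @return data.frame with one row per training goal: `train_goal`, `within`,
#'   `cross`, `n_retained`.
#' @export
xclass_subject <- function(ps, ratings, voxels, goals, k = 10, seed = 1L,
                           pooled_split = FALSE) {
  stopifnot(inherits(ps, "pattern_set"))
  subj <- ps$subject %||% unique(ratings$subject)[1]
  lk <- ratings_lookup(ratings, subj, goals)
  splits <- vector("list", 2)
  if (pooled_split) {
    # quartile cutoffs from the usefulness pooled over both goals, then each
    # goal's items labelled against those common cutoffs
    qs <- stats::quantile(c(lk$U[, 1], lk$U[, 2]), c(0.25, 0.75))
    for (g in 1:2) {
      v <- lk$U[, g]
      keep <- v <= qs[1] | v >= qs[2]
      if (sum(keep) < 4 || length(unique(v[keep] >= qs[2])) < 2)
        stop("pooled split leaves too few items for goal ", goals[g])
      splits[[g]] <- data.frame(item = lk$item[keep], value = v[keep],
                                label = factor(ifelse(v[keep] >= qs[2],
                                                      "high", "low"),
                                               levels = c("low", "high")))
    }
  } else {
    for (g in 1:2) splits[[g]] <- split_high_low(lk$U[, g], items = lk$item)
  }
  key <- paste(ps$conditions$item, ps$conditions$goal)
  get_x <- function(g, sp) {
    rows <- match(paste(sp$item, goals[g]), key)
    if (anyNA(rows)) stop("patterns missing for some retained conditions")
    ps$patterns[rows, voxels, drop = FALSE]
  }
  out <- vector("list", 2)
  for (g in 1:2) {
    og <- 3L - g
    sp <- splits[[g]]; spo <- splits[[og]]
    x_tr <- get_x(g, sp); x_te <- get_x(og, spo)
    wacc <- within_accuracy(x_tr, sp$label, k = k, seed = seed + g)
    m <- train_classifier(x_tr, sp$label)
    cacc <- cross_accuracy(m, x_te, spo$label)
    out[[g]] <- data.frame(subject = subj, train_goal = goals[g],
                           within = wacc, cross = cacc,
                           n_retained = nrow(sp))
  }
  do.call(rbind, out)
}

#' Group statistics for classifier outcomes
#'
#' Per region: one-sided Wilcoxon signed-rank tests of the subject-mean
#' within-goal and cross-goal accuracies against chance (0.5), and a paired
#' two-sided Wilcoxon test of within versus cross.
#'
#' @param outcomes data.frame with columns `subject`, `region`, `within`,
#'   `cross` (one or more rows per subject, averaged within subject first).
#' @return data.frame, one row per region: mean accuracies and the three
#'   p-values.
#' @export
xclass_group_stats <- function(outcomes) {
  if (is.null(outcomes$region)) outcomes$region <- "roi"
  res <- lapply(split(outcomes, outcomes$region), function(d) {
    w <- tapply(d$within, d$subject, mean)
    x <- tapply(d$cross, d$subject, mean)
    if (length(w) < 6) warning("fewer than 6 subjects in region ",
                               d$region[1])
    one_sided <- function(v) {
      if (all(v == 0.5)) return(1)     # degenerate: nothing to rank
      stats::wilcox.test(v, mu = 0.5, alternative = "greater",
                         exact = FALSE, correct = FALSE)$p.value
    }
    pw <- one_sided(w)
    px <- one_sided(x)
    pd <- if (all(w == x)) 1 else
      stats::wilcox.test(w, x, paired = TRUE, exact = FALSE,
                         correct = FALSE)$p.value
    data.frame(region = d$region[1], mean_within = mean(w),
               mean_cross = mean(x), p_within = pw, p_cross = px,
               p_within_vs_cross = pd)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
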