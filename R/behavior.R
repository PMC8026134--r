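# Behavioural analyses: choice model design + fitting, consistency-based
# subject exclusion, shared variance, quadratic confidence fit, rating
# correlation table.

#' Build the choice-model predictor table
#'
#' One row per choice trial with the eight predictors of the logistic choice
#' model: goal (effect-coded -0.5 / +0.5 for the first/second goal),
#' right-minus-left usefulness difference under the congruent (current) and
#' incongruent (other) goal, the same two confidence differences, the two
#' usefulness-by-confidence interactions, and the monetary-value difference.
#' The response is the chose-right indicator.
#'
#' Rating-based predictors are rescaled to the unit interval (slider range ->
#' [0, 1]) by default, the scale on which the model coefficients are
#' reported; the model itself is scale-covariant, so this only fixes the
#' units of the coefficients.
#'
#' @param choices choice-trial data.frame (see [generate_choices()]).
#' @param ratings rating table covering every chosen item under both goals.
#' @param goals the two goal labels (order defines the goal coding).
#' @param rating_scale slider interval used for rescaling.
#' @param scale_predictors rescale rating predictors to the unit interval
#'   (default TRUE).
#' @return data.frame: `subject`, `goal`, predictors `x_goal`, `cong_dU`,
#'   `incong_dU`, `cong_dC`, `incong_dC`, `cong_dUdC`, `incong_dUdC`,
#'   `d_monetary`, and response `chose_right` (0/1).
#' @export
build_choice_design <- function(choices, ratings,
                                goals = sort(unique(ratings$goal)),
                                rating_scale = c(0, 100),
                                scale_predictors = TRUE) {
  width <- if (scale_predictors) diff(rating_scale) else 1
  out <- vector("list", length(unique(choices$subject)))
  k <- 0L
  for (s in unique(choices$subject)) {
    lk <- ratings_lookup(ratings, s, goals)
    ch <- choices[choices$subject == s, ]
    il <- match(ch$left_item, lk$item); ir <- match(ch$right_item, lk$item)
    if (anyNA(il) || anyNA(ir)) {
      bad <- unique(c(ch$left_item[is.na(il)], ch$right_item[is.na(ir)]))
      stop("subject ", s, ": no ratings for item(s) ",
           paste(bad, collapse = ", "))
    }
    g <- match(ch$goal, goals)
    if (anyNA(g)) stop("subject ", s, ": unknown goal label in choices")
    og <- 3L - g
    pick <- function(M, row, col) M[cbind(row, col)]
    cong_dU <- (pick(lk$U, ir, g) - pick(lk$U, il, g)) / width
    incong_dU <- (pick(lk$U, ir, og) - pick(lk$U, il, og)) / width
    cong_dC <- (pick(lk$C, ir, g) - pick(lk$C, il, g)) / width
    incong_dC <- (pick(lk$C, ir, og) - pick(lk$C, il, og)) / width
    k <- k + 1L
    out[[k]] <- data.frame(
      subject = s, goal = ch$goal,
      x_goal = ifelse(g == 2L, 0.5, -0.5),
      cong_dU = cong_dU, incong_dU = incong_dU,
      cong_dC = cong_dC, incong_dC = incong_dC,
      cong_dUdC = cong_dU * cong_dC, incong_dUdC = incong_dU * incong_dC,
      d_monetary = lk$monetary[ir] - lk$monetary[il],
      chose_right = as.integer(ch$chosen_side == "right"))
  }
  do.call(rbind, out[seq_len(k)])
}

choice_predictors <- c("x_goal", "cong_dU", "incong_dU", "cong_dC",
                       "incong_dC", "cong_dUdC", "incong_dUdC", "d_monetary")

#' Bias-reduced (Firth) logistic regression
#'
#' Logistic regression by Firth's adjusted score, which removes the
#' first-order small-sample bias of the maximum-likelihood estimate and
#' yields finite coefficients under complete separation. Implemented as
#' iterated reweighted least squares on the working response augmented by
#' the hat-diagonal correction `h * (1/2 - mu)`.
#'
#' @param X design matrix (include the intercept column explicitly).
#' @param y 0/1 response vector.
#' @param max_iter,tol iteration control.
#' @return Named coefficient vector.
#' @export
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  # aliased columns get NA coefficients, mirroring stats::glm
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    full <- rep(NA_real_, ncol(X))
    names(full) <- colnames(X)
    full[keep] <- firth_logistic(X[, keep, drop = FALSE], y,
                                 max_iter = max_iter, tol = tol)
    return(full)
  }
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    # on very small designs the weighted information matrix can become
    # numerically singular mid-iteration; an escalating ridge keeps the
    # step defined without changing the converged solution materially
    ridge <- 0
    R <- NULL
    while (is.null(R)) {
      R <- tryCatch(chol(XtWX + diag(ridge, ncol(X))),
                    error = function(e) NULL)
      if (is.null(R)) {
        base_r <- max(mean(diag(XtWX)), 1e-8)
        ridge <- if (ridge == 0) 1e-8 * base_r else ridge * 10
        if (!is.finite(ridge) || ridge > 1e6 * base_r)
          stop("weighted design lost rank during fitting")
      }
    }
    Z <- backsolve(R, t(X), transpose = TRUE)
    h <- w * colSums(Z^2)          # leverage of each observation
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(backsolve(R, backsolve(R, U, transpose = TRUE)))
    # step-size cap (as in standard Firth implementations): prevents
    # overshoot into saturated probabilities on ill-conditioned designs
    step <- max(abs(delta))
    if (step > 5) delta <- delta * (5 / step)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  stats::setNames(beta, colnames(X))
}

#' Fit the logistic choice model
#'
#' Default estimator is the summary-statistics approximation to the mixed
#' model: a maximum-likelihood logistic regression per subject on the eight
#' predictors, followed by group-level one-sample t tests on the subject
#' coefficients. Subjects with (quasi-)complete separation are flagged and
#' excluded from the group tests with a warning. `estimator = "firth"` uses
#' bias-reduced per-subject fits ([firth_logistic()]) instead of maximum
#' likelihood; with ~100 trials and 9 parameters per subject the ML slopes
#' carry a noticeable upward small-sample bias that the adjusted score
#' removes, and separation cannot occur. `estimator = "mixed"` fits
#' the full random-slopes mixed model via \pkg{lme4} (random intercept plus
#' random slopes for the congruent usefulness and confidence differences)
#' and reports its fixed effects, keeping the per-subject slopes from the
#' summary-statistics pass. The mixed fixed effects are mildly attenuated
#' relative to the subject-conditional coefficients because random slopes on
#' the remaining predictors are not modelled.
#'
#' @param design output of [build_choice_design()].
#' @param estimator `"summary"` (default), `"firth"`, or `"mixed"`.
#' @param nAGQ integration accuracy passed to \pkg{lme4} for the mixed
#'   estimator (1 = adaptive Gauss-Hermite, 0 = faster penalised fit).
#' @return Object of class `choice_fit`: `coefficients` (group estimates),
#'   `se`, `p_value`, `t`, `df`, `per_subject` (matrix subjects x terms),
#'   `separated` (logical per subject), `estimator`.
#' @export
fit_choice_model <- function(design, estimator = c("summary", "firth",
                                                   "mixed"),
                             nAGQ = 1) {
  estimator <- match.arg(estimator)
  subs <- unique(design$subject)
  if (length(subs) < 2) stop("need at least 2 subjects")
  if (length(unique(design$chose_right)) < 2)
    stop("both response classes must be present")
  terms <- c("(Intercept)", choice_predictors)
  per <- matrix(NA_real_, length(subs), length(terms),
                dimnames = list(subs, terms))
  separated <- logical(length(subs))
  fml <- stats::as.formula(paste("chose_right ~",
                                 paste(choice_predictors, collapse = " + ")))
  for (i in seq_along(subs)) {
    d <- design[design$subject == subs[i], ]
    if (estimator == "firth") {
      X <- cbind("(Intercept)" = 1,
                 as.matrix(d[, choice_predictors, drop = FALSE]))
      co <- firth_logistic(X, d$chose_right)
      separated[i] <- FALSE          # Firth estimates are always finite
    } else {
      fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                         data = d))
      co <- stats::coef(fit)
      # separation heuristic: non-convergence, huge slopes, or fitted probs
      # pinned at 0/1
      mu <- stats::fitted(fit)
      separated[i] <- !fit$converged || any(abs(co) > 50, na.rm = TRUE) ||
        all(mu < 1e-6 | mu > 1 - 1e-6)
    }
    per[i, names(co)] <- co
  }
  if (any(separated))
    warning(sum(separated), " subject(s) flagged as separated and excluded ",
            "from the group tests")
  use <- per[!separated, , drop = FALSE]
  est <- colMeans(use, na.rm = TRUE)
  se <- apply(use, 2, function(x) stats::sd(x, na.rm = TRUE) /
                sqrt(sum(!is.na(x))))
  df <- colSums(!is.na(use)) - 1
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  mixed <- NULL
  if (estimator == "mixed") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("estimator = 'mixed' requires the lme4 package")
    # uncorrelated random intercept + slopes on the two congruent predictors:
    # richer structures are supported by refitting with a custom formula, but
    # this is the default documented random-effects structure
    mfml <- stats::as.formula(paste(
      "chose_right ~", paste(choice_predictors, collapse = " + "),
      "+ (1 + cong_dU + cong_dC || subject)"))
    mixed <- lme4::glmer(mfml, data = design, family = stats::binomial(),
                         nAGQ = nAGQ,
                         control = lme4::glmerControl(calc.derivs = FALSE))
    fe <- summary(mixed)$coefficients
    est <- fe[, "Estimate"]; se <- fe[, "Std. Error"]
    tval <- fe[, "z value"]
    # Wald inference on the fixed effects uses a between-subject df bound
    # (n_subjects - 1) rather than the normal reference: the effective
    # replication unit for the slopes with random effects is the subject,
    # and normal-based intervals are anti-conservative at n ~ 30
    df <- rep(length(subs) - 1, length(est))
    pval <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(coefficients = est, se = se, t = tval, p_value = pval,
                 df = df, per_subject = per, separated = separated,
                 estimator = estimator, mixed_fit = mixed),
            class = "choice_fit")
}

#' @export
coef.choice_fit <- function(object, ...) object$coefficients

#' @export
print.choice_fit <- function(x, ...) {
  cat("Logistic choice model (", x$estimator, " estimator, ",
      nrow(x$per_subject), " subjects, ", sum(x$separated),
      " separated)\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.choice_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, se = object$se,
                    t = object$t, df = object$df, p = object$p_value)
  ci <- object$coefficients +
    outer(object$se, c(-1, 1)) * stats::qt(0.975, object$df)
  out$ci_lo <- ci[, 1]; out$ci_hi <- ci[, 2]
  out
}

#' Exclude subjects with inconsistent choices
#'
#' Subjects whose individual congruent-usefulness slope is below the
#' threshold are excluded — the consistency rule used to remove participants
#' whose day-2 choices do not follow their day-1 valuations. With
#' unit-interval predictor scaling the slope is per full slider range; set
#' `threshold_scale` to the slider width if slopes were fitted on raw slider
#' units (the published threshold, 0.025, is per raw slider unit).
#'
#' @param fit a `choice_fit`.
#' @param threshold slope cutoff per raw slider unit (default 0.025).
#' @param slider_width width of the slider interval the predictors were
#'   rescaled by (default 100; use 1 if predictors were left raw).
#' @return List with `included` and `excluded` subject id vectors and the
#'   per-subject slopes used.
#' @export
exclude_inconsistent <- function(fit, threshold = 0.025, slider_width = 100) {
  stopifnot(inherits(fit, "choice_fit"))
  slopes <- fit$per_subject[, "cong_dU"] / slider_width
  subs <- rownames(fit$per_subject)
  excl <- is.na(slopes) | slopes < threshold
  list(included = subs[!excl], excluded = subs[excl],
       slopes = stats::setNames(slopes, subs), threshold = threshold)
}

#' Shared variance of a correlation
#'
#' Percentage of variance shared by two variables with Pearson correlation
#' `r`: `100 * r^2`, rounded to 2 decimals for reporting.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @return Shared variance in percent.
#' @export
shared_variance <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  round(100 * r^2, 2)
}

#' Quadratic relationship between confidence and usefulness
#'
#' Per subject (pooling both goals, usefulness centred within subject and
#' goal), regresses confidence on centred usefulness and its square; the
#' quadratic coefficients are then tested against zero at the group level
#' with a one-sample t test. Units: slider units of confidence per squared
#' slider unit of usefulness.
#'
#' @param ratings rating table ([generate_ratings()] layout).
#' @return List: `beta` (group mean quadratic coefficient), `t`, `df`, `p`,
#'   `ci` (95 percent), `per_subject` quadratic coefficients.
#' @export
fit_confidence_quadratic <- function(ratings) {
  subs <- unique(ratings$subject)
  per <- numeric(length(subs))
  for (i in seq_along(subs)) {
    rs <- ratings[ratings$subject == subs[i], ]
    # one fit per goal (intercept and linear term are goal-specific), then
    # the quadratic coefficients averaged within subject
    b2 <- vapply(split(rs, rs$goal), function(d) {
      uc <- d$usefulness - mean(d$usefulness)
      if (length(unique(uc)) < 3 || stats::sd(uc) == 0)
        stop("degenerate usefulness variance for subject ", subs[i])
      stats::coef(stats::lm(d$confidence ~ uc + I(uc^2)))["I(uc^2)"]
    }, 0)
    per[i] <- mean(b2)
  }
  tt <- if (length(subs) >= 2)
    tryCatch(stats::t.test(per), error = function(e) NULL) else NULL
  if (!is.null(tt)) {
    list(beta = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         ci = as.numeric(tt$conf.int), per_subject = per)
  } else {
    # single subject or zero between-subject variance: no group test
    list(beta = mean(per), t = NA, df = NA, p = NA,
         ci = c(mean(per), mean(per)), per_subject = per)
  }
}

#' Pairwise rating correlations across subjects
#'
#' Per-subject Pearson correlations between the five rating variables
#' (usefulness and confidence under each goal, monetary value), aggregated
#' across subjects as mean, SD, min and max. Entries undefined for a subject
#' (constant column) are dropped from that entry's aggregation and counted.
#'
#' @param ratings rating table.
#' @param goals the two goal labels.
#' @return List of 5 x 5 matrices: `mean`, `sd`, `min`, `max`, `n` (subjects
#'   contributing to each entry).
#' @export
rating_correlation_table <- function(ratings,
                                     goals = sort(unique(ratings$goal))) {
  subs <- unique(ratings$subject)
  vars <- c(paste0("U_", goals[1]), paste0("U_", goals[2]),
            paste0("C_", goals[1]), paste0("C_", goals[2]), "V_monetary")
  acc <- array(NA_real_, c(5, 5, length(subs)),
               dimnames = list(vars, vars, NULL))
  for (i in seq_along(subs)) {
    lk <- ratings_lookup(ratings, subs[i], goals)
    M <- cbind(lk$U[, 1], lk$U[, 2], lk$C[, 1], lk$C[, 2], lk$monetary)
    sds <- apply(M, 2, stats::sd)
    r <- suppressWarnings(stats::cor(M))
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
    diag(r)[sds > 0] <- 1
    acc[, , i] <- r
  }
  list(mean = apply(acc, 1:2, mean, na.rm = TRUE),
       sd = apply(acc, 1:2, stats::sd, na.rm = TRUE),
       min = apply(acc, 1:2, min, na.rm = TRUE),
       max = apply(acc, 1:2, max, na.rm = TRUE),
       n = apply(acc, 1:2, function(x) sum(!is.na(x))))
}

#' Paired test of reaction times across goals
#'
#' Paired t test of subject mean choice reaction times between the two goals.
#'
#' @param choices choice-trial data.frame with `rt`.
#' @param goals goal labels.
#' @return `htest` from [stats::t.test()].
#' @export
rt_goal_test <- function(choices, goals = sort(unique(choices$goal))) {
  m <- tapply(choices$rt, list(choices$subject, choices$goal), mean)
  stats::t.test(m[, goals[1]], m[, goals[2]], paired = TRUE)
}
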