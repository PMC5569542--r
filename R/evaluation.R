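#' Reliability of a daughter yield deviation
#'
#' `r2 = d_e / (d_e + K)` with `K = (4 - h2) / h2` (the Fikse–Banos
#' daughter-equivalent constant). `d_e` is the effective number of
#' daughters behind the DYD.
#'
#' @param d_e effective daughter count(s), >= 0 (scalar or vector).
#' @param h2 heritability in (0, 1].
#' @return Reliability value(s) in `[0, 1)`.
#' @export
dyd_reliability <- function(d_e, h2) {
  if (!(h2 > 0)) stop("h2 must be strictly positive")
  stopifnot(h2 <= 1, all(d_e >= 0))
  K <- (4 - h2) / h2
  d_e / (d_e + K)
}

#' Prediction accuracy
#'
#' Correlation between GEBV and DYD divided by the square root of the
#' average DYD reliability, rescaling the observable correlation to the
#' GEBV–true-breeding-value scale.
#'
#' @param gebv,dyd numeric vectors of equal length >= 3, neither constant.
#' @param mean_reliability average DYD reliability of the validation set,
#'   in (0, 1].
#' @return Scalar accuracy (sign preserved; not clamped to `[-1, 1]`).
#' @export
prediction_accuracy <- function(gebv, dyd, mean_reliability) {
  stopifnot(length(gebv) == length(dyd), length(gebv) >= 3,
            mean_reliability > 0, mean_reliability <= 1)
  if (sd(gebv) == 0 || sd(dyd) == 0)
    stop("constant vector: correlation undefined")
  cor(gebv, dyd) / sqrt(mean_reliability)
}

#' Prediction bias (dispersion)
#'
#' Ordinary least-squares slope of DYD on GEBV (with intercept). A slope
#' of 1 means no bias; below 1 the spread of the GEBV is too large;
#' above 1 too small.
#'
#' @param gebv,dyd numeric vectors of equal length >= 3.
#' @return Scalar regression coefficient.
#' @export
prediction_bias <- function(gebv, dyd) {
  stopifnot(length(gebv) == length(dyd), length(gebv) >= 3)
  if (var(gebv) == 0) stop("zero-variance GEBV: slope undefined")
  # cov/var rather than lm() keeps this O(n) inside the bootstrap
  sum((gebv - mean(gebv)) * (dyd - mean(dyd))) / sum((gebv - mean(gebv))^2)
}

#' Bootstrap standard errors of accuracy and bias
#'
#' Resamples GEBV–DYD *pairs* with replacement `n_boot` times (the link
#' between an animal's GEBV and its DYD is kept) and reports the standard
#' deviation of the recomputed accuracy and bias. Degenerate resamples
#' (constant GEBV or DYD) are redrawn and counted; more than 1% of them
#' is an error.
#'
#' @inheritParams prediction_accuracy
#' @param n_boot number of bootstrap resamples (>= 100; default 10000).
#' @param seed RNG seed.
#' @return List with `accuracy_se`, `bias_se`, `n_boot`, `n_degenerate`.
#' @export
bootstrap_se <- function(gebv, dyd, mean_reliability, n_boot = 10000L,
                         seed = 1L) {
  stopifnot(n_boot >= 100, length(gebv) == length(dyd), length(gebv) >= 3)
  n <- length(gebv)
  set.seed(seed)
  acc <- bias <- numeric(n_boot)
  n_degen <- 0L
  sqrt_rel <- sqrt(mean_reliability)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      gb <- gebv[idx]; db <- dyd[idx]
      if (sd(gb) > 0 && sd(db) > 0) break
      n_degen <- n_degen + 1L
      if (n_degen > 0.01 * n_boot)
        stop("more than 1% of bootstrap resamples degenerate; increase n")
    }
    acc[b] <- cor(gb, db) / sqrt_rel
    bias[b] <- sum((gb - mean(gb)) * (db - mean(db))) / sum((gb - mean(gb))^2)
  }
  list(accuracy_se = sd(acc), bias_se = sd(bias), n_boot = n_boot,
       n_degenerate = n_degen)
}

#' Hotelling–Williams test for two dependent correlations
#'
#' Two-sided test of `r12 = r13` when both correlations share variable 1
#' (here: the DYD, correlated with the GEBV of two methods), given the
#' correlation `r23` between the two predictors.
#'
#' `t = (r12 - r13) * sqrt((n - 1)(1 + r23) /
#'      (2 ((n - 1)/(n - 3)) |R| + rbar^2 (1 - r23)^3))`,
#' with `rbar = (r12 + r13)/2` and
#' `|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23`; `t` is referred to
#' a Student t distribution with `n - 3` degrees of freedom.
#'
#' @param r12,r13 correlations of the shared variable with predictors 2
#'   and 3, in (-1, 1).
#' @param r23 correlation between the two predictors, in (-1, 1).
#' @param n number of observations (>= 4).
#' @return List with `t`, `p_value`, `df`.
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  stopifnot(abs(r12) < 1, abs(r13) < 1, abs(r23) < 1, n >= 4)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12)
    stop("correlation triple is not positive semi-definite (|R| = ",
         format(detR), ")")
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t_stat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(t = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 3), df = n - 3)
}

#' Assemble an evaluation report for one method
#'
#' Convenience wrapper computing accuracy, bias and their bootstrap
#' standard errors for one GEBV vector against a phenotype table.
#'
#' @param gebv named GEBV vector for the validation animals.
#' @param phenotypes a [phenotype_table()] covering (at least) those
#'   animals.
#' @param h2 heritability used for the DYD reliabilities.
#' @param method_label text label for the report.
#' @param n_boot,seed bootstrap settings (see [bootstrap_se()]).
#' @return An `evaluation_report` list with `method_label`, `accuracy`,
#'   `accuracy_se`, `bias`, `bias_se`, `n_validation`,
#'   `mean_reliability`.
#' @export
evaluate_predictions <- function(gebv, phenotypes, h2,
                                 method_label = "method",
                                 n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(phenotypes, "phenotype_table"))
  ids <- names(gebv)
  if (is.null(ids)) stop("gebv must be named by animal id")
  ph <- phenotypes[match(ids, phenotypes$animal_id), ]
  if (anyNA(ph$animal_id))
    stop("animals missing from the phenotype table: ",
         paste(head(ids[is.na(ph$animal_id)], 5L), collapse = ", "))
  rel <- dyd_reliability(ph$d_e, h2)
  mean_rel <- mean(rel)
  bs <- bootstrap_se(gebv, ph$dyd, mean_rel, n_boot = n_boot, seed = seed)
  structure(list(method_label = method_label,
                 accuracy = prediction_accuracy(gebv, ph$dyd, mean_rel),
                 accuracy_se = bs$accuracy_se,
                 bias = prediction_bias(gebv, ph$dyd),
                 bias_se = bs$bias_se,
                 n_validation = length(gebv),
                 mean_reliability = mean_rel),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s: accuracy %.3f (%.3f), bias %.3f (%.3f), n = %d, mean r2(DYD) = %.3f\n",
              x$method_label, x$accuracy, x$accuracy_se, x$bias, x$bias_se,
              x$n_validation, x$mean_reliability))
  invisible(x)
}
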