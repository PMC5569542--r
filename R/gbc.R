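#' GBC configuration
#'
#' Settings for the iterative conditional expectation (ICE) fit of the
#' combined model `y = 1 mu + M Q q + g + e`.
#'
#' @param pi prior probability that a SNP carries a large effect, in
#'   (0, 1).
#' @param large_effect_fraction fraction `f` of the genetic variance
#'   assigned to one large-effect SNP of average heterozygosity
#'   (default 0.001; 0.01 is the usual alternative). Sets the slab
#'   variance `sigma2_q = f * sigma2_g / vbar`, `vbar = scale_c / m`.
#' @param max_outer_iter cap on outer ICE iterations.
#' @param tol convergence tolerance: the fit stops when the largest
#'   change in any reference GEBV (`M q + g`) over one outer iteration
#'   falls below `tol * sd(y)`.
#' @param pev_correction add the `m'_j PEV m_j` term to the likelihood
#'   ratio, correcting for the uncertainty of the other genetic effects
#'   (default `TRUE`).
#' @param ppr_literal use the literal published form `pi * (1 - pi)` for
#'   the prior-probability ratio instead of the odds `pi / (1 - pi)`
#'   (default `FALSE`; provided for comparison only — see the methods
#'   vignette).
#' @param include_gblup fit the G-BLUP background term (default `TRUE`;
#'   turning it off leaves a pure ICE Bayes-C fit, used by tests).
#' @return A `gbc_config` list.
#' @export
gbc_config <- function(pi = 0.01, large_effect_fraction = 0.001,
                       max_outer_iter = 1000L, tol = 1e-6,
                       pev_correction = TRUE, ppr_literal = FALSE,
                       include_gblup = TRUE) {
  stopifnot(pi > 0, pi < 1, large_effect_fraction > 0,
            large_effect_fraction < 1, max_outer_iter >= 1, tol > 0)
  structure(list(pi = pi, large_effect_fraction = large_effect_fraction,
                 max_outer_iter = as.integer(max_outer_iter), tol = tol,
                 pev_correction = isTRUE(pev_correction),
                 ppr_literal = isTRUE(ppr_literal),
                 include_gblup = isTRUE(include_gblup)),
            class = "gbc_config")
}

#' Log likelihood ratio for a large SNP effect
#'
#' `log(LR_j) = 1/2 log(lambda) - 1/2 log(m'm + lambda) +
#'  1/2 ((m'y*)^2 + m'PEVm) / sigma2_e / (m'm + lambda)`, comparing the
#' model with versus without a large effect at SNP j; `y*` is the record
#' vector corrected for every other effect in the model, and the
#' `m'PEVm` term corrects for the uncertainty of those other effects.
#'
#' @param m_j centered genotype column for the animals with records.
#' @param y_star corrected response `y*`.
#' @param lambda shrinkage ratio `sigma2_e / sigma2_q` (> 0).
#' @param sigma2_e residual variance (> 0).
#' @param pev_quadform precomputed `m'_j PEV m_j` (>= 0); pass 0 to
#'   disable the correction.
#' @return Scalar log likelihood ratio.
#' @export
log_likelihood_ratio <- function(m_j, y_star, lambda, sigma2_e,
                                 pev_quadform = 0) {
  stopifnot(lambda > 0, sigma2_e > 0, pev_quadform >= 0,
            length(m_j) == length(y_star))
  mtm <- sum(m_j^2)
  mty <- sum(m_j * y_star)
  0.5 * log(lambda) - 0.5 * log(mtm + lambda) +
    0.5 * (mty^2 + pev_quadform) / sigma2_e / (mtm + lambda)
}

#' Posterior probability of a large SNP effect
#'
#' `PostProb = PPR * LR / (PPR * LR + 1)` with the prior-probability
#' ratio `PPR = pi / (1 - pi)` (prior odds). Evaluated in log space so
#' that extreme likelihood ratios saturate at 0/1 without overflow.
#'
#' @param log_lr log likelihood ratio from [log_likelihood_ratio()].
#' @param pi prior inclusion probability in (0, 1).
#' @param ppr_literal if `TRUE`, use `PPR = pi * (1 - pi)` (the literal
#'   published form) instead of the odds.
#' @return Probability in `[0, 1]`.
#' @export
posterior_probability <- function(log_lr, pi, ppr_literal = FALSE) {
  stopifnot(pi > 0, pi < 1)
  log_ppr <- if (ppr_literal) log(pi * (1 - pi)) else log(pi / (1 - pi))
  stats::plogis(log_ppr + log_lr)
}

#' Conditional-expectation update of one SNP effect
#'
#' `q_hat_j = PostProb * m'_j y* / (m'_j m_j + lambda)`; the second factor
#' is the BLUP solution of the SNP effect given that it is large.
#'
#' @inheritParams log_likelihood_ratio
#' @param postprob posterior probability of a large effect at SNP j.
#' @return Scalar updated effect.
#' @export
snp_effect_update <- function(m_j, y_star, lambda, postprob) {
  stopifnot(lambda > 0, postprob >= 0, postprob <= 1)
  postprob * sum(m_j * y_star) / (sum(m_j^2) + lambda)
}

#' Fit the GBC model by iterative conditional expectation
#'
#' Fits `y = 1 mu + M Q q + g + e` on the reference animals: a Bayes-C
#' large-effect SNP term and a G-BLUP polygenic term, updated in turn
#' until the reference GEBV (`M q + g`) stabilise. Each outer iteration
#' updates (1) the mean, (2) the residual breeding values `g` given the
#' current SNP effects, and (3) every SNP effect in fixed ascending order
#' by [log_likelihood_ratio()] / [posterior_probability()] /
#' [snp_effect_update()], maintaining the working residual incrementally.
#' The PEV matrix entering the likelihood-ratio correction is computed
#' once, from the SNP-free G-BLUP fit, and held fixed.
#'
#' @param y response vector for the reference animals (aligned with
#'   `ref_ids`).
#' @param cg [center_genotypes()] for all animals.
#' @param grm [build_grm()] for all animals (ignored when
#'   `config$include_gblup` is `FALSE`).
#' @param params a [trait_params()].
#' @param config a [gbc_config()].
#' @param ref_ids reference animal ids (rows of `cg`/`grm` used for
#'   fitting); defaults to all animals.
#' @param val_ids optional validation ids, stored for [gbc_gebv()].
#' @return A `gbc_fit`: list with `q_hat`, `postprob`, `g_hat`, `mu_hat`,
#'   `working_residuals`, `lambda`, `sigma2_q`, `converged`,
#'   `n_outer_iter`, plus bookkeeping (`snp_ids`, `freqs`, `ref_ids`,
#'   `val_ids`, `config`, `params`).
#' @export
fit_gbc <- function(y, cg, grm = NULL, params, config = gbc_config(),
                    ref_ids = rownames(cg$M), val_ids = NULL) {
  stopifnot(inherits(cg, "centered_genotypes"),
            inherits(params, "trait_params"),
            inherits(config, "gbc_config"))
  cg_ref <- subset_centered(cg, ref_ids)
  M <- cg_ref$M
  n <- nrow(M); m <- ncol(M)
  if (length(y) != n) stop("length(y) must match the reference rows")
  if (any(!is.finite(y))) stop("non-finite response values")
  y <- as.numeric(y)

  vbar <- cg$scale_c / m
  sigma2_q <- config$large_effect_fraction * params$sigma2_g / vbar
  lambda <- params$sigma2_e / sigma2_q
  log_ppr <- if (config$ppr_literal) log(config$pi * (1 - config$pi))
             else log(config$pi / (1 - config$pi))
  mtm <- colSums(M^2)

  if (config$include_gblup) {
    if (is.null(grm)) stop("grm required when include_gblup = TRUE")
    G_rr <- grm_block(grm, ref_ids)
    base_fit <- solve_gblup(y, G_rr, params)
    # g update operator for a fixed-mean response r: g = G (G + lambda I)^-1 r
    smoother <- G_rr %*% solve(G_rr + diag(base_fit$lambda_g, n))
    pevq <- if (config$pev_correction)
      colSums(M * (base_fit$pev %*% M)) else rep(0, m)
  } else {
    smoother <- NULL
    pevq <- rep(0, m)
  }
  pevq <- pmax(pevq, 0)

  mu <- mean(y)
  q <- rep(0, m)
  g <- rep(0, n)
  e <- y - mu
  gebv <- rep(0, n)
  tol_abs <- config$tol * sd(y)
  converged <- FALSE
  it <- 0L
  while (it < config$max_outer_iter) {
    it <- it + 1L
    Mq <- as.numeric(M %*% q)
    mu_new <- mean(y - Mq - g)
    if (config$include_gblup) {
      g <- as.numeric(smoother %*% (y - mu_new - Mq))
    }
    e <- y - mu_new - Mq - g
    mu <- mu_new
    sw <- ice_sweep_cpp(M, e, q, mtm, pevq, lambda, params$sigma2_e, log_ppr)
    q <- sw$q; e <- sw$e
    gebv_new <- y - mu - e   # = M q + g
    delta <- max(abs(gebv_new - gebv))
    gebv <- gebv_new
    if (delta < tol_abs) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GBC did not converge in %d outer iterations (last max GEBV change %.3g, tol %.3g)",
                    config$max_outer_iter, delta, tol_abs))
  names(q) <- colnames(M)
  pp <- sw$postprob; names(pp) <- colnames(M)
  names(g) <- ref_ids
  structure(list(q_hat = q, postprob = pp, g_hat = g, mu_hat = mu,
                 working_residuals = e, lambda = lambda,
                 sigma2_q = sigma2_q, converged = converged,
                 n_outer_iter = it, snp_ids = colnames(M),
                 freqs = cg$freqs, ref_ids = ref_ids, val_ids = val_ids,
                 config = config, params = params),
            class = "gbc_fit")
}

#' @export
print.gbc_fit <- function(x, ...) {
  cat(sprintf(
    "gbc_fit: %d SNPs, %d animals; %sconverged in %d iterations; %d SNPs with PostProb > 0.5\n",
    length(x$q_hat), length(x$g_hat), if (x$converged) "" else "NOT ",
    x$n_outer_iter, sum(x$postprob > 0.5)))
  invisible(x)
}

#' Validation GEBV from a GBC fit
#'
#' `GEBV = M_v q_hat + G_vr G_rr^-1 g_hat`: the SNP term evaluated on the
#' validation genotypes plus the G-BLUP projection of the residual
#' breeding values.
#'
#' @param fit a [fit_gbc()] result.
#' @param cg_val [center_genotypes()] rows for the validation animals
#'   (same SNPs and centering frequencies as the fit).
#' @param grm_vr,grm_rr validation x reference and reference GRM blocks;
#'   may be omitted when the fit has no G-BLUP term.
#' @return Named numeric GEBV vector.
#' @export
gbc_gebv <- function(fit, cg_val, grm_vr = NULL, grm_rr = NULL) {
  stopifnot(inherits(fit, "gbc_fit"), inherits(cg_val, "centered_genotypes"))
  check_snp_alignment(fit$snp_ids, fit$freqs, cg_val)
  gebv <- as.numeric(cg_val$M %*% fit$q_hat)
  if (fit$config$include_gblup) {
    if (is.null(grm_vr) || is.null(grm_rr))
      stop("grm_vr and grm_rr required for a fit with a G-BLUP term")
    grm_vr <- as.matrix(grm_vr)
    grm_rr <- if (inherits(grm_rr, "grm")) grm_rr$values else as.matrix(grm_rr)
    if (ncol(grm_vr) != length(fit$g_hat) ||
        nrow(grm_rr) != length(fit$g_hat))
      stop("GRM blocks not conformable with the fit")
    gebv <- gebv + as.numeric(grm_vr %*% solve(grm_rr, fit$g_hat))
  }
  names(gebv) <- rownames(cg_val$M)
  gebv
}

#' Select GBC hyperparameters by cross-validation
#'
#' Partitions the reference animals into `k_folds` folds (seeded), fits
#' GBC on k-1 folds for every `(pi, f)` pair on the grid, predicts the
#' held-out fold, and scores each pair by the mean across folds of the
#' correlation between prediction and held-out response. The default
#' `pi` grid is 1% and then 5% to 30% in steps of 5%.
#'
#' @inheritParams fit_gbc
#' @param pi_grid candidate prior inclusion probabilities.
#' @param f_grid candidate large-effect variance fractions.
#' @param k_folds number of folds (>= 2).
#' @param seed RNG seed for the fold assignment.
#' @param base_config a [gbc_config()] supplying the non-grid settings.
#' @return List with `pi`, `large_effect_fraction` (the argmax pair) and
#'   `cv_table` (data.frame: pi, f, score).
#' @export
select_hyperparameters_cv <- function(y, cg, grm, params,
                                      pi_grid = c(0.01, seq(0.05, 0.30, by = 0.05)),
                                      f_grid = 0.001, k_folds = 5L,
                                      seed = 1L,
                                      ref_ids = rownames(cg$M),
                                      base_config = gbc_config()) {
  stopifnot(k_folds >= 2, all(pi_grid > 0 & pi_grid < 1),
            all(f_grid > 0 & f_grid < 1))
  n <- length(ref_ids)
  if (length(y) != n) stop("length(y) must match ref_ids")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  if (min(tabulate(fold, k_folds)) < 2L)
    stop("a fold has fewer than 2 animals; reduce k_folds")
  grid <- expand.grid(pi = pi_grid, f = f_grid)
  scores <- matrix(NA_real_, nrow(grid), k_folds)
  for (k in seq_len(k_folds)) {
    hold <- fold == k
    train_ids <- ref_ids[!hold]
    hold_ids <- ref_ids[hold]
    cg_hold <- subset_centered(cg, hold_ids)
    for (r in seq_len(nrow(grid))) {
      cfg <- gbc_config(pi = grid$pi[r],
                        large_effect_fraction = grid$f[r],
                        max_outer_iter = base_config$max_outer_iter,
                        tol = base_config$tol,
                        pev_correction = base_config$pev_correction,
                        ppr_literal = base_config$ppr_literal,
                        include_gblup = base_config$include_gblup)
      fit <- suppressWarnings(
        fit_gbc(y[!hold], cg, grm, params, cfg, ref_ids = train_ids))
      pred <- if (cfg$include_gblup)
        gbc_gebv(fit, cg_hold, grm_block(grm, hold_ids, train_ids),
                 grm_block(grm, train_ids))
      else gbc_gebv(fit, cg_hold)
      scores[r, k] <- cor(pred, y[hold])
    }
  }
  grid$score <- rowMeans(scores)
  best <- which.max(grid$score)
  list(pi = grid$pi[best], large_effect_fraction = grid$f[best],
       cv_table = grid)
}
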