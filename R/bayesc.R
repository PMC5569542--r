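#' Bayes-C sampler configuration
#'
#' Chain defaults follow common practice for 50K-chip analyses: 20,000
#' iterations, 2000 burn-in, thinning of 100 (longer chains change
#' prediction accuracy negligibly; see the methods vignette).
#'
#' @param pi prior probability that a SNP has a (nonzero) effect, in
#'   (0, 1]. `pi = 1` disables the spike and yields a ridge/SNP-BLUP
#'   posterior, useful for validation.
#' @param n_iter,burn_in,thin chain length, burn-in and thinning interval.
#' @param seed RNG seed applied at chain start.
#' @param sample_variances sample `sigma2_q` and `sigma2_e` from
#'   scaled-inverse-chi-square full conditionals instead of keeping them
#'   fixed (default `FALSE`; fixed variances make the sampler directly
#'   checkable against ridge-regression oracles).
#' @return A `bayesc_config` list.
#' @export
bayesc_config <- function(pi = 0.1, n_iter = 20000L, burn_in = 2000L,
                          thin = 100L, seed = 1L, sample_variances = FALSE) {
  stopifnot(pi > 0, pi <= 1, burn_in < n_iter, thin >= 1)
  structure(list(pi = pi, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 sample_variances = isTRUE(sample_variances)),
            class = "bayesc_config")
}

slab_variance <- function(f, sigma2_g, scale_c, m) {
  vbar <- scale_c / m
  f * sigma2_g / vbar
}

#' Run the Bayes-C Gibbs sampler
#'
#' Samples the spike-and-slab model `y = 1 mu + M Q q + e` by single-site
#' Gibbs updates in fixed SNP order (see [bayesc_config()] for the chain
#' settings). Effects are posterior means over the thinned post-burn-in
#' samples; inclusion probabilities are the matching inclusion
#' frequencies.
#'
#' @param y response vector for the reference animals.
#' @param cg_ref [center_genotypes()] rows for the reference animals.
#' @param params a [trait_params()].
#' @param config a [bayesc_config()].
#' @return A `bayesc_fit`: list with `q_hat`, `inclusion_prob` (both named
#'   by SNP), `mu_hat`, `q_mcse` (per-SNP Monte-Carlo standard errors),
#'   `n_samples_kept`, `sigma2_q`, `freqs` and `snp_ids`.
#' @export
run_bayesc_gibbs <- function(y, cg_ref, params, config = bayesc_config()) {
  stopifnot(inherits(cg_ref, "centered_genotypes"),
            inherits(params, "trait_params"),
            inherits(config, "bayesc_config"))
  M <- cg_ref$M
  if (length(y) != nrow(M)) stop("length(y) must match the genotype rows")
  if (any(!is.finite(y))) stop("non-finite response values")
  # Fixed slab: expected genic variance from included SNPs,
  # pi * m * sigma2_q * vbar with vbar = scale_c/m, equals sigma2_g.
  sigma2_q <- params$sigma2_g / (config$pi * cg_ref$scale_c)
  if (!(sigma2_q > 0)) stop("zero-variance slab")
  set.seed(config$seed)
  res <- bayesc_chain_cpp(M, as.numeric(y), config$pi, params$sigma2_e,
                          sigma2_q, config$n_iter, config$burn_in,
                          config$thin, config$sample_variances,
                          4.2, 4.2)
  names(res$q_hat) <- names(res$inclusion_prob) <- names(res$q_mcse) <-
    colnames(M)
  structure(c(res, list(sigma2_q = sigma2_q, freqs = cg_ref$freqs,
                        snp_ids = colnames(M), config = config)),
            class = "bayesc_fit")
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat(sprintf(
    "bayesc_fit: %d SNPs, %d kept samples, mu_hat = %.4g, mean P(incl) = %.3f\n",
    length(x$q_hat), x$n_samples_kept, x$mu_hat, mean(x$inclusion_prob)))
  invisible(x)
}

#' Validation GEBV from a Bayes-C fit
#'
#' `GEBV = M_v q_hat` (the intercept is excluded: GEBV are expressed as
#' deviations). The validation genotypes must be centered with the same
#' allele frequencies as the training set.
#'
#' @param fit a [run_bayesc_gibbs()] result.
#' @param cg_val [center_genotypes()] rows for the validation animals.
#' @return Named numeric GEBV vector.
#' @export
bayesc_gebv <- function(fit, cg_val) {
  stopifnot(inherits(fit, "bayesc_fit"), inherits(cg_val, "centered_genotypes"))
  check_snp_alignment(fit$snp_ids, fit$freqs, cg_val)
  gebv <- as.numeric(cg_val$M %*% fit$q_hat)
  names(gebv) <- rownames(cg_val$M)
  gebv
}

check_snp_alignment <- function(snp_ids, freqs, cg_val) {
  if (!identical(snp_ids, colnames(cg_val$M))) {
    mism <- which(snp_ids != colnames(cg_val$M))[1L]
    if (length(snp_ids) != ncol(cg_val$M))
      stop("SNP sets differ in size between fit and validation genotypes")
    stop(sprintf("SNP mismatch at column %d: fit has '%s', validation has '%s'",
                 mism, snp_ids[mism], colnames(cg_val$M)[mism]))
  }
  if (max(abs(freqs - cg_val$freqs)) > 1e-10)
    stop("centering allele frequencies differ between fit and validation")
  invisible(TRUE)
}
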