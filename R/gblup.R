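#' Trait variance parameters
#'
#' Bundles the heritability and variance components supplied by the user
#' (variance-component estimation is out of scope; values typically come
#' from a REML analysis of the full recording data).
#'
#' @param h2 heritability in (0, 1].
#' @param sigma2_g additive genetic variance, trait units squared.
#' @param sigma2_e residual variance of the response, trait units squared.
#' @return A `trait_params` list with fields `h2`, `sigma2_g`, `sigma2_e`
#'   and the derived daughter-equivalent constant `K = (4 - h2)/h2`.
#' @export
trait_params <- function(h2, sigma2_g, sigma2_e) {
  stopifnot(h2 > 0, h2 <= 1, sigma2_g > 0, sigma2_e > 0)
  structure(list(h2 = h2, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 K = (4 - h2) / h2),
            class = "trait_params")
}

#' Solve the G-BLUP mixed model
#'
#' Fits `y = 1 mu + g + e` with `g ~ MVN(0, sigma2_g G)` and
#' `e ~ MVN(0, sigma2_e I)` (one record per animal, so the incidence
#' matrix is the identity) by direct solution of the mixed-model
#' equations with coefficient matrix `[[n, 1'], [1, I + G^-1 lambda]]`,
#' `lambda = sigma2_e / sigma2_g`. The full prediction-error-(co)variance
#' matrix `PEV = sigma2_e * C^gg` (the g,g block of the inverse
#' coefficient matrix) is returned because downstream methods need
#' quadratic forms in it.
#'
#' If G is numerically singular (duplicated genotypes are a common cause)
#' the solve is retried once with `1e-6` added to the diagonal, with a
#' warning; a second failure is an error.
#'
#' @param y response vector (e.g. daughter yield deviations), one per
#'   reference animal, aligned with `grm_rr`.
#' @param grm_rr a [build_grm()] result (or its reference-block matrix)
#'   restricted to the reference animals.
#' @param params a [trait_params()].
#' @param weights optional positive record weights; when supplied the
#'   residual variance for animal i is `sigma2_e / weights_i`
#'   (off by default: the homoscedastic model is the reference model).
#' @return A `mixed_model_fit`: list with `mu_hat`, `g_hat` (named by
#'   animal), `pev` (n x n), `lambda_g`, `sigma2_g`, `sigma2_e`.
#' @export
solve_gblup <- function(y, grm_rr, params, weights = NULL) {
  G <- if (inherits(grm_rr, "grm")) grm_rr$values else as.matrix(grm_rr)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n, inherits(params, "trait_params"))
  if (any(!is.finite(y))) stop("non-finite response values")
  lambda <- params$sigma2_e / params$sigma2_g
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) NULL)
  if (is.null(Ginv)) {
    warning("G numerically singular; retrying with 1e-6 ridge on diagonal")
    G <- G + diag(1e-6, n)
    Ginv <- chol2inv(chol(G))  # second failure propagates as an error
  }
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights > 0))
    as.numeric(weights)
  }
  # MME: [[1'W1, 1'W], [W1, W + Ginv*lambda]] (mu, g) = (1'Wy, Wy)
  C <- matrix(0, n + 1L, n + 1L)
  C[1L, 1L] <- sum(w)
  C[1L, -1L] <- w
  C[-1L, 1L] <- w
  C[-1L, -1L] <- diag(w, n) + Ginv * lambda
  rhs <- c(sum(w * y), w * y)
  Cinv <- solve(C)
  sol <- Cinv %*% rhs
  g_hat <- as.numeric(sol[-1L])
  names(g_hat) <- rownames(G)
  structure(list(mu_hat = sol[1L], g_hat = g_hat,
                 pev = params$sigma2_e * Cinv[-1L, -1L, drop = FALSE],
                 lambda_g = lambda,
                 sigma2_g = params$sigma2_g, sigma2_e = params$sigma2_e),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit: n = %d, mu_hat = %.4g, lambda_g = %.4g\n",
              length(x$g_hat), x$mu_hat, x$lambda_g))
  invisible(x)
}

#' Project G-BLUP breeding values onto validation animals
#'
#' `g_v = G_vr G_rr^-1 g_r`: the conditional expectation of the validation
#' animals' genomic values given the reference solutions, algebraically
#' equal to solving the joint mixed-model equations with the validation
#' records treated as missing.
#'
#' @param fit a [solve_gblup()] result on the reference set.
#' @param grm_vr validation x reference block of the (all-animal) GRM.
#' @param grm_rr reference block of the same GRM.
#' @return Named numeric GEBV vector in validation-animal order.
#' @export
predict_validation_gblup <- function(fit, grm_vr, grm_rr) {
  grm_vr <- as.matrix(grm_vr)
  grm_rr <- if (inherits(grm_rr, "grm")) grm_rr$values else as.matrix(grm_rr)
  n_r <- length(fit$g_hat)
  if (ncol(grm_vr) != n_r || nrow(grm_rr) != n_r)
    stop("GRM blocks not conformable with the reference fit")
  gebv <- as.numeric(grm_vr %*% solve(grm_rr, fit$g_hat))
  names(gebv) <- rownames(grm_vr)
  gebv
}
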