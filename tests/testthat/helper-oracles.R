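# Independent oracles used across the suite. These deliberately take the
# slow, explicit route (double loops, dense inversion, quadrature) so they
# share no code path with the implementation they check.

# element-wise double-loop VanRaden G
grm_loop_oracle <- function(counts, freqs) {
  n <- nrow(counts); m <- ncol(counts)
  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    x <- counts[i, j]
    M[i, j] <- if (is.na(x)) 0 else x - 2 * freqs[j]
  }
  cc <- 0
  for (j in seq_len(m)) cc <- cc + 2 * freqs[j] * (1 - freqs[j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    G[i, k] <- sum(M[i, ] * M[k, ]) / cc
  G
}

# dense mixed-model-equation solve for y = 1mu + g + e, g ~ N(0, s2g G)
mme_oracle <- function(y, G, sigma2_g, sigma2_e) {
  n <- length(y)
  lambda <- sigma2_e / sigma2_g
  C <- rbind(c(n, rep(1, n)),
             cbind(rep(1, n), diag(n) + solve(G) * lambda))
  Cinv <- solve(C)
  sol <- Cinv %*% c(sum(y), y)
  list(mu_hat = sol[1], g_hat = as.numeric(sol[-1]),
       pev = unname(sigma2_e * Cinv[-1, -1]))
}

# joint MME over reference + validation animals, validation records missing
joint_mme_val_oracle <- function(y_ref, G_all, ref_idx, val_idx,
                                 sigma2_g, sigma2_e) {
  n_all <- nrow(G_all); n_r <- length(ref_idx)
  Z <- matrix(0, n_r, n_all)
  Z[cbind(seq_len(n_r), ref_idx)] <- 1
  lambda <- sigma2_e / sigma2_g
  C <- rbind(c(n_r, colSums(Z)),
             cbind(rowSums(t(Z)), crossprod(Z) + solve(G_all) * lambda))
  sol <- solve(C, c(sum(y_ref), as.numeric(crossprod(Z, y_ref))))
  as.numeric(sol[-1])[val_idx]
}

# marginal-likelihood ratio of the one-SNP model by numerical integration:
# LR = int N(y; m q, s2e I) N(q; 0, s2q) dq / N(y; 0, s2e I)
loglr_quadrature_oracle <- function(m_j, y_star, sigma2_q, sigma2_e) {
  log_f0 <- sum(dnorm(y_star, 0, sqrt(sigma2_e), log = TRUE))
  integrand <- function(q) {
    vapply(q, function(qq) {
      exp(sum(dnorm(y_star, m_j * qq, sqrt(sigma2_e), log = TRUE)) -
            log_f0) * dnorm(qq, 0, sqrt(sigma2_q))
    }, numeric(1))
  }
  hw <- 12 * sqrt(sigma2_q)
  log(integrate(integrand, -hw, hw, rel.tol = 1e-10)$value)
}

# exact posterior mean of a single spike-and-slab SNP effect by quadrature
single_snp_posterior_mean_oracle <- function(m_j, y, pi, sigma2_q, sigma2_e) {
  log_f0 <- sum(dnorm(y, 0, sqrt(sigma2_e), log = TRUE))
  lik <- function(qq) exp(sum(dnorm(y, m_j * qq, sqrt(sigma2_e),
                                    log = TRUE)) - log_f0)
  hw <- 12 * sqrt(sigma2_q)
  f1 <- integrate(function(q) vapply(q, function(qq)
    lik(qq) * dnorm(qq, 0, sqrt(sigma2_q)), numeric(1)),
    -hw, hw, rel.tol = 1e-10)$value
  num <- integrate(function(q) vapply(q, function(qq)
    qq * lik(qq) * dnorm(qq, 0, sqrt(sigma2_q)), numeric(1)),
    -hw, hw, rel.tol = 1e-10)$value
  pi * num / (pi * f1 + (1 - pi) * 1)
}

# small random genotype fixture; columns forced polymorphic so that
# centering never sees a degenerate frequency
random_geno <- function(n, m, seed = 1, miss_rate = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  counts <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss_rate > 0)
    counts[runif(length(counts)) < miss_rate] <- NA
  for (j in seq_len(m)) {
    v <- counts[, j]
    if (all(is.na(v)) || length(unique(v[!is.na(v)])) < 2)
      counts[1:2, j] <- c(0, 1)
  }
  genotype_matrix(counts)
}

tiny_scenario <- function(seed = 1, n_ref = 150, n_val = 30, m = 300,
                          ...) {
  make_scenario(sim_config(n_ref = n_ref, n_val = n_val, m_snps = m,
                           n_sires = 10, seed = seed, ...))
}

scenario_parts <- function(sc) {
  grm <- build_grm(sc$cg)
  list(grm = grm,
       y = sc$phenotypes$dyd[match(sc$ref_ids, sc$phenotypes$animal_id)],
       G_rr = gbcpred:::grm_block(grm, sc$ref_ids),
       G_vr = gbcpred:::grm_block(grm, sc$val_ids, sc$ref_ids),
       cg_ref = gbcpred:::subset_centered(sc$cg, sc$ref_ids),
       cg_val = gbcpred:::subset_centered(sc$cg, sc$val_ids),
       ph_val = sc$phenotypes[match(sc$val_ids, sc$phenotypes$animal_id), ])
}
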