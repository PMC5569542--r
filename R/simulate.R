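#' Simulation scenario configuration
#'
#' The default preset emulates a progeny-tested dairy population at desk
#' scale: 1000 reference and 124 validation bulls in half-sib families
#' (validation animals are offspring of reference sires, so their largest
#' genomic relationship to the reference set clusters near 0.5), 2000
#' unlinked SNPs with MAF in `[0.05, 0.5]`, a genetic architecture of two
#' large QTL (10% of the genetic variance each) on a polygenic
#' background, heritability 0.25, and effective daughter counts
#' `d_e ~ N(177, 31)` truncated at 108 — the regime of a typical
#' 50K-chip bull evaluation.
#'
#' @param n_ref,n_val reference and validation animal counts.
#' @param n_sires number of half-sib sires (0 = unrelated animals); the
#'   sires are members of the reference set.
#' @param m_snps number of SNPs before MAF filtering.
#' @param maf_range interval within (0, 0.5] from which SNP allele
#'   frequencies are drawn uniformly.
#' @param n_large_qtl number of large QTL.
#' @param large_qtl_fraction fraction of `sigma2_g` explained by each
#'   large QTL.
#' @param h2 heritability of the underlying trait.
#' @param sigma2_g genetic variance.
#' @param d_e_mean,d_e_sd,d_e_min effective-daughter-count distribution
#'   (normal, truncated below at `d_e_min`).
#' @param ld_blocks optional block size for an exchangeable-correlation
#'   LD mode (default 1 = unlinked SNPs).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_ref = 1000L, n_val = 124L, n_sires = 20L,
                       m_snps = 2000L, maf_range = c(0.05, 0.5),
                       n_large_qtl = 2L, large_qtl_fraction = 0.10,
                       h2 = 0.25, sigma2_g = 1,
                       d_e_mean = 177, d_e_sd = 31, d_e_min = 108,
                       ld_blocks = 1L, seed = 1L) {
  stopifnot(n_ref >= 1, n_val >= 1, n_sires >= 0, m_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_large_qtl >= 0, large_qtl_fraction >= 0,
            n_large_qtl * large_qtl_fraction <= 1,
            h2 > 0, h2 <= 1, sigma2_g > 0, d_e_mean > 0, d_e_sd >= 0,
            ld_blocks >= 1)
  structure(list(n_ref = as.integer(n_ref), n_val = as.integer(n_val),
                 n_sires = as.integer(n_sires), m_snps = as.integer(m_snps),
                 maf_range = as.numeric(maf_range),
                 n_large_qtl = as.integer(n_large_qtl),
                 large_qtl_fraction = large_qtl_fraction,
                 h2 = h2, sigma2_g = sigma2_g,
                 d_e_mean = d_e_mean, d_e_sd = d_e_sd, d_e_min = d_e_min,
                 ld_blocks = as.integer(ld_blocks), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes
#'
#' With `n_sires = 0`, allele counts are independent
#' `Binomial(2, p_j)` draws with `p_j ~ Uniform(maf_range)`. With
#' `n_sires > 0`, gene dropping in half-sib families: sires carry two
#' population haplotypes; every non-sire animal receives one gamete
#' sampled locus-by-locus from its sire and one population gamete.
#' Sires are the first `n_sires` reference animals, and validation
#' animals are offspring of reference sires, so validation-to-reference
#' `Relmax` on the VanRaden GRM clusters near 0.5. With `ld_blocks > 1`,
#' consecutive SNPs within a block share a latent gamete-level draw with
#' exchangeable correlation (a crude LD mode for qualitative
#' experiments).
#'
#' @param config a [sim_config()]; uses `config$seed`.
#' @return A [genotype_matrix()] with animal ids `ref...`/`val...`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps
  n <- config$n_ref + config$n_val
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  ids <- c(sprintf("ref%04d", seq_len(config$n_ref)),
           sprintf("val%04d", seq_len(config$n_val)))

  draw_gamete <- function(k) {
    # k haplotypes x m loci of Bernoulli(p_j) alleles; optional block LD
    # via a shared latent uniform per block
    if (config$ld_blocks <= 1L)
      matrix(rbinom(k * m, 1L, rep(p, each = k)), nrow = k)
    else {
      block <- (seq_len(m) - 1L) %/% config$ld_blocks
      u_block <- matrix(runif(k * (max(block) + 1L)), nrow = k)
      u <- 0.5 * u_block[, block + 1L, drop = FALSE] +
        0.5 * matrix(runif(k * m), nrow = k)
      (u < matrix(p, k, m, byrow = TRUE)) + 0L
    }
  }

  if (config$n_sires == 0L) {
    counts <- draw_gamete(n) + draw_gamete(n)
  } else {
    n_sires <- min(config$n_sires, config$n_ref)
    sire_h1 <- draw_gamete(n_sires)
    sire_h2 <- draw_gamete(n_sires)
    counts <- matrix(0L, n, m)
    counts[seq_len(n_sires), ] <- sire_h1 + sire_h2
    n_off <- n - n_sires
    sire_of <- sample.int(n_sires, n_off, replace = TRUE)
    pick <- matrix(runif(n_off * m) < 0.5, n_off, m)
    sire_gam <- ifelse(pick, sire_h1[sire_of, , drop = FALSE],
                       sire_h2[sire_of, , drop = FALSE])
    counts[(n_sires + 1L):n, ] <- sire_gam + draw_gamete(n_off)
  }
  genotype_matrix(counts, animal_ids = ids)
}

#' Simulate a trait architecture
#'
#' Picks `n_large_qtl` SNP columns uniformly (seeded sub-stream) and
#' sizes each large effect so its variance contribution
#' `q^2 var(M_j)` equals `large_qtl_fraction * sigma2_g` (random sign).
#' The remaining genetic variance is spread over all other SNPs as
#' i.i.d. normal effects. The polygenic background is drawn before the
#' QTL positions so it is unchanged by `n_large_qtl`.
#'
#' @param config a [sim_config()].
#' @param cg [center_genotypes()] of the simulated genotypes.
#' @return Numeric effect vector (length m, named by SNP) with attribute
#'   `qtl_idx` giving the large-QTL column indices.
#' @export
simulate_architecture <- function(config, cg) {
  stopifnot(inherits(config, "sim_config"),
            inherits(cg, "centered_genotypes"),
            config$n_large_qtl <= ncol(cg$M))
  qtl_var_total <- config$n_large_qtl * config$large_qtl_fraction *
    config$sigma2_g
  if (qtl_var_total > config$sigma2_g)
    stop("large-QTL variance exceeds sigma2_g")
  set.seed(config$seed + 1L)
  m <- ncol(cg$M)
  col_var <- apply(cg$M, 2L, var)
  effects <- rnorm(m)
  qtl_idx <- if (config$n_large_qtl > 0L)
    sample.int(m, config$n_large_qtl) else integer(0)
  poly_idx <- setdiff(seq_len(m), qtl_idx)
  poly_var_total <- config$sigma2_g - qtl_var_total
  if (length(poly_idx) && poly_var_total > 0) {
    sigma2_poly <- poly_var_total / sum(col_var[poly_idx])
    effects[poly_idx] <- effects[poly_idx] * sqrt(sigma2_poly)
  } else {
    effects[poly_idx] <- 0
  }
  if (length(qtl_idx)) {
    signs <- sample(c(-1, 1), length(qtl_idx), replace = TRUE)
    effects[qtl_idx] <- signs *
      sqrt(config$large_qtl_fraction * config$sigma2_g / col_var[qtl_idx])
  }
  names(effects) <- colnames(cg$M)
  attr(effects, "qtl_idx") <- qtl_idx
  effects
}

#' Simulate DYD-like phenotypes
#'
#' `DYD_i = TBV_i + eps_i` with noise variance
#' `sigma2_g (1 - r2_i) / r2_i`, where `r2_i = d_e_i / (d_e_i + K)` is
#' the target reliability of animal i and `d_e_i` is a truncated-normal
#' effective daughter count. By construction
#' `cor(DYD, TBV)^2` approaches `r2` in large samples.
#'
#' @param tbv named true-breeding-value vector.
#' @param config a [sim_config()].
#' @return A [phenotype_table()] with columns `animal_id`, `dyd`, `d_e`,
#'   `reliability`.
#' @export
simulate_phenotypes <- function(tbv, config) {
  stopifnot(inherits(config, "sim_config"), !is.null(names(tbv)))
  set.seed(config$seed + 2L)
  n <- length(tbv)
  d_e <- rnorm(n, config$d_e_mean, config$d_e_sd)
  for (i in seq_len(50L)) {           # truncated normal by redraw
    low <- d_e < config$d_e_min
    if (!any(low)) break
    d_e[low] <- rnorm(sum(low), config$d_e_mean, config$d_e_sd)
  }
  d_e <- pmax(d_e, config$d_e_min)
  r2 <- dyd_reliability(d_e, config$h2)
  noise_var <- config$sigma2_g * (1 - r2) / r2
  phenotype_table(data.frame(
    animal_id = names(tbv),
    dyd = as.numeric(tbv) + rnorm(n, 0, sqrt(noise_var)),
    d_e = d_e, reliability = r2,
    stringsAsFactors = FALSE))
}

#' Build a complete simulated scenario
#'
#' Composes [simulate_genotypes()], a MAF filter at 0.05,
#' [simulate_architecture()] and [simulate_phenotypes()], and returns the
#' bundle together with the reference/validation split and the quantities
#' a fitting engine needs (`params` with `sigma2_e` set to the mean DYD
#' noise variance).
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset`: list with `genotypes`, `cg`
#'   ([center_genotypes()] of the filtered set), `tbv`, `qtl_effects`
#'   (with `qtl_idx` attribute), `phenotypes`, `ref_ids`, `val_ids`,
#'   `params` ([trait_params()]), and `config`.
#' @export
make_scenario <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  geno <- filter_by_maf(geno, 0.05)
  cg <- center_genotypes(geno)
  effects <- simulate_architecture(config, cg)
  tbv <- as.numeric(cg$M %*% effects)
  names(tbv) <- rownames(cg$M)
  phen <- simulate_phenotypes(tbv, config)
  sigma2_e <- mean(config$sigma2_g * (1 - phen$reliability) /
                     phen$reliability)
  structure(list(
    genotypes = geno, cg = cg, tbv = tbv, qtl_effects = effects,
    phenotypes = phen,
    ref_ids = grep("^ref", rownames(cg$M), value = TRUE),
    val_ids = grep("^val", rownames(cg$M), value = TRUE),
    params = trait_params(config$h2, config$sigma2_g, sigma2_e),
    config = config), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d ref + %d val animals, %d SNPs, %d large QTL\n",
              length(x$ref_ids), length(x$val_ids), ncol(x$cg$M),
              length(attr(x$qtl_effects, "qtl_idx"))))
  invisible(x)
}
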