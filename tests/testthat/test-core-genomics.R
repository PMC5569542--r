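test_that("allele frequencies count alleles over non-missing calls", {
  g <- genotype_matrix(cbind(a = c(0, 1, 2, 2, NA),
                             b = c(0, 1, 2, 0, 1),
                             c = c(2, 2, 2, 2, 2)))
  p <- allele_frequencies(g)
  expect_equal(unname(p["a"]), 5 / 8)   # 5 alt alleles over 8 chromosomes
  expect_equal(unname(p["b"]), 4 / 10)
  expect_equal(unname(p["c"]), 1.0)
  expect_true(all(p >= 0 & p <= 1))

  g2 <- genotype_matrix(cbind(x = c(0, 1, 2), y = c(NA, NA, NA)))
  expect_error(allele_frequencies(g2), "y")
})

test_that("genotype_matrix validates entries and identifiers", {
  expect_error(genotype_matrix(cbind(c(0, 3))), "not in \\{0,1,2,NA\\}")
  expect_error(genotype_matrix(cbind(a = 0:1, b = 0:1),
                               animal_ids = c("x", "x")),
               "duplicate animal")
  expect_error(genotype_matrix(matrix(0:1, 2, 2), snp_ids = c("s", "s")),
               "duplicate SNP")
})

test_that("MAF filter keeps the boundary and preserves order", {
  # 50 animals = 100 chromosomes: engineer p = 0.04, 0.05, 0.5 exactly
  g <- genotype_matrix(cbind(s1 = c(rep(1, 4), rep(0, 46)),
                             s2 = c(rep(1, 5), rep(0, 45)),
                             s3 = rep(1, 50)))
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(0.04, 0.05, 0.5))
  kept <- filter_by_maf(g, 0.05)
  expect_identical(colnames(kept$counts), c("s2", "s3"))  # boundary kept
  expect_identical(rownames(kept$counts), rownames(g$counts))

  expect_identical(filter_by_maf(g, 0)$counts, g$counts)  # identity at 0
  mono <- genotype_matrix(cbind(m = rep(0, 10), s = rep(c(0, 1), 5)))
  expect_identical(colnames(filter_by_maf(mono, 0.05)$counts), "s")
  expect_error(filter_by_maf(genotype_matrix(cbind(m = rep(2, 5))), 0.05),
               "threshold")
})

test_that("centering subtracts 2p and imputes missing to the mean", {
  g <- genotype_matrix(cbind(a = c(0, 2), b = c(1, NA)))
  cg <- center_genotypes(g, freqs = c(0.5, 0.5))
  expect_equal(unname(cg$M[, "a"]), c(-1, 1))
  expect_equal(unname(cg$M[, "b"]), c(0, 0))   # 1 - 2*0.5; NA -> 0
  expect_equal(cg$scale_c, 1.0)                # 2*(0.25 + 0.25)
  expect_error(center_genotypes(g, freqs = c(0, 0.5)), "degenerate")
})

test_that("column sums of M vanish for complete self-computed frequencies", {
  g <- random_geno(40, 25, seed = 7)
  cg <- center_genotypes(g)
  expect_true(all(abs(colSums(cg$M)) < 1e-9 * nrow(cg$M)))
  expect_equal(cg$scale_c, 2 * sum(cg$freqs * (1 - cg$freqs)),
               tolerance = 1e-12)
})

test_that("filter then recompute frequencies respects the threshold", {
  g <- random_geno(60, 50, seed = 21, miss_rate = 0.02)
  f <- filter_by_maf(g, 0.2)
  p <- allele_frequencies(f)
  expect_true(all(pmin(p, 1 - p) >= 0.2))
})

test_that("GRM matches spec worked example and the double-loop oracle", {
  g <- genotype_matrix(rbind(c(0, 2), c(1, 1), c(2, 0)))
  cg <- center_genotypes(g, freqs = c(0.5, 0.5))
  G <- build_grm(cg)$values
  expect_equal(unname(G),
               rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)))

  for (seed in 1:3) {
    gg <- random_geno(12, 30, seed = seed, miss_rate = 0.05)
    p <- allele_frequencies(gg)
    got <- build_grm(center_genotypes(gg, p))$values
    expect_equal(unname(got), grm_loop_oracle(gg$counts, p),
                 tolerance = 1e-10)
    expect_true(all(abs(got - t(got)) < 1e-10))
    ev <- eigen(got, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-8 * max(ev))
    expect_true(all(diag(got) >= 0))
  }

  hets <- genotype_matrix(matrix(1, 4, 6))
  expect_equal(unname(build_grm(center_genotypes(hets,
                                                 rep(0.5, 6)))$values),
               matrix(0, 4, 4))
})

test_that("relatedness summary follows the footnote definitions", {
  # single reference animal: all four measures collapse
  v <- diag(3); dimnames(v) <- list(letters[1:3], letters[1:3])
  v["a", "b"] <- v["b", "a"] <- 0.3
  grm1 <- structure(list(values = v, scale_c = 1), class = "grm")
  rs <- relatedness_summary(grm1, "a", "b")
  expect_equal(rs$meanRel, 0.3)
  expect_equal(rs$Relmax, 0.3)
  expect_equal(rs$Rel5, 0.3)
  expect_equal(rs$Rel10, 0.3)
  expect_true(attr(rs, "truncated"))

  # worked example: top-5 absolute mean
  rel <- c(0.5, 0.25, 0.1, 0, 0, 0)
  vv <- diag(7)
  vv[1, 2:7] <- vv[2:7, 1] <- rel
  dimnames(vv) <- list(paste0("i", 1:7), paste0("i", 1:7))
  grm2 <- structure(list(values = vv, scale_c = 1), class = "grm")
  rs2 <- relatedness_summary(grm2, "i1", paste0("i", 2:7))
  expect_equal(rs2$Relmax, 0.5)
  expect_equal(rs2$Rel5, 0.17)

  expect_error(relatedness_summary(grm2, "i1", c("i1", "i2")), "overlap")
})

test_that("absolute-relationship ordering and meanRel bound hold on random GRMs", {
  # Rel5/Rel10 use absolute values, so the ordering invariant is stated
  # against the absolute row maximum; Relmax itself is the signed maximum
  # and bounds meanRel from above.
  for (seed in 1:5) {
    g <- random_geno(30, 60, seed = seed)
    grm <- build_grm(center_genotypes(g))
    ids <- rownames(grm$values)
    rs <- relatedness_summary(grm, ids[1:5], ids[6:30])
    abs_max <- apply(abs(grm$values[ids[1:5], ids[6:30]]), 1L, max)
    expect_true(all(abs_max >= rs$Rel5 - 1e-12))
    expect_true(all(rs$Rel5 >= rs$Rel10 - 1e-12))
    expect_true(all(rs$meanRel <= rs$Relmax + 1e-12))
  }
})
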