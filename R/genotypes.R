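#' Genotype matrix container
#'
#' Holds raw alternative-allele counts for a set of animals at a set of
#' biallelic SNPs. Entries are 0 (reference homozygote), 1 (heterozygote),
#' 2 (alternative homozygote) or `NA` (missing call).
#'
#' @param counts numeric matrix, animals in rows and SNPs in columns;
#'   non-missing entries must be 0, 1 or 2.
#' @param animal_ids character vector of unique animal identifiers
#'   (defaults to rownames of `counts`).
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   colnames of `counts`).
#' @param chrom,pos optional per-SNP chromosome labels and 1-based
#'   positions.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts` (the matrix, dimnames set), `chrom` and `pos`.
#' @export
genotype_matrix <- function(counts, animal_ids = rownames(counts),
                            snp_ids = colnames(counts),
                            chrom = NULL, pos = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(animal_ids)) animal_ids <- paste0("animal", seq_len(nrow(counts)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(counts)))
  animal_ids <- as.character(animal_ids)
  snp_ids <- as.character(snp_ids)
  if (length(animal_ids) != nrow(counts))
    stop("length(animal_ids) must equal nrow(counts)")
  if (length(snp_ids) != ncol(counts))
    stop("length(snp_ids) must equal ncol(counts)")
  if (anyDuplicated(animal_ids))
    stop("duplicate animal ids: ", animal_ids[duplicated(animal_ids)][1L])
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ", snp_ids[duplicated(snp_ids)][1L])
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype entry not in {0,1,2,NA}: value %s at animal '%s', SNP '%s'",
                 format(counts[idx[1L], idx[2L]]),
                 animal_ids[idx[1L]], snp_ids[idx[2L]]))
  }
  if (!is.null(chrom) && length(chrom) != ncol(counts))
    stop("chrom must have one entry per SNP")
  if (!is.null(pos) && length(pos) != ncol(counts))
    stop("pos must have one entry per SNP")
  dimnames(counts) <- list(animal_ids, snp_ids)
  structure(list(counts = counts, chrom = chrom, pos = pos),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs (%d missing calls)\n",
              nrow(x$counts), ncol(x$counts), sum(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

animal_ids <- function(geno) rownames(geno$counts)
snp_ids <- function(geno) colnames(geno$counts)

#' Alternative-allele frequencies
#'
#' Computes, per SNP, the frequency of the alternative allele over all
#' non-missing calls: `p_j = sum(x_ij) / (2 * n_nonmissing)`.
#'
#' @param geno a [genotype_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  counts <- geno$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("empty genotype matrix")
  n_called <- colSums(!is.na(counts))
  if (any(n_called == 0L))
    stop("SNP(s) with no non-missing calls: ",
         paste(colnames(counts)[n_called == 0L][1:min(5, sum(n_called == 0L))],
               collapse = ", "))
  colSums(counts, na.rm = TRUE) / (2 * n_called)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency `min(p_j, 1 - p_j)` is at
#' least `threshold`; the boundary value is kept (only frequencies strictly
#' below the threshold are discarded). Animal set and column order are
#' preserved.
#'
#' @param geno a [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5)`; the conventional value
#'   for 50K-chip data is 0.05.
#' @return A filtered [genotype_matrix()].
#' @export
filter_by_maf <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"),
            threshold >= 0, threshold < 0.5)
  p <- allele_frequencies(geno)
  keep <- pmin(p, 1 - p) >= threshold
  if (!any(keep))
    stop("no SNPs pass the MAF filter at threshold ", threshold,
         "; reduce the threshold")
  genotype_matrix(geno$counts[, keep, drop = FALSE],
                  chrom = geno$chrom[keep], pos = geno$pos[keep])
}

#' Center genotypes around twice the allele frequency
#'
#' Builds the scaled design matrix `M_ij = x_ij - 2 p_j` used by all three
#' prediction engines, together with the VanRaden scaling constant
#' `c = 2 * sum_j p_j (1 - p_j)`. Missing calls are imputed to the column
#' mean `2 p_j`, i.e. to 0 after centering.
#'
#' @param geno a [genotype_matrix()].
#' @param freqs allele frequencies (defaults to [allele_frequencies()] of
#'   `geno`); must be strictly inside (0, 1) — filter monomorphic SNPs
#'   first.
#' @return An object of class `centered_genotypes`: list with `M`
#'   (numeric matrix, dimnames kept), `freqs` and `scale_c`.
#' @export
center_genotypes <- function(geno, freqs = allele_frequencies(geno)) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- ncol(geno$counts)
  if (length(freqs) != m)
    stop("freqs must have one entry per SNP")
  if (any(freqs <= 0 | freqs >= 1))
    stop("degenerate allele frequency (0 or 1); apply filter_by_maf first")
  M <- sweep(geno$counts, 2L, 2 * freqs, `-`)
  M[is.na(M)] <- 0
  structure(list(M = M, freqs = as.numeric(freqs),
                 scale_c = 2 * sum(freqs * (1 - freqs))),
            class = "centered_genotypes")
}

#' @export
print.centered_genotypes <- function(x, ...) {
  cat(sprintf("centered_genotypes: %d x %d, scale_c = %.4f\n",
              nrow(x$M), ncol(x$M), x$scale_c))
  invisible(x)
}

subset_centered <- function(cg, ids) {
  stopifnot(all(ids %in% rownames(cg$M)))
  structure(list(M = cg$M[ids, , drop = FALSE], freqs = cg$freqs,
                 scale_c = cg$scale_c),
            class = "centered_genotypes")
}
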