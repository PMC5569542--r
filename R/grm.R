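#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / c` with `M` the centered genotypes and
#' `c = 2 * sum_j p_j (1 - p_j)`. In the prediction pipelines G is built
#' from all animals (reference and validation together) so that the
#' validation block is available for projection.
#'
#' @param cg a [center_genotypes()] result.
#' @return An object of class `grm`: list with `values` (symmetric
#'   n x n matrix with animal-id dimnames) and `scale_c`.
#' @export
build_grm <- function(cg) {
  stopifnot(inherits(cg, "centered_genotypes"))
  if (!(cg$scale_c > 0)) stop("scale_c must be strictly positive")
  G <- tcrossprod(cg$M) / cg$scale_c
  G <- (G + t(G)) / 2   # enforce exact symmetry against FP drift
  structure(list(values = G, scale_c = cg$scale_c), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, mean diagonal %.4f\n",
              nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

grm_block <- function(grm, row_ids, col_ids = row_ids) {
  v <- grm$values
  miss <- setdiff(c(row_ids, col_ids), rownames(v))
  if (length(miss))
    stop("ids absent from GRM: ", paste(head(miss, 5L), collapse = ", "))
  v[row_ids, col_ids, drop = FALSE]
}

#' Genomic relatedness of validation animals to a reference set
#'
#' For each validation animal i and the reference animals j, summarises the
#' GRM row `rel(i, j)`: `meanRel` (plain mean), `Relmax` (signed maximum),
#' and `Rel5` / `Rel10` (mean of the 5 / 10 largest absolute
#' relationships). In half-sib populations `Relmax` near 0.5 indicates the
#' sire is in the reference set.
#'
#' @param grm a [build_grm()] result containing both id sets.
#' @param validation_ids,reference_ids disjoint, non-empty id vectors.
#' @return An object of class `relatedness_summary`: a data.frame with one
#'   row per validation animal and columns `animal_id`, `meanRel`,
#'   `Relmax`, `Rel5`, `Rel10`, plus attributes `group_mean`, `group_sd`
#'   and `truncated` (TRUE when fewer reference animals than 10).
#' @export
relatedness_summary <- function(grm, validation_ids, reference_ids) {
  stopifnot(inherits(grm, "grm"),
            length(validation_ids) > 0, length(reference_ids) > 0)
  if (length(intersect(validation_ids, reference_ids)))
    stop("validation and reference id sets overlap")
  R <- grm_block(grm, validation_ids, reference_ids)
  top_mean <- function(r, k) {
    a <- sort(abs(r), decreasing = TRUE)
    mean(a[seq_len(min(k, length(a)))])
  }
  out <- data.frame(
    animal_id = validation_ids,
    meanRel = rowMeans(R),
    Relmax = apply(R, 1L, max),
    Rel5 = apply(R, 1L, top_mean, k = 5L),
    Rel10 = apply(R, 1L, top_mean, k = 10L),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "group_mean") <- colMeans(out[, -1L])
  attr(out, "group_sd") <- vapply(out[, -1L], sd, numeric(1))
  attr(out, "truncated") <- length(reference_ids) < 10L
  class(out) <- c("relatedness_summary", "data.frame")
  out
}
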