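#' Phenotype table
#'
#' @param df data.frame with columns `animal_id`, `dyd`, `d_e` (and
#'   optionally `reliability`).
#' @return A `phenotype_table` (data.frame subclass).
#' @export
phenotype_table <- function(df) {
  need <- c("animal_id", "dyd", "d_e")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$animal_id <- as.character(df$animal_id)
  if (anyDuplicated(df$animal_id))
    stop("duplicate animal ids in phenotype table: ",
         df$animal_id[duplicated(df$animal_id)][1L])
  if (any(!is.finite(df$d_e)) || any(df$d_e < 0))
    stop("d_e must be finite and non-negative")
  if (!is.null(df$reliability) &&
      any(df$reliability < 0 | df$reliability > 1))
    stop("reliability must lie in [0, 1]")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a genotype matrix from file
#'
#' Two dialects are accepted and auto-detected from the header line:
#'
#' * delimited matrix — header of SNP ids, first column the animal id,
#'   entries 0/1/2/NA; tab- or comma-separated (sniffed);
#' * PLINK RAW (`--recode A`) — columns `FID IID PAT MAT SEX PHENOTYPE`
#'   followed by per-SNP allele counts; `IID` becomes the animal id and
#'   the trailing allele tag of the SNP name (e.g. `snp1_A`) is kept
#'   as-is.
#'
#' @param path file path.
#' @param format_hint `"auto"` (default), `"delim"` or `"raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format_hint = c("auto", "delim", "raw")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
         else " "
  toks <- strsplit(header, sep, fixed = TRUE)[[1L]]
  fmt <- if (format_hint != "auto") format_hint
         else if (length(toks) >= 2L && toupper(toks[1L]) == "FID" &&
                  toupper(toks[2L]) == "IID") "raw" else "delim"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1L),
                          na.strings = c("NA", "na", ""))
  if (fmt == "raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(toupper(names(dt)[1:6]) == meta))
      stop("PLINK RAW header must start with FID IID PAT MAT SEX PHENOTYPE")
    ids <- as.character(dt[[2L]])
    counts <- as.matrix(dt[, -(1:6)])
  } else {
    ids <- dt[[1L]]
    counts <- as.matrix(dt[, -1L])
  }
  if (!is.numeric(counts)) {
    bad <- which(!apply(counts, 2L, function(col)
      all(is.na(col) | col %in% c("0", "1", "2"))))[1L]
    row <- which(!(is.na(counts[, bad]) | counts[, bad] %in% c("0", "1", "2")))[1L]
    stop(sprintf("unparseable genotype token '%s' at row %d (animal '%s'), column '%s'",
                 counts[row, bad], row, ids[row], colnames(counts)[bad]))
  }
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype value %s not in {0,1,2,NA} at row %d (animal '%s'), column '%s'",
                 format(counts[idx[1L], idx[2L]]), idx[1L], ids[idx[1L]],
                 colnames(counts)[idx[2L]]))
  }
  genotype_matrix(counts, animal_ids = ids)
}

#' Write a genotype matrix (canonical tab-separated dialect)
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dt <- data.table::data.table(animal_id = rownames(geno$counts))
  dt <- cbind(dt, data.table::as.data.table(geno$counts))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a delimited file with header columns `animal_id`, `dyd`, `de`
#' (or `d_e`); extra columns are ignored with a message.
#'
#' @param path file path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = 1L))
  names(dt)[names(dt) == "de"] <- "d_e"
  need <- c("animal_id", "dyd", "d_e")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("phenotype file missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(dt), c(need, "reliability"))
  if (length(extra))
    message("ignoring extra phenotype column(s): ",
            paste(extra, collapse = ", "))
  phenotype_table(as.data.frame(dt[, intersect(c(need, "reliability"),
                                               names(dt)), with = FALSE]))
}

#' Write a phenotype table
#' @param phen a [phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  stopifnot(inherits(phen, "phenotype_table"))
  out <- phen
  names(out)[names(out) == "d_e"] <- "de"
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a genomic relationship matrix
#'
#' @param grm a [build_grm()] result.
#' @param path output path.
#' @param lower_triangle write only the lower triangle in long format
#'   (`id1, id2, rel`); otherwise the full matrix with an id header.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, lower_triangle = FALSE) {
  stopifnot(inherits(grm, "grm"))
  v <- grm$values
  if (lower_triangle) {
    idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
    dt <- data.table::data.table(
      id1 = rownames(v)[idx[, 1L]], id2 = colnames(v)[idx[, 2L]],
      rel = signif(v[idx], 6L))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  } else {
    dt <- data.table::data.table(animal_id = rownames(v))
    dt <- cbind(dt, data.table::as.data.table(signif(v, 6L)))
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Write a GEBV table
#' @param gebv named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gebv <- function(gebv, path) {
  stopifnot(!is.null(names(gebv)))
  data.table::fwrite(
    data.table::data.table(animal_id = names(gebv),
                           gebv = signif(as.numeric(gebv), 6L)),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a GEBV table written by [write_gebv()]
#' @param path file path.
#' @return Named numeric vector.
#' @export
read_gebv <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = 1L))
  out <- as.numeric(dt$gebv)
  names(out) <- dt$animal_id
  out
}

#' Write per-SNP effect summaries
#'
#' Columns: `snp_id`, `q_hat`, and `postprob` (GBC) or `inclusion_prob`
#' (Bayes-C) — the data behind per-chromosome effect plots.
#'
#' @param fit a `gbc_fit` or `bayesc_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_effects <- function(fit, path) {
  dt <- if (inherits(fit, "gbc_fit"))
    data.table::data.table(snp_id = fit$snp_ids,
                           q_hat = signif(fit$q_hat, 6L),
                           postprob = signif(fit$postprob, 6L))
  else if (inherits(fit, "bayesc_fit"))
    data.table::data.table(snp_id = fit$snp_ids,
                           q_hat = signif(fit$q_hat, 6L),
                           inclusion_prob = signif(fit$inclusion_prob, 6L))
  else stop("fit must be a gbc_fit or bayesc_fit")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param summary named list (method, hyperparameters, convergence, seed,
#'   timing, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
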