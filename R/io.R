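write_tsv <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rownames_col),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a cohort dataset as plain TSV files
#'
#' Writes `<id>_beta.tsv` (rows = CpG ids, columns = sample ids),
#' `<id>_pheno.tsv` (sample id, time, event, covariates),
#' `<id>_truth.tsv` and `<id>_cellfrac.tsv`.
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- cohort$cohort_id
  p <- file.path(dir, paste0(id, c("_beta.tsv", "_pheno.tsv",
                                   "_truth.tsv", "_cellfrac.tsv")))
  write_tsv(as.data.frame(cohort$beta), p[1], rownames_col = "cpg_id")
  pheno <- cbind(cohort$covariates[, "sample_id", drop = FALSE],
                 time = cohort$time, event = cohort$event,
                 cohort$covariates[, -1, drop = FALSE])
  write_tsv(pheno, p[2])
  write_tsv(data.frame(cpg_id = names(cohort$truth),
                       true_loghr = unname(cohort$truth)), p[3])
  write_tsv(as.data.frame(cohort$cell_fractions_true), p[4],
            rownames_col = "sample_id")
  invisible(p)
}

#' Read a cohort dataset written by [write_cohort_tsv()]
#' @param dir directory holding the files.
#' @param cohort_id cohort identifier (file prefix).
#' @return a `cohort_dataset`.
#' @export
read_cohort_tsv <- function(dir, cohort_id) {
  pre <- file.path(dir, cohort_id)
  b <- utils::read.delim(paste0(pre, "_beta.tsv"), check.names = FALSE)
  beta <- as.matrix(b[, -1, drop = FALSE])
  rownames(beta) <- b$cpg_id
  pheno <- utils::read.delim(paste0(pre, "_pheno.tsv"),
                             stringsAsFactors = TRUE)
  pheno$sample_id <- as.character(pheno$sample_id)
  truth <- utils::read.delim(paste0(pre, "_truth.tsv"))
  cf <- utils::read.delim(paste0(pre, "_cellfrac.tsv"), check.names = FALSE)
  frac <- as.matrix(cf[, -1, drop = FALSE])
  rownames(frac) <- cf$sample_id
  cov <- pheno[, setdiff(names(pheno), c("time", "event")), drop = FALSE]
  structure(list(cohort_id = cohort_id, beta = beta, covariates = cov,
                 time = pheno$time, event = pheno$event,
                 cell_fractions_true = frac,
                 truth = stats::setNames(truth$true_loghr, truth$cpg_id)),
            class = "cohort_dataset")
}

#' Write GWAS summary statistics as TSV
#' @param summaries list with `exposure` and `outcome` data frames.
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly, the two paths.
#' @export
write_mr_tsv <- function(summaries, dir, prefix = "mr") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c("_exposure.tsv", "_outcome.tsv")))
  write_tsv(summaries$exposure, p[1])
  write_tsv(summaries$outcome, p[2])
  invisible(p)
}
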