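#' Pipeline run configuration
#'
#' @param stages character vector of stages to execute, in canonical order:
#'   simulate, qc, ewas, meta, paf, mr, deconv, qtl, enrich, clock.
#' @param out_dir directory for stage outputs (TSV interchange).
#' @param model covariate set for the survival fits.
#' @param sim a [sim_config()] for the simulate stage.
#' @param min_cohorts,iqr_min,max_missing probe-QC thresholds.
#' @param meta_min_cohorts minimum cohorts per pooled CpG.
#' @param fdr_q significance level for multiplicity control.
#' @param retain_p,sig_p meQTL thresholds.
#' @param cis_bp eQTM cis/trans cutoff.
#' @param seed master seed; every stage derives its randomness from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "qc", "ewas", "meta", "paf",
                                  "mr", "deconv", "qtl", "enrich", "clock"),
                       out_dir = tempfile("survewas_run_"),
                       model = c("full", "basic"),
                       sim = sim_config(),
                       min_cohorts = 4L, iqr_min = 0.001, max_missing = 0.10,
                       meta_min_cohorts = 3L, fdr_q = 0.05,
                       retain_p = 1e-4, sig_p = 1e-14, cis_bp = 500000,
                       seed = 1L) {
  model <- match.arg(model)
  known <- c("simulate", "qc", "ewas", "meta", "paf", "mr", "deconv",
             "qtl", "enrich", "clock")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(fdr_q > 0, fdr_q < 1, retain_p > 0, retain_p <= 1,
            sig_p > 0, sig_p <= 1, cis_bp >= 0, min_cohorts >= 1,
            iqr_min >= 0, max_missing > 0, max_missing <= 1)
  structure(list(stages = known[known %in% stages], out_dir = out_dir,
                 model = model, sim = sim, min_cohorts = min_cohorts,
                 iqr_min = iqr_min, max_missing = max_missing,
                 meta_min_cohorts = meta_min_cohorts, fdr_q = fdr_q,
                 retain_p = retain_p, sig_p = sig_p, cis_bp = cis_bp,
                 seed = as.integer(seed)),
            class = "run_config")
}

dependency_error <- function(stage, missing) {
  stop(structure(class = c("survewas_dependency_error", "error",
                           "condition"),
                 list(message = sprintf(
                   "stage '%s' missing upstream output: %s", stage,
                   paste(missing, collapse = ", ")),
                   call = NULL)))
}

require_files <- function(stage, paths) {
  miss <- paths[!file.exists(paths)]
  if (length(miss)) dependency_error(stage, miss)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

stage_log <- function(stage, t0) {
  message(sprintf("[survewas] %-8s done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in canonical order with plain-TSV
#' interchange between them: simulate cohorts; probe QC; per-cohort EWAS
#' (with two-step auto-selection); IVW meta-analysis plus leave-one-out,
#' cohort-exclusion sensitivity and inflation diagnostics; attributable
#' fractions for the top CpGs; two-sample MR on simulated summary
#' statistics; cell deconvolution and NLR models; meQTL/eQTM scans;
#' genomic-feature enrichment; and synthetic-clock scoring with adjusted
#' mortality models.  A stage whose upstream outputs are absent raises a
#' typed dependency error naming the stage.
#'
#' @param config a [run_config()].
#' @return the run manifest (invisibly written to
#'   `<out_dir>/manifest.tsv`): list with the config hash, seed, package
#'   version, executed stages, and per-stage row counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  counts <- list()
  cohort_ids <- sprintf("cohort%02d", seq_len(config$sim$n_cohorts))
  ids <- cpg_ids(config$sim$n_cpgs)
  annot_path <- file.path(od, "annotation.tsv")
  ref <- generate_reference_matrix(n_cpgs = config$sim$n_cpgs,
                                   seed = config$sim$seed)

  for (stage in config$stages) {
    t0 <- as.numeric(Sys.time())
    switch(stage,
      simulate = {
        cohorts <- generate_cohorts(config$sim, ref)
        for (co in cohorts) write_cohort_tsv(co, od)
        write_tsv(simulate_probe_annotation(ids, seed = config$sim$seed),
                  annot_path)
        counts$simulate <- length(cohorts) * config$sim$n_cpgs
      },
      qc = {
        require_files("qc", c(annot_path,
                              file.path(od, paste0(cohort_ids[1],
                                                   "_beta.tsv"))))
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        annot <- read_probe_annotation(annot_path)
        qc <- filter_probes(cohorts, annot,
                            min_cohorts = min(config$min_cohorts,
                                              length(cohorts)),
                            iqr_min = config$iqr_min,
                            max_missing = config$max_missing)
        write_tsv(data.frame(cpg_id = qc$kept), file.path(od, "kept.tsv"))
        write_tsv(data.frame(rule = names(qc$counts),
                             excluded = unname(qc$counts)),
                  file.path(od, "qc_report.tsv"))
        counts$qc <- length(qc$kept)
      },
      ewas = {
        require_files("ewas", file.path(od, "kept.tsv"))
        kept <- utils::read.delim(file.path(od, "kept.tsv"))$cpg_id
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        res <- do.call(rbind, lapply(cohorts, function(co)
          run_cohort_ewas(co, model = config$model,
                          cpg_ids = intersect(kept, rownames(co$beta)))))
        write_tsv(res, file.path(od, "ewas_results.tsv"))
        counts$ewas <- nrow(res)
      },
      meta = {
        require_files("meta", file.path(od, "ewas_results.tsv"))
        res <- utils::read.delim(file.path(od, "ewas_results.tsv"))
        ma <- meta_analyze(res, min_cohorts = config$meta_min_cohorts,
                           alpha = config$fdr_q)
        write_tsv(ma$meta, file.path(od, "meta_results.tsv"))
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        cstats <- do.call(rbind, lapply(cohorts, function(co) {
          p <- res$pval[res$cohort_id == co$cohort_id & res$converged]
          data.frame(cohort_id = co$cohort_id,
                     death_prop = mean(co$event),
                     lambda = if (length(p)) genomic_inflation(p)
                              else NA_real_)
        }))
        write_tsv(cstats, file.path(od, "cohort_stats.tsv"))
        sens <- tryCatch(
          sensitivity_exclusion(cstats, res,
                                min_cohorts = config$meta_min_cohorts),
          error = function(e) NULL)
        if (!is.null(sens) && !is.null(sens$meta))
          write_tsv(sens$meta, file.path(od, "meta_sensitivity.tsv"))
        top <- ma$meta$cpg_id[ma$meta$fdr_sig]
        if (length(top)) {
          loo <- do.call(rbind, lapply(top, function(cid)
            leave_one_out(res[res$cpg_id == cid, ],
                          min_cohorts = config$meta_min_cohorts)))
          if (!is.null(loo) && nrow(loo))
            write_tsv(loo, file.path(od, "meta_leave_one_out.tsv"))
        }
        writeLines(format(ma$lambda, digits = 10),
                   file.path(od, "lambda.txt"))
        counts$meta <- nrow(ma$meta)
      },
      paf = {
        require_files("paf", file.path(od, "meta_results.tsv"))
        meta <- utils::read.delim(file.path(od, "meta_results.tsv"))
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        top <- meta$cpg_id[order(meta$pval)][seq_len(min(5, nrow(meta)))]
        paf <- do.call(rbind, lapply(cohorts, function(co)
          do.call(rbind, lapply(top, function(cid) {
            r <- paf_from_cohort(co, cid, model = config$model)
            data.frame(cpg_id = cid, cohort_id = co$cohort_id,
                       pc = r$pc, rr = r$rr, paf = r$paf)
          }))))
        write_tsv(paf, file.path(od, "paf.tsv"))
        counts$paf <- nrow(paf)
      },
      mr = {
        mr_sum <- generate_mr_summaries(n_snps = 30, true_effect = 0.3,
                                        pleiotropy_frac = 0.2,
                                        pleiotropy_mean = 0.05,
                                        seed = config$seed + 101L)
        write_mr_tsv(mr_sum, od)
        set <- harmonize(mr_sum$exposure, mr_sum$outcome)
        mr_res <- mr_all_methods(set, n_boot = 200, seed = config$seed)
        write_tsv(mr_res, file.path(od, "mr_results.tsv"))
        counts$mr <- nrow(mr_res)
      },
      deconv = {
        require_files("deconv", file.path(od, paste0(cohort_ids[1],
                                                     "_beta.tsv")))
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        dec <- do.call(rbind, lapply(cohorts, function(co) {
          fr <- estimate_cell_fractions(co$beta, ref)
          nlr <- compute_nlr(fr)
          data.frame(cohort_id = co$cohort_id,
                     sample_id = rownames(fr), fr, nlr = nlr,
                     check.names = FALSE)
        }))
        write_tsv(dec, file.path(od, "cell_fractions.tsv"))
        counts$deconv <- nrow(dec)
      },
      qtl = {
        require_files("qtl", file.path(od, paste0(cohort_ids[1],
                                                  "_beta.tsv")))
        co <- read_cohort_tsv(od, cohort_ids[1])
        gen <- simulate_genotypes(50, colnames(co$beta),
                                  seed = config$seed + 202L)
        keep_snp <- filter_genotypes(gen$metadata)
        covs <- cbind(age = co$covariates$age,
                      sex = as.numeric(co$covariates$sex == "M"),
                      bmi = co$covariates$bmi,
                      co$cell_fractions_true[, -1])
        rownames(covs) <- co$covariates$sample_id
        sub <- co$beta[seq_len(min(50, nrow(co$beta))), , drop = FALSE]
        sub[is.na(sub)] <- matrix(rowMeans(sub, na.rm = TRUE),
                                  nrow(sub), ncol(sub))[is.na(sub)]
        meqtl <- meqtl_scan(sub, gen$dosage[keep_snp, , drop = FALSE],
                            covariates = covs,
                            retain_p = config$retain_p,
                            sig_p = config$sig_p)
        write_tsv(meqtl, file.path(od, "meqtl.tsv"))
        counts$qtl <- nrow(meqtl)
      },
      enrich = {
        require_files("enrich", c(file.path(od, "meta_results.tsv"),
                                  annot_path))
        meta <- utils::read.delim(file.path(od, "meta_results.tsv"))
        annot <- read_probe_annotation(annot_path)
        sig <- meta$cpg_id[order(meta$pval)][
          seq_len(max(5, sum(meta$fdr_sig)))]
        enr <- fisher_enrichment(sig, meta$cpg_id, annot)
        write_tsv(enr, file.path(od, "enrichment.tsv"))
        counts$enrich <- nrow(enr)
      },
      clock = {
        require_files("clock", file.path(od, paste0(cohort_ids[1],
                                                    "_beta.tsv")))
        cohorts <- lapply(cohort_ids, read_cohort_tsv, dir = od)
        clk <- synthetic_clock(ids, seed = config$seed + 303L)
        sc <- do.call(rbind, lapply(cohorts, function(co) {
          score <- apply_clock(co$beta, clk)
          acc <- age_acceleration(score, co$covariates$age, "difference")
          data.frame(cohort_id = co$cohort_id, sample_id = names(score),
                     clock = score, acceleration = acc)
        }))
        write_tsv(sc, file.path(od, "clock_scores.tsv"))
        counts$clock <- nrow(sc)
      })
    stage_log(stage, t0)
  }
  manifest <- list(package_version = as.character(
                     utils::packageVersion("survewas")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = paste(config$stages, collapse = ","))
  manifest <- c(manifest,
                stats::setNames(counts, paste0("rows_", names(counts))))
  write_tsv(data.frame(key = names(manifest),
                       value = unlist(lapply(manifest, as.character))),
            file.path(od, "manifest.tsv"))
  invisible(manifest)
}
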