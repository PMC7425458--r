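#' Genotype QC pre-filter
#'
#' Drops variants failing the array-QC thresholds: call rate < 0.98,
#' Hardy-Weinberg equilibrium p < 5e-6, minor allele frequency < 0.01.
#'
#' @param metadata data frame `snp_id, call_rate, hwe_p, maf`.
#' @param call_rate_min,hwe_p_min,maf_min thresholds.
#' @return character vector of retained SNP ids.
#' @export
filter_genotypes <- function(metadata, call_rate_min = 0.98,
                             hwe_p_min = 5e-6, maf_min = 0.01) {
  keep <- metadata$call_rate >= call_rate_min &
    metadata$hwe_p >= hwe_p_min & metadata$maf >= maf_min
  metadata$snp_id[keep]
}

residualize <- function(X, W) {
  # X: feature x sample; W: sample x covariate (may be NULL)
  Xc <- X - rowMeans(X)
  if (is.null(W) || ncol(W) == 0) return(Xc)
  Q <- qr.Q(qr(cbind(1, W)))
  Xc <- X - X %*% Q %*% t(Q)
  Xc
}

classify_cis_trans <- function(chrom1, pos1, chrom2, start2, end2 = start2,
                               cis_bp = 500000) {
  same <- !is.na(chrom1) & !is.na(chrom2) & chrom1 == chrom2
  inside <- same & pos1 >= start2 & pos1 <= end2
  dist <- ifelse(same,
                 ifelse(inside, 0,
                        pmin(abs(pos1 - start2), abs(pos1 - end2))),
                 NA_real_)
  cls <- ifelse(!same, "cross-chromosome",
                ifelse(dist <= cis_bp, "cis", "trans"))
  list(distance = dist, cis_trans = cls)
}

#' meQTL scan: per SNP-CpG pair linear association
#'
#' Covariate-adjusted linear models for every CpG x SNP pair, computed by
#' residualizing both matrices against the covariates and correlating the
#' residuals (algebraically identical to the per-pair multiple regression
#' t-test).  Following the source analysis convention, the default
#' regression direction treats the SNP dosage as the dependent variable and
#' methylation as the predictor; `direction = "methylation_on_snp"` gives
#' the conventional orientation.  The p-value is identical either way; only
#' the coefficient scale differs.
#'
#' Pairs are retained only at `p < retain_p` (output-size control) and
#' flagged genome-wide significant at `p < sig_p`.
#'
#' @param beta CpG x sample methylation matrix.
#' @param genotypes SNP x sample dosage matrix (0..2).
#' @param covariates sample x covariate numeric matrix (or NULL).
#' @param retain_p retention threshold (default 1e-4).
#' @param sig_p genome-wide significance threshold (default 1e-14).
#' @param direction which variable is dependent.
#' @param cpg_annot optional data frame `cpg_id, chrom, pos`.
#' @param snp_annot optional data frame `snp_id, chrom, pos`.
#' @param cis_bp cis/trans distance cutoff.
#' @return data frame `cpg_id, partner_id, beta, se, pval, significant`
#'   (plus `distance, cis_trans` when annotations are supplied), with
#'   attribute `"n_skipped"` counting constant-row pairs.
#' @export
meqtl_scan <- function(beta, genotypes, covariates = NULL,
                       retain_p = 1e-4, sig_p = 1e-14,
                       direction = c("snp_on_methylation",
                                     "methylation_on_snp"),
                       cpg_annot = NULL, snp_annot = NULL,
                       cis_bp = 500000) {
  direction <- match.arg(direction)
  samples <- intersect(colnames(beta), colnames(genotypes))
  if (length(samples) < 4) stop("fewer than 4 shared samples")
  M <- beta[, samples, drop = FALSE]
  G <- genotypes[, samples, drop = FALSE]
  W <- if (is.null(covariates)) NULL
       else as.matrix(covariates)[samples, , drop = FALSE]
  ok_m <- apply(M, 1, function(x) stats::sd(x) > 0)
  ok_g <- apply(G, 1, function(x) stats::sd(x) > 0)
  n_skipped <- sum(!ok_m) * nrow(G) + sum(ok_m) * sum(!ok_g)
  M <- M[ok_m, , drop = FALSE]; G <- G[ok_g, , drop = FALSE]
  n <- length(samples)
  q <- if (is.null(W)) 0 else ncol(W)
  df <- n - 2 - q
  Mr <- residualize(M, W); Gr <- residualize(G, W)
  sm <- sqrt(rowSums(Mr^2)); sg <- sqrt(rowSums(Gr^2))
  r <- tcrossprod(Mr / sm, Gr / sg)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df)
  coef <- if (direction == "snp_on_methylation")
    r * outer(1 / sm, sg) * 1  # slope of G on M: cov/var(M) = r*sg/sm
  else r * outer(sm, 1 / sg)
  se_coef <- abs(coef / tt)
  idx <- which(p < retain_p, arr.ind = TRUE)
  out <- data.frame(cpg_id = rownames(M)[idx[, 1]],
                    partner_id = rownames(G)[idx[, 2]],
                    beta = coef[idx], se = se_coef[idx], pval = p[idx],
                    significant = p[idx] < sig_p,
                    stringsAsFactors = FALSE)
  if (!is.null(cpg_annot) && !is.null(snp_annot) && nrow(out) > 0) {
    ci <- cpg_annot[match(out$cpg_id, cpg_annot$cpg_id), ]
    si <- snp_annot[match(out$partner_id, snp_annot$snp_id), ]
    ct <- classify_cis_trans(ci$chrom, ci$pos, si$chrom, si$pos, si$pos,
                             cis_bp = cis_bp)
    out$distance <- ct$distance
    out$cis_trans <- ct$cis_trans
  }
  out <- out[order(out$pval), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' eQTM scan: methylation vs gene expression with a batch random intercept
#'
#' For every same-chromosome CpG-probe pair, regresses (log2,
#' quantile-normalized) expression on methylation with fixed covariates and
#' a random intercept for RNA amplification batch (fitted with lmer,
#' Satterthwaite p-values).  When only one batch level is present, or the
#' mixed fit is singular/non-convergent (e.g. noiseless data), the model
#' degrades to a fixed-intercept linear model with batch as a fixed factor,
#' with a warning recorded in the output.
#'
#' Distance is measured from the CpG position to the gene's [start, end]
#' interval (0 inside); pairs at most `cis_bp` apart are cis, farther
#' same-chromosome pairs trans.
#'
#' @param beta CpG x sample methylation matrix.
#' @param expression probe x sample expression matrix.
#' @param covariates sample x covariate numeric matrix (or NULL).
#' @param batch factor of RNA amplification batches per sample.
#' @param cpg_annot data frame `cpg_id, chrom, pos`.
#' @param gene_annot data frame `probe_id, chrom, start, end`.
#' @param cis_bp cis/trans cutoff (default 500,000 bp, inclusive).
#' @return data frame `cpg_id, partner_id, beta, se, pval, distance,
#'   cis_trans, model_used`.
#' @export
eqtm_scan <- function(beta, expression, covariates = NULL, batch,
                      cpg_annot, gene_annot, cis_bp = 500000) {
  samples <- intersect(colnames(beta), colnames(expression))
  batch <- factor(batch)
  if (length(batch) != length(samples))
    batch <- batch[match(samples, colnames(expression))]
  W <- if (is.null(covariates)) NULL
       else as.matrix(covariates)[samples, , drop = FALSE]
  single_batch <- nlevels(droplevels(batch)) < 2
  if (single_batch)
    warning("single batch level: fitting fixed-intercept models")
  pairs <- merge(cpg_annot[cpg_annot$cpg_id %in% rownames(beta), ],
                 gene_annot[gene_annot$probe_id %in% rownames(expression), ],
                 by = "chrom", suffixes = c("_cpg", "_gene"))
  if (nrow(pairs) == 0) return(data.frame())
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cid <- pairs$cpg_id[i]; pid <- pairs$probe_id[i]
    d <- data.frame(expr = expression[pid, samples],
                    meth = beta[cid, samples], batch = droplevels(batch))
    if (!is.null(W)) d <- cbind(d, W)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) < 4 || stats::sd(d$meth) == 0) return(NULL)
    covs <- setdiff(names(d), c("expr", "meth", "batch"))
    rhs <- paste(c("meth", covs), collapse = " + ")
    used <- "lmm"
    fit <- NULL
    if (!single_batch) {
      fit <- tryCatch({
        f <- stats::as.formula(paste("expr ~", rhs, "+ (1 | batch)"))
        m <- suppressMessages(suppressWarnings(
          lmerTest::lmer(f, data = d)))
        if (lme4::isSingular(m, tol = 1e-6)) NULL else m
      }, error = function(e) NULL)
    }
    if (is.null(fit)) {
      used <- "fixed"
      f <- stats::as.formula(paste("expr ~", rhs,
                                   if (!single_batch ||
                                       nlevels(d$batch) > 1) "+ batch"
                                   else ""))
      fit <- stats::lm(f, data = d)
      cf <- summary(fit)$coefficients
    } else {
      cf <- summary(fit)$coefficients
    }
    est <- cf["meth", 1]; se <- cf["meth", 2]
    pv <- cf["meth", ncol(cf)]
    pos <- pairs$pos[i]
    inside <- pos >= pairs$start[i] && pos <= pairs$end[i]
    dist <- if (inside) 0 else min(abs(pos - pairs$start[i]),
                                   abs(pos - pairs$end[i]))
    data.frame(cpg_id = cid, partner_id = pid, beta = est, se = se,
               pval = pv, distance = dist,
               cis_trans = if (dist <= cis_bp) "cis" else "trans",
               model_used = used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame() else out
}
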