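#' Simulate a 450K-style probe annotation table
#'
#' Produces the manifest fields the QC cascade and enrichment analysis
#' consume, with realistic flag rates (a small fraction of control, non-CpG,
#' allosomal, cross-reactive and SNP-proximal probes).
#'
#' @param cpg_ids character vector of probe ids.
#' @param seed RNG seed.
#' @return data frame with columns `cpg_id, chrom, pos, gene_name,
#'   island_relation, gene_region, is_control, is_noncpg, is_crossreactive,
#'   snp_within_10bp`.
#' @export
simulate_probe_annotation <- function(cpg_ids, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(cpg_ids)
  chrom <- sample(c(as.character(1:22), "X", "Y"), n, TRUE,
                  prob = c(rep(0.95 / 22, 22), 0.04, 0.01))
  data.frame(
    cpg_id = cpg_ids,
    chrom = chrom,
    pos = sample.int(2.4e8, n, replace = TRUE),
    gene_name = ifelse(stats::runif(n) < 0.25, "",
                       sprintf("GENE%04d", sample.int(2000, n, TRUE))),
    island_relation = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                               "S_Shelf", "OpenSea"), n, TRUE,
                             prob = c(0.31, 0.13, 0.12, 0.05, 0.05, 0.34)),
    gene_region = sample(c("Body", "1stExon", "3'UTR", "5'UTR", "TSS200",
                           "TSS1500", "Intergenic"), n, TRUE,
                         prob = c(0.32, 0.03, 0.04, 0.10, 0.11, 0.15, 0.25)),
    is_control = stats::runif(n) < 0.01,
    is_noncpg = stats::runif(n) < 0.01,
    is_crossreactive = stats::runif(n) < 0.06,
    snp_within_10bp = stats::runif(n) < 0.05,
    stringsAsFactors = FALSE)
}

#' Read a probe annotation TSV, accepting Illumina manifest column names
#'
#' Recognises `IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name` and
#' `Relation_to_UCSC_CpG_Island` as aliases for the internal field names.
#'
#' @param path TSV file path.
#' @return annotation data frame as in [simulate_probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  alias <- c(IlmnID = "cpg_id", CHR = "chrom", MAPINFO = "pos",
             UCSC_RefGene_Name = "gene_name",
             Relation_to_UCSC_CpG_Island = "island_relation")
  hit <- names(alias) %in% names(ann)
  names(ann)[match(names(alias)[hit], names(ann))] <- alias[hit]
  for (fl in c("is_control", "is_noncpg", "is_crossreactive",
               "snp_within_10bp"))
    if (fl %in% names(ann)) ann[[fl]] <- as.logical(ann[[fl]])
  ann
}

probe_availability <- function(cohorts, ids) {
  avail <- vapply(cohorts, function(co) {
    present <- ids %in% rownames(co$beta)
    ok <- logical(length(ids))
    ok[present] <- rowSums(!is.na(co$beta[ids[present], , drop = FALSE])) > 0
    ok
  }, logical(length(ids)))
  if (is.null(dim(avail))) avail <- matrix(avail, nrow = length(ids))
  rowSums(avail)
}

#' Consortium-level probe exclusion cascade
#'
#' Applies the pre-meta-analysis probe filters in a fixed order, tallying
#' each probe under the first rule that removes it: control probes; non-CpG
#' probes; allosomal (X/Y) probes; cross-reactive probes; probes with an
#' underlying SNP within 10 bp; non-varying probes (IQR of the per-cohort
#' medians of available values below `iqr_min`); probes with missingness at
#' or above `max_missing` across all pooled samples; probes flagged for
#' non-converging cohort fits; probes available (any observed value) in
#' fewer than `min_cohorts` cohorts.
#'
#' @param cohorts list of `cohort_dataset` objects (or any list whose
#'   elements have a `beta` CpG x sample matrix).
#' @param annot probe annotation data frame covering every CpG present.
#' @param min_cohorts minimum number of cohorts a probe must be observed in
#'   (default 4, i.e. "more than three"; set 3 for "three or more").
#' @param iqr_min non-variation threshold on the beta scale (default 0.001,
#'   i.e. 0.1%).
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param nonconverged_cpgs ids flagged non-converging by the survival fits.
#' @return list with `kept` (character vector), `counts` (named integer
#'   vector of per-rule exclusions, in rule order) and `rule` (per-probe
#'   first removing rule, `"kept"` if retained).
#' @export
filter_probes <- function(cohorts, annot, min_cohorts = 4L,
                          iqr_min = 0.001, max_missing = 0.10,
                          nonconverged_cpgs = character()) {
  ids <- unique(unlist(lapply(cohorts, function(co) rownames(co$beta))))
  missing_ann <- setdiff(ids, annot$cpg_id)
  if (length(missing_ann))
    stop("CpGs absent from annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "),
         if (length(missing_ann) > 10) " ...")
  ann <- annot[match(ids, annot$cpg_id), ]

  med <- vapply(cohorts, function(co) {
    m <- rep(NA_real_, length(ids))
    present <- ids %in% rownames(co$beta)
    m[present] <- apply(co$beta[ids[present], , drop = FALSE], 1,
                        stats::median, na.rm = TRUE)
    m
  }, numeric(length(ids)))
  if (is.null(dim(med))) med <- matrix(med, nrow = length(ids))
  pooled_iqr <- apply(med, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    stats::IQR(x)
  })
  # missingness is judged within the cohorts that assay the probe at all;
  # whole-cohort absence is the availability rule's concern
  obs_tot <- Reduce(`+`, lapply(cohorts, function(co) {
    present <- ids %in% rownames(co$beta)
    v <- cbind(obs = numeric(length(ids)), tot = numeric(length(ids)))
    v[present, "obs"] <- rowSums(!is.na(co$beta[ids[present], ,
                                                drop = FALSE]))
    v[present, "tot"] <- ncol(co$beta)
    v
  }))
  miss_frac <- ifelse(obs_tot[, "tot"] > 0,
                      1 - obs_tot[, "obs"] / obs_tot[, "tot"], 1)
  n_avail <- probe_availability(cohorts, ids)

  rules <- list(
    control = ann$is_control,
    noncpg = ann$is_noncpg,
    allosomal = ann$chrom %in% c("X", "Y"),
    crossreactive = ann$is_crossreactive,
    snp_within_10bp = ann$snp_within_10bp,
    nonvarying = !is.na(pooled_iqr) & pooled_iqr < iqr_min,
    missingness = miss_frac >= max_missing,
    nonconverging = ids %in% nonconverged_cpgs,
    availability = n_avail < min_cohorts)

  rule <- rep("kept", length(ids))
  for (rn in names(rules)) {
    hit <- rules[[rn]] & rule == "kept"
    hit[is.na(hit)] <- FALSE
    rule[hit] <- rn
  }
  counts <- vapply(names(rules), function(rn) sum(rule == rn), integer(1))
  list(kept = ids[rule == "kept"], counts = counts,
       rule = stats::setNames(rule, ids))
}
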