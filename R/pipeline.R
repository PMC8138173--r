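# End-to-end orchestration: filter -> BMI calls -> FA calls -> paired
# calls -> overlaps -> direction proportions -> genomic-context and
# beta-quartile distributions -> optional gene-set enrichment, with
# deterministic TSV outputs.

#' Pipeline configuration
#'
#' @param beta Path to the beta-matrix TSV (both states' samples).
#' @param samples Path to the sample-sheet CSV.
#' @param annotation Path to the probe-manifest CSV.
#' @param islands Path to the CpG-island BED.
#' @param snp_list Optional path to a SNP-affected probe list.
#' @param detection_p Optional path to a detection p-value TSV.
#' @param gene_sets Optional path to a GMT file for enrichment.
#' @param out_dir Output directory.
#' @param alpha Significance level (default 0.05).
#' @param min_delta Minimum absolute delta-beta (default 0.10).
#' @param detection_threshold Detection-p cutoff (default 0.01).
#' @param shore_width,shelf_width Island-geography widths (default 2000).
#' @param adjust_cells Use cell-composition-adjusted p-values (default
#'   FALSE; both p-values are always reported for associations).
#' @param age_alpha Age-filter level (default 0.05; `NA` disables).
#' @param covariates Association covariates beyond BMI (default the three
#'   saturation groups).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(beta, samples, annotation, islands,
                            snp_list = NULL, detection_p = NULL,
                            gene_sets = NULL, out_dir,
                            alpha = 0.05, min_delta = 0.10,
                            detection_threshold = 0.01,
                            shore_width = 2000L, shelf_width = 2000L,
                            adjust_cells = FALSE, age_alpha = 0.05,
                            covariates = names(fa_saturation_groups())) {
  stopifnot(alpha > 0, alpha < 1, min_delta > 0, min_delta < 1,
            detection_threshold > 0, detection_threshold < 1,
            shore_width > 0, shelf_width > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full differential-methylation pipeline
#'
#' Stages: read and validate inputs; probe filter onto a shared FS/PS
#' universe; BMI and fatty-acid association calls per prandial state;
#' paired FS-vs-PS calls per BMI class; overlap and direction summaries;
#' genomic-context (gene compartment and CpG-island relation)
#' distributions against the filtered universe; baseline beta-quartile
#' distributions; optional gene-set over-representation. All outputs are
#' TSV under `out_dir`; re-running on identical inputs reproduces them
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of summary objects (also serialized to
#'   `summary.tsv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  ds <- .stage("read_beta", read_beta_matrix(config$beta))
  sheet <- .stage("read_samples", read_sample_sheet(config$samples))
  ann <- .stage("read_annotation", read_probe_annotation(config$annotation))
  isl <- .stage("read_islands", read_island_bed(config$islands))
  snp <- if (!is.null(config$snp_list))
    .stage("read_snp_list", read_probe_list(config$snp_list)) else character()
  detp <- if (!is.null(config$detection_p))
    .stage("read_detection", read_detection_p(config$detection_p)) else NULL
  gsets <- if (!is.null(config$gene_sets))
    .stage("read_gene_sets", read_gmt(config$gene_sets)) else NULL

  ds <- methylation_dataset(ds$beta, sheet)
  states <- split_states(ds)

  filt <- .stage("filter", filter_probe_universe(
    states$FS, states$PS, annotation = ann, snp_probes = snp,
    detection_p = detp, detection_threshold = config$detection_threshold,
    alpha = config$age_alpha))
  write_filter_report(filt$report_fs, file.path(config$out_dir, "filter_fs.tsv"))
  write_filter_report(filt$report_ps, file.path(config$out_dir, "filter_ps.tsv"))
  universe <- filt$retained
  log_line("probe filter: %d of %d probes retained", length(universe),
           nrow(ds$beta))
  ann <- annotate_island_relation(ann[match(universe, ann$probe_id), ], isl,
                                  shore_width = config$shore_width,
                                  shelf_width = config$shelf_width)

  # association calls per state and covariate
  specs <- c(list(covariate_spec("BMI")),
             lapply(config$covariates, covariate_spec))
  assoc <- list()
  for (st in names(filt)[1:2]) {
    dset <- filt[[st]]
    for (spec in specs) {
      res <- .stage(paste0("call_", spec$name, "_", st),
                    call_dm_for_covariate(dset, spec, alpha = config$alpha,
                                          min_delta = config$min_delta,
                                          adjust_cells = config$adjust_cells))
      key <- paste(spec$name, toupper(st), sep = "_")
      assoc[[key]] <- res
      write_results(res, file.path(config$out_dir,
                                   paste0("assoc_", key, ".tsv")),
                    params = list(alpha = config$alpha,
                                  min_delta = config$min_delta))
      log_line("%s: %d dmCpG", key, sum(res$is_dmcpg))
    }
  }

  # paired calls per BMI class
  paired <- list()
  for (cls in .BMI_CLASSES) {
    res <- .stage(paste0("paired_", cls),
                  suppressWarnings(call_paired_dm(filt$fs, filt$ps, cls,
                                                  alpha = config$alpha,
                                                  min_delta = config$min_delta,
                                                  adjust_cells = config$adjust_cells)))
    paired[[cls]] <- res
    write_results(res, file.path(config$out_dir, paste0("paired_", cls, ".tsv")),
                  params = list(alpha = config$alpha,
                                min_delta = config$min_delta))
    log_line("paired %s: %d dmCpG", cls, sum(res$is_dmcpg))
  }

  dm_sets <- c(lapply(assoc, function(r) r$probe_id[r$is_dmcpg]),
               lapply(paired, function(r) r$probe_id[r$is_dmcpg]))
  names(dm_sets) <- c(names(assoc), paste0("paired_", names(paired)))

  # overlaps: BMI vs each FA covariate within state (denominator = FA
  # set), FA vs FA within state (denominator = smaller set)
  ov <- list()
  for (st in c("FS", "PS")) {
    fa_keys <- paste(config$covariates, st, sep = "_")
    bmi_key <- paste("BMI", st, sep = "_")
    for (k in fa_keys) {
      if (length(dm_sets[[k]]))
        ov[[length(ov) + 1L]] <- overlap(dm_sets[[bmi_key]], dm_sets[[k]],
                                         "b_count", bmi_key, k)
    }
    pairs <- utils::combn(fa_keys, 2L, simplify = FALSE)
    for (pr in pairs) {
      if (length(dm_sets[[pr[1]]]) && length(dm_sets[[pr[2]]]))
        ov[[length(ov) + 1L]] <- overlap(dm_sets[[pr[1]]], dm_sets[[pr[2]]],
                                         "min_count", pr[1], pr[2])
    }
  }
  overlaps <- if (length(ov)) do.call(rbind, ov) else
    data.frame(label_a = character(), label_b = character(), shared = integer(),
               denominator = integer(), percent = numeric())
  write.table(overlaps, file.path(config$out_dir, "overlaps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # direction proportions and genomic context per non-empty dmCpG set
  all_res <- c(assoc, setNames(paired, paste0("paired_", names(paired))))
  ctx_rows <- list()
  baseline_n <- subset_dataset(filt$fs,
    samples = filt$fs$samples$sample_id[filt$fs$samples$bmi_class == "N"])
  for (nm in names(dm_sets)) {
    set <- dm_sets[[nm]]
    if (!length(set)) next
    dp <- direction_proportions(all_res[[nm]])
    qd <- quartile_distribution(set, baseline_n)
    row <- data.frame(set = nm, n = length(set), pct_hypo = dp[["pct_hypo"]],
                      pct_hyper = dp[["pct_hyper"]],
                      q1 = qd[1], q2 = qd[2], q3 = qd[3], q4 = qd[4],
                      stringsAsFactors = FALSE)
    for (cat in c("compartment", "island_relation")) {
      cd <- suppressMessages(context_distribution(set, ann, universe, cat))
      row[[paste0("chi2_", cat)]] <- cd$chi2
      row[[paste0("p_", cat)]] <- cd$p
    }
    ctx_rows[[nm]] <- row
  }
  set_summary <- if (length(ctx_rows)) do.call(rbind, ctx_rows) else
    data.frame(set = character())
  rownames(set_summary) <- NULL
  write.table(set_summary, file.path(config$out_dir, "dmcpg_sets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # enrichment of paired-call host genes, when gene sets are supplied
  if (!is.null(gsets)) {
    gene_of <- setNames(ann$gene, ann$probe_id)
    uni_genes <- setdiff(unique(ann$gene), "")
    for (cls in .BMI_CLASSES) {
      set <- dm_sets[[paste0("paired_", cls)]]
      genes <- setdiff(unique(gene_of[set]), "")
      if (!length(genes)) next
      enr <- gene_set_enrichment(genes, gsets, uni_genes, fdr_alpha = config$alpha)
      write.table(enr, file.path(config$out_dir,
                                 paste0("enrichment_paired_", cls, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  counts <- vapply(dm_sets, length, integer(1L))
  summary_df <- data.frame(key = c("n_input", "n_retained",
                                   paste0("n_dmcpg_", names(counts))),
                           value = c(nrow(ds$beta), length(universe), counts),
                           stringsAsFactors = FALSE)
  write.table(summary_df, file.path(config$out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(filter = filt[c("report_fs", "report_ps")],
                 dm_sets = dm_sets, overlaps = overlaps,
                 set_summary = set_summary, summary = summary_df))
}
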