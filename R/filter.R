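# Four-stage probe filter: SNP-affected -> sex chromosomes -> detection
# failure -> missing values -> age-associated. Reasons are attributed in
# that fixed order (a probe failing several stages counts once, under the
# first); the retained set is order-independent.

#' Filter probes to the analysis-ready universe
#'
#' Removes, in order: probes on a user-supplied SNP-affected list; probes
#' on chrX/chrY; probes failing detection (p-value above
#' `detection_threshold` under `detection_rule`, when a detection table is
#' supplied); probes with any missing beta; and probes whose M-values
#' associate with subject age at `p < alpha` under the same
#' normality-adaptive correlation test used for covariate calling.
#'
#' @param dataset A `methylation_dataset` (one prandial state, or any
#'   sample set sharing one age per sample).
#' @param annotation Probe annotation covering every probe (error if not).
#' @param snp_probes Character vector of SNP-affected probe IDs (default
#'   none; supply a published compilation).
#' @param detection_p Optional probes x samples detection p-value matrix.
#' @param detection_rule Quantifier for detection failure: `"any"` sample
#'   above threshold (default, strictest), `"all"`, or `"mean"`.
#' @param detection_threshold Detection p cutoff (default 0.01).
#' @param ages Per-sample ages; defaults to `dataset$samples$age`.
#' @param alpha Age-association level (default 0.05). `NA` skips the age
#'   stage.
#' @return List with `dataset` (filtered) and `report` (a `filter_report`).
#' @export
filter_probes <- function(dataset, annotation, snp_probes = character(),
                          detection_p = NULL,
                          detection_rule = c("any", "all", "mean"),
                          detection_threshold = 0.01,
                          ages = NULL, alpha = 0.05) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  detection_rule <- match.arg(detection_rule)
  probes <- rownames(dataset$beta)
  missing_ann <- setdiff(probes, annotation$probe_id)
  if (length(missing_ann))
    stop(sprintf("annotation missing probe(s), e.g. %s", missing_ann[1L]))
  ann <- annotation[match(probes, annotation$probe_id), ]
  if (is.null(ages) && !is.null(dataset$samples)) ages <- dataset$samples$age

  reason <- rep(NA_character_, length(probes))
  mark <- function(reason, idx, label) {
    new <- idx & is.na(reason)
    reason[new] <- label
    reason
  }
  reason <- mark(reason, probes %in% snp_probes, "snp")
  reason <- mark(reason, ann$chrom %in% c("chrX", "chrY", "X", "Y"), "sex")
  if (!is.null(detection_p)) {
    if (!all(probes %in% rownames(detection_p)))
      stop("detection table missing probes")
    dp <- detection_p[probes, colnames(dataset$beta), drop = FALSE]
    fail <- switch(detection_rule,
                   any = apply(dp > detection_threshold, 1L, any),
                   all = apply(dp > detection_threshold, 1L, all),
                   mean = rowMeans(dp) > detection_threshold)
    reason <- mark(reason, fail, "detection")
  }
  reason <- mark(reason, !complete.cases(dataset$beta), "missing")

  if (!is.na(alpha)) {
    if (is.null(ages)) stop("age filter needs ages (or an attached sample sheet)")
    if (sd(ages) == 0) stop("ages are constant; cannot run the age filter")
    cand <- which(is.na(reason))
    m <- beta_to_m(dataset$beta[cand, , drop = FALSE])
    age_normal <- shapiro_normal(ages, alpha = 0.05)$is_normal
    age_assoc <- vapply(seq_along(cand), function(i) {
      yi <- m[i, ]
      if (sd(yi) == 0) return(FALSE)  # constant probe cannot associate
      use <- if (age_normal && shapiro_normal(yi)$is_normal) "pearson" else "spearman"
      adaptive_cor_test(ages, yi, method = use)$p < alpha
    }, logical(1L))
    reason[cand[age_assoc]] <- "age"
  }

  keep <- is.na(reason)
  report <- filter_report(
    n_input = length(probes),
    n_removed_snp = sum(reason == "snp", na.rm = TRUE),
    n_removed_sex = sum(reason == "sex", na.rm = TRUE),
    n_removed_detection = sum(reason == "detection", na.rm = TRUE),
    n_removed_missing = sum(reason == "missing", na.rm = TRUE),
    n_removed_age = sum(reason == "age", na.rm = TRUE)
  )
  list(dataset = subset_dataset(dataset, probes = probes[keep]), report = report)
}

#' Construct a filter attrition report
#'
#' @param n_input,n_removed_snp,n_removed_sex,n_removed_detection,n_removed_missing,n_removed_age
#'   Stage counts (no double counting; reasons attributed in the fixed
#'   order SNP, sex, detection, missing, age).
#' @return A `filter_report` list; `n_retained` is derived.
#' @export
filter_report <- function(n_input, n_removed_snp = 0L, n_removed_sex = 0L,
                          n_removed_detection = 0L, n_removed_missing = 0L,
                          n_removed_age = 0L) {
  removed <- n_removed_snp + n_removed_sex + n_removed_detection +
    n_removed_missing + n_removed_age
  structure(list(n_input = n_input, n_removed_snp = n_removed_snp,
                 n_removed_sex = n_removed_sex,
                 n_removed_detection = n_removed_detection,
                 n_removed_missing = n_removed_missing,
                 n_removed_age = n_removed_age,
                 n_retained = n_input - removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("probe filter attrition:\n")
  for (f in names(x)) cat(sprintf("  %-20s %d\n", f, x[[f]]))
  invisible(x)
}

#' Serialize a filter report as two-column TSV
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(stage = names(unclass(report)),
                   count = unlist(unclass(report), use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter both prandial states onto one shared probe universe
#'
#' Runs [filter_probes()] on the fasting and postprandial datasets
#' independently, then removes the union of all removed probes from both,
#' so downstream paired and association analyses share one probe universe.
#'
#' @param ds_fs,ds_ps Datasets for the two states (same probe set).
#' @param ... Passed to [filter_probes()].
#' @return List with `fs`, `ps` (filtered datasets), `report_fs`,
#'   `report_ps`, and `retained` (the shared probe IDs).
#' @export
filter_probe_universe <- function(ds_fs, ds_ps, ...) {
  if (!identical(rownames(ds_fs$beta), rownames(ds_ps$beta)))
    stop("FS and PS datasets must share one probe set")
  f_fs <- filter_probes(ds_fs, ...)
  f_ps <- filter_probes(ds_ps, ...)
  retained <- intersect(rownames(f_fs$dataset$beta), rownames(f_ps$dataset$beta))
  list(fs = subset_dataset(ds_fs, probes = retained),
       ps = subset_dataset(ds_ps, probes = retained),
       report_fs = f_fs$report, report_ps = f_ps$report,
       retained = retained)
}
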