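# Fasting-vs-postprandial differential methylation within one BMI class,
# using the paired test selected by normality of the per-subject
# differences: paired t when the Shapiro-Wilk check passes, Wilcoxon
# signed-rank (exact null for n <= 25 after dropping zero differences)
# otherwise.

#' Normality-adaptive paired test
#'
#' Tests per-subject differences `d = x_ps - x_fs`. If the differences
#' pass [shapiro_normal()] at `alpha_normality`, a two-sided paired t-test
#' is used; otherwise the Wilcoxon signed-rank test, with the exact null
#' distribution for n <= 25 non-zero differences (zero differences
#' dropped, standard signed-rank convention) and the normal approximation
#' with continuity correction above, or always when `approx = TRUE`.
#'
#' All-zero differences (or fewer than 3 non-zero under the Wilcoxon
#' branch) return `p = 1` by convention.
#'
#' @param x_fs,x_ps Subject-aligned numeric vectors, n >= 3.
#' @param alpha_normality Level for the Shapiro-Wilk gate (default 0.05).
#' @param approx Force the asymptotic Wilcoxon p-value.
#' @return List with `test` ("paired_t" or "wilcoxon") and `p`.
#' @export
paired_test <- function(x_fs, x_ps, alpha_normality = 0.05, approx = FALSE) {
  stopifnot(length(x_fs) == length(x_ps))
  n <- length(x_fs)
  if (n < 3L) stop("paired test requires n >= 3")
  d <- x_ps - x_fs
  if (all(d == 0)) {
    message("all paired differences zero; p = 1 by convention")
    return(list(test = "wilcoxon", p = 1))
  }
  normal <- if (sd(d) == 0) FALSE else shapiro_normal(d, alpha_normality)$is_normal
  if (normal) {
    return(list(test = "paired_t", p = t.test(x_ps, x_fs, paired = TRUE)$p.value))
  }
  dz <- d[d != 0]
  if (length(dz) < 3L) return(list(test = "wilcoxon", p = 1))
  exact <- !approx && length(dz) <= 25L && !anyDuplicated(abs(dz))
  wt <- suppressWarnings(
    wilcox.test(dz, exact = exact, correct = TRUE)
  )
  list(test = "wilcoxon", p = wt$p.value)
}

#' Cell-composition-adjusted paired test
#'
#' Difference-space adjustment for paired prandial contrasts: the
#' per-subject differences `d = x_ps - x_fs` are regressed on the
#' per-subject differences of the leukocyte proportions, and the
#' prandial effect is the two-sided t-test of the model intercept. Under
#' normal errors this is exactly calibrated, and it removes any
#' methylation shift explained by a cell-composition shift between
#' states.
#'
#' At most `n - 3` cell-difference columns are used (selected by
#' variance, deterministically), so very small classes get a partial
#' adjustment; constant columns are dropped.
#'
#' @param x_fs,x_ps Subject-aligned numeric vectors.
#' @param cells_fs,cells_ps Subject-aligned leukocyte-proportion matrices
#'   (subjects x cell types) for the two states.
#' @return List with `test` (`"paired_t_adjusted"`) and `p`.
#' @export
paired_test_adjusted <- function(x_fs, x_ps, cells_fs, cells_ps) {
  n <- length(x_fs)
  stopifnot(length(x_ps) == n, nrow(cells_fs) == n, nrow(cells_ps) == n)
  if (n < 4L) stop("adjusted paired test requires n >= 4")
  d <- x_ps - x_fs
  dc <- as.matrix(cells_ps) - as.matrix(cells_fs)
  v <- apply(dc, 2L, sd)
  dc <- dc[, v > 0, drop = FALSE]
  max_cols <- n - 3L
  if (ncol(dc) > max_cols) {
    v <- apply(dc, 2L, sd)
    dc <- dc[, order(v, decreasing = TRUE)[seq_len(max_cols)], drop = FALSE]
  }
  fit <- if (ncol(dc) > 0L) lm(d ~ dc) else lm(d ~ 1)
  smry <- summary(fit)$coefficients
  list(test = "paired_t_adjusted", p = unname(smry["(Intercept)", "Pr(>|t|)"]))
}

#' Call prandial-state dmCpGs within one BMI class
#'
#' Per probe: p-value from [paired_test()] on M-values of the class's
#' subjects in both states; effect size `delta beta = mean PS beta - mean
#' FS beta`; a dmCpG requires `p < alpha` AND `|delta beta| > min_delta`;
#' direction is `hyper` when methylation rises postprandially.
#'
#' With 4 subjects per class the exact Wilcoxon branch cannot reach
#' p < 0.05 (its minimum two-sided p is 0.125), so calls at that class
#' size arise only from the t branch; a warning notes this.
#'
#' @param ds_fs,ds_ps `methylation_dataset`s for the two states, identical
#'   probe universe, same subjects (error otherwise).
#' @param bmi_class `"N"`, `"Ow"` or `"Ob"`.
#' @param alpha Significance level (default 0.05).
#' @param min_delta Minimum absolute delta-beta (default 0.10).
#' @param adjust_cells Use [paired_test_adjusted()] (difference-space
#'   cell-composition adjustment) instead of the adaptive paired test.
#'   With 4 subjects only one cell-difference column fits, so the
#'   adjustment is partial at that class size.
#' @param approx Force asymptotic Wilcoxon p-values.
#' @return Data frame of class `paired_result`, one row per probe.
#' @export
call_paired_dm <- function(ds_fs, ds_ps, bmi_class, alpha = 0.05,
                           min_delta = 0.10, adjust_cells = FALSE,
                           approx = FALSE) {
  stopifnot(inherits(ds_fs, "methylation_dataset"),
            inherits(ds_ps, "methylation_dataset"))
  bmi_class <- match.arg(bmi_class, .BMI_CLASSES)
  if (!identical(rownames(ds_fs$beta), rownames(ds_ps$beta)))
    stop("FS and PS datasets must share one probe universe")
  sf <- ds_fs$samples; sp <- ds_ps$samples
  if (is.null(sf) || is.null(sp)) stop("both datasets need sample sheets")
  keep_f <- sf$sample_id[sf$bmi_class == bmi_class]
  keep_p <- sp$sample_id[sp$bmi_class == bmi_class]
  fs <- subset_dataset(ds_fs, samples = keep_f)
  ps <- subset_dataset(ds_ps, samples = keep_p)
  ord_f <- order(fs$samples$subject_id); ord_p <- order(ps$samples$subject_id)
  fs <- subset_dataset(fs, samples = fs$samples$sample_id[ord_f])
  ps <- subset_dataset(ps, samples = ps$samples$sample_id[ord_p])
  if (!identical(fs$samples$subject_id, ps$samples$subject_id))
    stop("subject mismatch between FS and PS for class ", bmi_class)
  n <- nrow(fs$samples)
  if (n < 3L) stop("need at least 3 subjects in the class")
  if (n == 4L)
    warning("class size 4: the exact Wilcoxon branch cannot reach p < 0.05 ",
            "(minimum two-sided p = 0.125); calls arise only from the t branch")

  m_fs <- beta_to_m(fs$beta); m_ps <- beta_to_m(ps$beta)
  cells_fs <- if (adjust_cells) cell_matrix(fs$samples) else NULL
  cells_ps <- if (adjust_cells) cell_matrix(ps$samples) else NULL
  nprobe <- nrow(m_fs)
  res <- data.frame(
    probe_id = rownames(m_fs), bmi_class = bmi_class,
    test = character(nprobe), p = numeric(nprobe),
    delta_beta = numeric(nprobe), direction = character(nprobe),
    is_dmcpg = logical(nprobe), stringsAsFactors = FALSE
  )
  for (i in seq_len(nprobe)) {
    pt <- if (adjust_cells) {
      paired_test_adjusted(m_fs[i, ], m_ps[i, ], cells_fs, cells_ps)
    } else {
      suppressMessages(paired_test(m_fs[i, ], m_ps[i, ],
                                   alpha_normality = 0.05, approx = approx))
    }
    db <- mean(ps$beta[i, ]) - mean(fs$beta[i, ])
    res$test[i] <- pt$test
    res$p[i] <- pt$p
    res$delta_beta[i] <- db
    res$direction[i] <- if (db > 0) "hyper" else "hypo"
    res$is_dmcpg[i] <- (pt$p < alpha) && (abs(db) > min_delta)
  }
  class(res) <- c("paired_result", "data.frame")
  res
}
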