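# Normality-adaptive per-probe correlation calling of dmCpGs against a
# continuous covariate (BMI or blood fatty-acid percent) within one
# prandial state. Tests run on M-values; effect size is the difference of
# group-mean beta between extreme groups.

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] returning the decision used
#' throughout the package: a vector is treated as normal when the
#' Shapiro-Wilk p-value is at least `alpha`.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Significance level for rejecting normality (default 0.05).
#' @return List with `W`, `p`, `is_normal`.
#' @export
shapiro_normal <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) stop("Shapiro-Wilk is undefined for a constant vector")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, is_normal = sw$p.value >= alpha)
}

#' Normality-adaptive correlation test
#'
#' Pearson's correlation when the normality gate passes, Spearman's rank
#' correlation otherwise, mirroring the adaptive test-selection rule of
#' small-cohort EWAS. The default gate requires BOTH vectors to pass the
#' Shapiro-Wilk check at `alpha`; `gate = "either"` or `"y_only"` relax
#' that. Spearman uses average ranks for ties; its p-value comes from the
#' t approximation unless `exact_spearman = TRUE` (no-ties case only).
#'
#' @param x,y Numeric vectors of equal length >= 4, both non-constant.
#' @param alpha Normality-gate level (default 0.05).
#' @param gate Which vectors must pass normality for Pearson.
#' @param method `"auto"` (adaptive) or force `"pearson"`/`"spearman"`.
#' @param exact_spearman Use the exact Spearman null (only without ties).
#' @return List with `method` ("pearson"/"spearman"), `r`, `p`, `n`.
#' @export
adaptive_cor_test <- function(x, y, alpha = 0.05,
                              gate = c("both", "either", "y_only"),
                              method = c("auto", "pearson", "spearman"),
                              exact_spearman = FALSE) {
  gate <- match.arg(gate)
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("correlation requires n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation is undefined for a constant vector")
  if (method == "auto") {
    nx <- shapiro_normal(x, alpha)$is_normal
    ny <- shapiro_normal(y, alpha)$is_normal
    normal <- switch(gate,
                     both = nx && ny,
                     either = nx || ny,
                     y_only = ny)
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- if (method == "pearson") {
    cor.test(x, y, method = "pearson")
  } else {
    suppressWarnings(cor.test(x, y, method = "spearman", exact = exact_spearman))
  }
  list(method = method, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Define an association covariate
#'
#' @param name Covariate name: `"BMI"`, a measured fatty acid (e.g.
#'   `"PA"`, `"C20:1"`), or a saturation group (`"SFA"`, `"MUFA"`,
#'   `"PUFA"`).
#' @param kind One of `"bmi"`, `"individual_fa"`, `"saturation_group"`;
#'   inferred from `name` when missing.
#' @param members For saturation groups, the member fatty acids (defaults
#'   to [fa_saturation_groups()]).
#' @return Object of class `covariate_spec`.
#' @details Glucose and C18:3 are never permitted covariates (glycemia was
#'   uninformative and C18:3 was incompletely determined in the design
#'   this package targets).
#' @export
covariate_spec <- function(name, kind = NULL, members = NULL) {
  if (name %in% .EXCLUDED_COVARIATES)
    stop(sprintf("'%s' is an excluded covariate", name))
  if (is.null(kind)) {
    kind <- if (identical(toupper(name), "BMI")) "bmi"
            else if (name %in% names(.FA_GROUPS)) "saturation_group"
            else "individual_fa"
  }
  kind <- match.arg(kind, c("bmi", "individual_fa", "saturation_group"))
  if (kind == "individual_fa" && !(name %in% .MEASURED_FA))
    stop(sprintf("unknown fatty acid '%s'", name))
  if (kind == "saturation_group") {
    if (is.null(members)) members <- .FA_GROUPS[[name]]
    if (is.null(members) || !length(members))
      stop("saturation group needs non-empty members")
    if (!all(members %in% .MEASURED_FA))
      stop("saturation-group members must be measured fatty acids")
  }
  structure(list(name = name, kind = kind, members = members),
            class = "covariate_spec")
}

#' Covariate values per sample
#'
#' BMI returns the BMI column; an individual fatty acid returns its
#' percent; a saturation group returns the sum of its members' percents.
#'
#' @param samples Sample sheet rows (one prandial state).
#' @param spec A [covariate_spec()].
#' @return Named numeric vector (names = sample IDs).
#' @export
covariate_values <- function(samples, spec) {
  stopifnot(inherits(spec, "covariate_spec"))
  v <- switch(spec$kind,
    bmi = samples$bmi,
    individual_fa = {
      fm <- fa_matrix(samples)
      if (!(spec$name %in% colnames(fm)))
        stop(sprintf("fatty acid '%s' not present in sample sheet", spec$name))
      fm[, spec$name]
    },
    saturation_group = {
      fm <- fa_matrix(samples)
      if (!all(spec$members %in% colnames(fm)))
        stop("saturation-group member missing from sample sheet")
      rowSums(fm[, spec$members, drop = FALSE])
    })
  setNames(as.numeric(v), samples$sample_id)
}

#' Delta-beta between extreme covariate groups
#'
#' For BMI the extreme groups are the obese and normoweight classes
#' (`mean beta(Ob) - mean beta(N)`). For fatty-acid covariates the groups
#' are the top and bottom covariate tertiles of size `floor(n/3)` —
#' which, in the balanced 12-subject design, are exactly the BMI analogue.
#'
#' @param beta_row Numeric vector of beta-values (one probe), aligned to
#'   `samples`.
#' @param samples Sample sheet rows for one prandial state.
#' @param spec A [covariate_spec()].
#' @param group_size Extreme-group size for FA covariates (default
#'   `floor(n/3)`).
#' @return Signed delta-beta (top/obese minus bottom/normoweight).
#' @export
delta_beta_extremes <- function(beta_row, samples, spec, group_size = NULL) {
  stopifnot(length(beta_row) == nrow(samples))
  if (spec$kind == "bmi") {
    top <- samples$bmi_class == "Ob"
    bot <- samples$bmi_class == "N"
  } else {
    x <- covariate_values(samples, spec)
    n <- length(x)
    if (is.null(group_size)) group_size <- n %/% 3L
    if (group_size < 2L) stop("extreme groups need at least 2 samples")
    ord <- order(x)
    bot <- seq_along(x) %in% ord[seq_len(group_size)]
    top <- seq_along(x) %in% ord[seq.int(n - group_size + 1L, n)]
  }
  if (sum(top) < 2L || sum(bot) < 2L) stop("empty or too-small extreme group")
  mean(beta_row[top]) - mean(beta_row[bot])
}

#' Cell-composition-adjusted association p-value
#'
#' Ordinary least-squares fit of a probe's M-values on the covariate plus
#' the leukocyte proportions (one cell type dropped for identifiability;
#' constant columns dropped), returning the two-sided t-test p-value of
#' the covariate coefficient. This is the linear-model form of
#' reference-based cell-composition correction for whole-blood arrays.
#'
#' @param m_row M-values for one probe (length = samples).
#' @param covariate Numeric covariate vector.
#' @param proportions Samples x cell-types matrix; rows sum to 1.
#' @return Adjusted p-value (scalar).
#' @export
adjust_cell_composition <- function(m_row, covariate, proportions) {
  proportions <- as.matrix(proportions)
  stopifnot(length(m_row) == length(covariate),
            nrow(proportions) == length(m_row))
  if (any(abs(rowSums(proportions) - 1) > 1e-6))
    stop("cell-proportion rows must sum to 1")
  # drop one column (identifiability under the sum-to-1 constraint) plus
  # any constant column
  keep <- apply(proportions, 2L, sd) > 0
  covars <- proportions[, keep, drop = FALSE]
  if (ncol(covars) > 0L) covars <- covars[, -ncol(covars), drop = FALSE]
  if (length(m_row) <= ncol(covars) + 2L)
    stop("too few samples for the adjusted model")
  fit <- if (ncol(covars) > 0L) lm(m_row ~ covariate + covars)
         else lm(m_row ~ covariate)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design in cell-composition adjustment")
  smry <- summary(fit)$coefficients
  unname(smry["covariate", "Pr(>|t|)"])
}

#' Call dmCpGs against a continuous covariate within one prandial state
#'
#' Per probe: M-values are tested against the covariate with
#' [adaptive_cor_test()]; the effect size is [delta_beta_extremes()]; a
#' probe is a dmCpG when the working p-value (cell-adjusted when
#' `adjust_cells`) is below `alpha` AND `|delta beta| > min_delta`.
#' Direction is `hyper` for positive association, `hypo` for negative.
#' P-values are nominal (no genome-wide correction), matching the
#' discovery-oriented design this package targets; apply
#' [stats::p.adjust()] downstream if desired.
#'
#' @param dataset `methylation_dataset` restricted to ONE prandial state,
#'   >= 6 samples, with attached sample sheet.
#' @param spec A [covariate_spec()].
#' @param alpha Significance level (default 0.05).
#' @param min_delta Minimum absolute delta-beta (default 0.10).
#' @param adjust_cells Use the cell-composition-adjusted p-value for
#'   calling (requires `cell_` columns). Both p-values are reported.
#' @param gate,group_size Passed to [adaptive_cor_test()] /
#'   [delta_beta_extremes()].
#' @return Data frame of class `association_result`, one row per tested
#'   probe. Probes with zero variance in this state are excluded with a
#'   message.
#' @export
call_dm_for_covariate <- function(dataset, spec, alpha = 0.05, min_delta = 0.10,
                                  adjust_cells = FALSE, gate = "both",
                                  group_size = NULL) {
  stopifnot(inherits(dataset, "methylation_dataset"), !is.null(dataset$samples))
  samples <- dataset$samples
  state <- unique(samples$prandial_state)
  if (length(state) != 1L)
    stop("dataset must be restricted to a single prandial state")
  if (nrow(samples) < 6L) stop("need at least 6 samples")
  x <- covariate_values(samples, spec)
  if (sd(x) == 0) stop("covariate is constant")
  beta <- dataset$beta
  m <- beta_to_m(beta)
  props <- if (adjust_cells) cell_matrix(samples) else NULL
  const <- apply(m, 1L, sd) == 0
  if (any(const)) {
    message(sprintf("excluding %d constant probe(s) in state %s", sum(const), state))
    m <- m[!const, , drop = FALSE]
    beta <- beta[!const, , drop = FALSE]
  }
  nprobe <- nrow(m)
  res <- data.frame(
    probe_id = rownames(m), covariate = spec$name, prandial_state = state,
    method = character(nprobe), r = numeric(nprobe), p = numeric(nprobe),
    p_cell_adjusted = NA_real_, delta_beta = numeric(nprobe),
    direction = character(nprobe), is_dmcpg = logical(nprobe),
    stringsAsFactors = FALSE
  )
  x_normal <- shapiro_normal(x, alpha)$is_normal
  forced <- switch(gate, both = if (!x_normal) "spearman" else NULL,
                   either = if (x_normal) "pearson" else NULL,
                   y_only = NULL)
  for (i in seq_len(nprobe)) {
    yi <- m[i, ]
    ct <- if (!is.null(forced) && forced == "spearman") {
      adaptive_cor_test(x, yi, alpha, method = "spearman")
    } else {
      ny <- shapiro_normal(yi, alpha)$is_normal
      use <- switch(gate,
                    both = if (x_normal && ny) "pearson" else "spearman",
                    either = if (x_normal || ny) "pearson" else "spearman",
                    y_only = if (ny) "pearson" else "spearman")
      adaptive_cor_test(x, yi, alpha, method = use)
    }
    db <- delta_beta_extremes(beta[i, ], samples, spec, group_size)
    pa <- if (adjust_cells) adjust_cell_composition(yi, x, props) else NA_real_
    res$method[i] <- ct$method
    res$r[i] <- ct$r
    res$p[i] <- ct$p
    res$p_cell_adjusted[i] <- pa
    res$delta_beta[i] <- db
    res$direction[i] <- if (ct$r > 0) "hyper" else "hypo"
    p_used <- if (adjust_cells) pa else ct$p
    res$is_dmcpg[i] <- (p_used < alpha) && (abs(db) > min_delta)
  }
  class(res) <- c("association_result", "data.frame")
  res
}
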