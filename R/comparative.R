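# Set-level synthesis over called dmCpG sets: overlap percentages,
# direction proportions, FS/PS count comparisons, CpG-island geography,
# genomic-context and beta-quartile distributions, and hypergeometric
# gene-set over-representation with Benjamini-Hochberg control.

#' Overlap between two dmCpG sets
#'
#' `percent = 100 * |a intersect b| / denominator`, with the denominator
#' chosen by `policy`: `b_count` (size of `b`; use with `b` the FA set in
#' BMI-vs-FA comparisons), `min_count` (the smaller set; FA-vs-FA
#' comparisons), or `a_count`.
#'
#' @param a,b Character vectors of probe IDs.
#' @param policy Denominator policy.
#' @param label_a,label_b Optional labels carried into the output.
#' @return Data frame row with `label_a`, `label_b`, `shared`,
#'   `denominator`, `percent`.
#' @export
overlap <- function(a, b, policy = c("b_count", "min_count", "a_count"),
                    label_a = "a", label_b = "b") {
  policy <- match.arg(policy)
  a <- unique(a); b <- unique(b)
  denominator <- switch(policy,
                        b_count = length(b),
                        a_count = length(a),
                        min_count = min(length(a), length(b)))
  if (denominator == 0L) stop("zero denominator under policy ", policy)
  shared <- length(intersect(a, b))
  data.frame(label_a = label_a, label_b = label_b, shared = shared,
             denominator = denominator, percent = 100 * shared / denominator,
             stringsAsFactors = FALSE)
}

#' Hypo/hyper direction proportions of a dmCpG set
#'
#' @param results An `association_result` or `paired_result` table, or any
#'   data frame with a `direction` column; only `is_dmcpg` rows are used
#'   when that column is present.
#' @return Named numeric vector `c(pct_hypo, pct_hyper)` summing to 100.
#' @export
direction_proportions <- function(results) {
  if ("is_dmcpg" %in% names(results)) results <- results[results$is_dmcpg, , drop = FALSE]
  if (!nrow(results)) stop("empty dmCpG set")
  n <- nrow(results)
  hypo <- sum(results$direction == "hypo")
  c(pct_hypo = 100 * hypo / n, pct_hyper = 100 * (n - hypo) / n)
}

#' Compare two groups of overlap percentages (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test; exact null for combined
#' n <= 20 without ties, tie-corrected normal approximation otherwise.
#' Identical constant groups return p = 1.
#'
#' @param percents_a,percents_b Numeric vectors, each length >= 2.
#' @return List with `U` and `p`.
#' @export
compare_overlap_groups <- function(percents_a, percents_b) {
  if (length(percents_a) < 2L || length(percents_b) < 2L)
    stop("each group needs at least 2 values")
  if (length(unique(c(percents_a, percents_b))) == 1L)
    return(list(U = length(percents_a) * length(percents_b) / 2, p = 1))
  combined <- length(percents_a) + length(percents_b)
  ties <- anyDuplicated(c(percents_a, percents_b)) > 0L
  wt <- suppressWarnings(
    wilcox.test(percents_a, percents_b, exact = combined <= 20L && !ties,
                correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Compare FS and PS dmCpG counts across covariates
#'
#' Computes the mean of per-covariate FS/PS count ratios (terms with a
#' zero PS count dropped with a message) and a p-value from the adaptive
#' paired test applied to the aligned count vectors.
#'
#' @param fs_counts,ps_counts Aligned numeric count vectors (one entry per
#'   covariate).
#' @return List with `mean_ratio`, `p`, `n_used` (ratio terms kept).
#' @export
compare_counts_fs_ps <- function(fs_counts, ps_counts) {
  stopifnot(length(fs_counts) == length(ps_counts))
  usable <- ps_counts > 0
  if (sum(usable) < 3L) stop("fewer than 3 covariates with non-zero PS counts")
  if (any(!usable))
    message(sprintf("dropping %d covariate(s) with zero PS count from the ratio",
                    sum(!usable)))
  ratios <- fs_counts[usable] / ps_counts[usable]
  pt <- suppressMessages(paired_test(ps_counts, fs_counts))
  list(mean_ratio = mean(ratios), p = pt$p, n_used = sum(usable))
}

#' Classify probes into island / shore / shelf / open sea
#'
#' Geography convention (0-based half-open intervals): a position inside
#' `[start, end)` is `island`; the 2,000 gap bases on either side
#' (`end .. end+1999` and `start-2000 .. start-1`) are `shore`; the next
#' 2,000 bases `shelf`; everything farther is `open_sea`. Equivalently, a
#' non-island position with gap distance d to the nearest island edge is
#' shore for d in [0, 2000), shelf for d in [2000, 4000).
#'
#' @param chrom Character vector of chromosomes (parallel to `pos`).
#' @param pos Integer vector of 0-based positions.
#' @param islands An [island_set()] (merged, sorted).
#' @param shore_width,shelf_width Widths in bases (defaults 2000).
#' @return Character vector of classifications.
#' @export
classify_island_relation <- function(chrom, pos, islands,
                                     shore_width = 2000L, shelf_width = 2000L) {
  stopifnot(length(chrom) == length(pos))
  out <- rep("open_sea", length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (!nrow(isl)) next
    p <- pos[idx]
    # islands are disjoint and sorted; locate the flanking intervals
    j <- findInterval(p, isl$start)           # j-th island has start <= p
    inside <- j >= 1L & p < ifelse(j >= 1L, isl$end[pmax(j, 1L)], 0L)
    # gap distance rightward of island j (first base after the end is d = 0)
    d_right <- ifelse(j >= 1L, p - isl$end[pmax(j, 1L)], Inf)
    # gap distance leftward of island j+1 (last base before start is d = 0)
    nxt <- j + 1L
    d_left <- ifelse(nxt <= nrow(isl), isl$start[pmin(nxt, nrow(isl))] - p - 1L, Inf)
    d <- pmin(d_right, d_left)
    cls <- ifelse(inside, "island",
           ifelse(d < shore_width, "shore",
           ifelse(d < shore_width + shelf_width, "shelf", "open_sea")))
    out[idx] <- cls
  }
  out
}

#' Annotate probes with their CpG-island relation
#'
#' @param annotation Probe annotation table.
#' @param islands An [island_set()].
#' @param ... Passed to [classify_island_relation()].
#' @return `annotation` with an `island_relation` column.
#' @export
annotate_island_relation <- function(annotation, islands, ...) {
  annotation$island_relation <-
    classify_island_relation(annotation$chrom, annotation$pos, islands, ...)
  annotation
}

#' Genomic-context distribution of a dmCpG set vs the probe universe
#'
#' Counts dmCpGs per category (gene compartment or CpG-island relation)
#' and tests the counts against the background proportions of the full
#' probe universe by a chi-square goodness-of-fit test (default; the
#' background is orders of magnitude larger than any dmCpG set, so its
#' proportions are treated as fixed). `mode = "contingency"` runs the
#' 2 x k contingency chi-square instead. Categories with expected count
#' < 1 are merged into the neighboring category with a message.
#'
#' @param dm_probes Character vector of dmCpG probe IDs (subset of
#'   `background`).
#' @param annotation Annotation table with the `category` column (use
#'   [annotate_island_relation()] first for island relations).
#' @param background Character vector: the probe universe.
#' @param category `"compartment"` or `"island_relation"`.
#' @param mode `"gof"` or `"contingency"`.
#' @param collapse_promoter Aggregate promoter/utr5/first_exon into one
#'   "promoter" super-category (the 5'-regulatory reporting convention);
#'   raw compartments are used by default.
#' @return List with `categories`, `dm_counts`, `background_counts`,
#'   `chi2`, `df`, `p`.
#' @export
context_distribution <- function(dm_probes, annotation, background,
                                 category = c("compartment", "island_relation"),
                                 mode = c("gof", "contingency"),
                                 collapse_promoter = FALSE) {
  category <- match.arg(category)
  mode <- match.arg(mode)
  dm_probes <- unique(dm_probes)
  if (!length(dm_probes)) stop("empty dmCpG set")
  if (!all(dm_probes %in% background)) stop("dmCpG set must be within the background")
  if (!(category %in% names(annotation)))
    stop(sprintf("annotation lacks the '%s' column", category))
  ann <- annotation[match(background, annotation$probe_id), ]
  if (anyNA(ann$probe_id)) stop("annotation missing background probes")
  labels <- ann[[category]]
  if (collapse_promoter && category == "compartment")
    labels[labels %in% c("promoter", "utr5", "first_exon")] <- "promoter"
  lev <- unique(labels)
  bg_counts <- table(factor(labels, levels = lev))
  dm_counts <- table(factor(labels[match(dm_probes, background)], levels = lev))

  n_dm <- sum(dm_counts)
  expected <- n_dm * as.numeric(bg_counts) / sum(bg_counts)
  # merge categories with expected < 1 into their (left, else right) neighbor
  while (length(expected) > 1L && any(expected < 1)) {
    i <- which(expected < 1)[1L]
    j <- if (i > 1L) i - 1L else i + 1L
    message(sprintf("merging sparse category '%s' into '%s'", lev[i], lev[j]))
    dm_counts[j] <- dm_counts[j] + dm_counts[i]
    bg_counts[j] <- bg_counts[j] + bg_counts[i]
    lev[j] <- paste(lev[j], lev[i], sep = "+")
    dm_counts <- dm_counts[-i]; bg_counts <- bg_counts[-i]; lev <- lev[-i]
    expected <- n_dm * as.numeric(bg_counts) / sum(bg_counts)
  }
  if (mode == "gof") {
    obs <- as.numeric(dm_counts)
    props <- as.numeric(bg_counts) / sum(bg_counts)
    if (length(obs) < 2L) stop("need at least 2 categories")
    chi2 <- sum((obs - n_dm * props)^2 / (n_dm * props))
    df <- length(obs) - 1L
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    tab <- rbind(dm = as.numeric(dm_counts),
                 rest = as.numeric(bg_counts) - as.numeric(dm_counts))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  }
  list(categories = lev, dm_counts = as.numeric(dm_counts),
       background_counts = as.numeric(bg_counts), chi2 = chi2, df = df, p = p)
}

#' Baseline beta-quartile distribution of a dmCpG set
#'
#' Bins each dmCpG's mean baseline beta (over the normoweight samples of
#' one state) into the quartile bins `[0, .25) [.25, .5) [.5, .75)
#' [.75, 1]` (left-closed).
#'
#' @param dm_probes Character vector of probe IDs.
#' @param baseline A `methylation_dataset` restricted to the baseline
#'   (normoweight) samples of one prandial state; every dmCpG must be
#'   present.
#' @return Named integer vector of counts over the four bins, summing to
#'   the set size.
#' @export
quartile_distribution <- function(dm_probes, baseline) {
  stopifnot(inherits(baseline, "methylation_dataset"))
  dm_probes <- unique(dm_probes)
  miss <- setdiff(dm_probes, rownames(baseline$beta))
  if (length(miss)) stop(sprintf("probe %s absent from baseline", miss[1L]))
  if (ncol(baseline$beta) < 1L) stop("baseline needs at least one sample")
  mb <- rowMeans(baseline$beta[dm_probes, , drop = FALSE])
  bins <- cut(mb, breaks = c(0, 0.25, 0.5, 0.75, 1), right = FALSE,
              include.lowest = FALSE,
              labels = c("[0,0.25)", "[0.25,0.5)", "[0.5,0.75)", "[0.75,1]"))
  bins[mb >= 0.75] <- "[0.75,1]"   # close the top bin at 1
  counts <- table(bins)
  setNames(as.integer(counts), names(counts))
}

#' Gene-set over-representation (hypergeometric, BH-corrected)
#'
#' One-sided hypergeometric tail p-value per target set for the overlap
#' between the dmCpG-hosting genes and the set, within an explicit gene
#' universe; Benjamini-Hochberg q-values; significance at `q < fdr_alpha`.
#'
#' @param dm_genes Character vector of dmCpG-hosting genes (subset of
#'   `universe`).
#' @param target_sets Named list of gene sets (e.g. from [read_gmt()]);
#'   each is intersected with the universe.
#' @param universe Character vector: all genes eligible for calling.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return Data frame with `set`, `set_size`, `overlap`, `expected`,
#'   `fold`, `p`, `q`, `significant`, ordered by p.
#' @export
gene_set_enrichment <- function(dm_genes, target_sets, universe,
                                fdr_alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  dm_genes <- unique(dm_genes)
  if (!all(dm_genes %in% universe)) stop("dm_genes must be within the universe")
  n_u <- length(universe); n_dm <- length(dm_genes)
  rows <- lapply(names(target_sets), function(nm) {
    set <- intersect(unique(target_sets[[nm]]), universe)
    k <- length(intersect(dm_genes, set))
    expected <- n_dm * length(set) / n_u
    p <- phyper(k - 1L, length(set), n_u - length(set), n_dm, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k,
               expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_alpha
  out[order(out$p), , drop = FALSE]
}
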