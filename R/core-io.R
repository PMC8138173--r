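# Domain containers and plain-text readers/writers.
#
# Conventions: beta matrices are probes x samples with probe IDs as
# rownames and sample IDs as colnames; all genomic coordinates are
# 0-based half-open (BED native); sample sheets are CSV with fatty-acid
# columns prefixed "fa_" and leukocyte-fraction columns prefixed "cell_".

.ASSOC_COLS <- c("probe_id", "covariate", "prandial_state", "method", "r",
                 "p", "p_cell_adjusted", "delta_beta", "direction", "is_dmcpg")
.PAIRED_COLS <- c("probe_id", "bmi_class", "test", "p", "delta_beta",
                  "direction", "is_dmcpg")

#' Construct a methylation dataset
#'
#' Bundles a probes-by-samples beta matrix with aligned per-sample
#' metadata. Beta values must lie strictly inside (0, 1) (clip on import,
#' see [read_beta_matrix()]); missing values are tolerated here and
#' removed probe-wise by [filter_probes()].
#'
#' @param beta Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param samples Optional sample sheet (`data.frame` as returned by
#'   [read_sample_sheet()]) whose `sample_id` column matches `colnames(beta)`.
#'   Rows are reordered to the column order of `beta`.
#' @return An object of class `methylation_dataset`: a list with elements
#'   `beta` and `samples`.
#' @export
methylation_dataset <- function(beta, samples = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("`beta` must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` needs probe IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe IDs")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample IDs")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] <= 0 || rng[2] >= 1)
    stop("beta-values must lie strictly in (0, 1); clip at import")
  if (!is.null(samples)) {
    samples <- .validate_sample_sheet(samples)
    if (!setequal(samples$sample_id, colnames(beta)))
      stop("sample sheet IDs do not match beta matrix columns")
    samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(beta = beta, samples = samples), class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  if (!is.null(x$samples)) {
    st <- table(x$samples$prandial_state)
    cat("  states:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$beta)

#' Subset a methylation dataset by probes and/or samples
#'
#' @param ds A `methylation_dataset`.
#' @param probes Probe IDs (or logical/integer index) to keep; default all.
#' @param samples Sample IDs (or index) to keep; default all.
#' @return A `methylation_dataset`.
#' @export
subset_dataset <- function(ds, probes = NULL, samples = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  beta <- ds$beta
  if (!is.null(probes)) {
    if (is.character(probes) && !all(probes %in% rownames(beta)))
      stop("unknown probe IDs in subset")
    beta <- beta[probes, , drop = FALSE]
  }
  meta <- ds$samples
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% colnames(beta)))
      stop("unknown sample IDs in subset")
    beta <- beta[, samples, drop = FALSE]
    if (!is.null(meta)) meta <- meta[match(colnames(beta), meta$sample_id), , drop = FALSE]
  }
  structure(list(beta = beta, samples = meta), class = "methylation_dataset")
}

#' Split a dataset into one analysis unit per prandial state
#'
#' @param ds A `methylation_dataset` with attached samples.
#' @return Named list of `methylation_dataset` (`FS`, `PS`), each ordered
#'   by subject ID so paired comparisons align.
#' @export
split_states <- function(ds) {
  stopifnot(inherits(ds, "methylation_dataset"), !is.null(ds$samples))
  out <- lapply(.PRANDIAL_STATES, function(st) {
    keep <- ds$samples$sample_id[ds$samples$prandial_state == st]
    sub <- subset_dataset(ds, samples = keep)
    ord <- order(sub$samples$subject_id)
    subset_dataset(sub, samples = sub$samples$sample_id[ord])
  })
  names(out) <- .PRANDIAL_STATES
  out
}

# ---- beta matrix ----------------------------------------------------------

.read_matrix_tsv <- function(path, what = "value") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("matrix TSV needs a probe-ID column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop(sprintf("duplicate probe IDs (e.g. %s)",
                                       ids[duplicated(ids)][1L]))
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate sample IDs in header")
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- ids
  m
}

#' Read a beta matrix from TSV
#'
#' First column probe IDs, header row sample IDs. Probes containing any
#' missing or unparsable cell are dropped with a message (probe-wise
#' removal, not imputation). Values of exactly 0 or 1 are clipped into
#' `(clip, 1 - clip)` with a warning, since the M-value transform diverges
#' there; values outside `[0, 1]` are an error naming the offending cell.
#'
#' @param path Path to a TSV file.
#' @param clip Clipping constant for beta exactly 0 or 1 (default `1e-6`).
#' @return A `methylation_dataset` without sample metadata; attach it via
#'   [methylation_dataset()] or [read_sample_sheet()]. The number of
#'   probes dropped for missing data is recorded in attribute
#'   `n_removed_missing`.
#' @export
read_beta_matrix <- function(path, clip = 1e-6) {
  m <- .read_matrix_tsv(path)
  out <- range(m, na.rm = TRUE)
  if (out[1] < 0 || out[2] > 1) {
    idx <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta outside [0, 1] at probe %s, sample %s",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  n_clip <- sum(m == 0 | m == 1, na.rm = TRUE)
  if (n_clip > 0L) {
    warning(sprintf("%d beta-value(s) exactly 0 or 1 clipped to [%g, %g]",
                    n_clip, clip, 1 - clip))
    m[m == 0] <- clip
    m[m == 1] <- 1 - clip
  }
  miss <- !complete.cases(m)
  if (any(miss)) {
    message(sprintf("dropping %d probe(s) with missing values", sum(miss)))
    m <- m[!miss, , drop = FALSE]
  }
  ds <- methylation_dataset(m)
  attr(ds, "n_removed_missing") <- sum(miss)
  ds
}

#' Write a beta matrix to TSV
#'
#' @param ds A `methylation_dataset` (or bare numeric matrix).
#' @param path Output path.
#' @param digits Significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(ds, path, digits = 6L) {
  m <- if (inherits(ds, "methylation_dataset")) ds$beta else ds
  df <- data.frame(probe_id = rownames(m), signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample sheet ---------------------------------------------------------

.validate_sample_sheet <- function(df) {
  req <- c("sample_id", "subject_id", "prandial_state", "bmi", "bmi_class", "age")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in sample sheet")
  if (!all(df$prandial_state %in% .PRANDIAL_STATES))
    stop("prandial_state must be one of FS, PS")
  if (!all(df$bmi_class %in% .BMI_CLASSES))
    stop("bmi_class must be one of N, Ow, Ob")
  expect <- bmi_class_of(df$bmi)
  bad <- which(is.na(expect) | expect != df$bmi_class)
  if (length(bad))
    stop(sprintf("bmi_class '%s' inconsistent with bmi = %g for sample %s",
                 df$bmi_class[bad[1L]], df$bmi[bad[1L]], df$sample_id[bad[1L]]))
  fa <- grep("^fa_", names(df), value = TRUE)
  if (length(fa) && any(as.matrix(df[fa]) < 0))
    stop("fatty-acid values must be non-negative")
  cells <- grep("^cell_", names(df), value = TRUE)
  if (length(cells)) {
    cm <- as.matrix(df[cells])
    if (any(cm < 0)) stop("cell proportions must be non-negative")
    s <- rowSums(cm)
    if (any(abs(s - 1) > 1e-6))
      stop(sprintf("cell proportions for sample %s sum to %.8f, not 1",
                   df$sample_id[which.max(abs(s - 1))], s[which.max(abs(s - 1))]))
  }
  df
}

#' Read and validate a sample sheet
#'
#' CSV with required columns `sample_id`, `subject_id`, `prandial_state`
#' (FS/PS), `bmi`, `bmi_class` (N/Ow/Ob), `age`, plus fatty-acid columns
#' prefixed `fa_` and leukocyte-fraction columns prefixed `cell_`.
#'
#' `bmi_class` is validated against the conventional bins (N 18.5-24.9,
#' Ow 25-29.9, Ob > 30). Fatty-acid values are percent-normalized per
#' sample (each FA as percent of the summed measured FA, so rows sum to
#' 100); cell fractions must already sum to 1 within 1e-6.
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame` (class `sample_sheet`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- .validate_sample_sheet(df)
  df <- percent_normalize_fa(df)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Percent-normalize fatty-acid columns of a sample sheet
#'
#' Rescales every `fa_` column so the measured fatty acids sum to 100 per
#' sample. Idempotent.
#'
#' @param df Sample sheet `data.frame`.
#' @return `df` with normalized `fa_` columns.
#' @export
percent_normalize_fa <- function(df) {
  fa <- grep("^fa_", names(df), value = TRUE)
  if (!length(fa)) return(df)
  fm <- as.matrix(df[fa])
  tot <- rowSums(fm)
  if (any(tot <= 0)) stop("fatty-acid profile sums to zero for at least one sample")
  df[fa] <- fm / tot * 100
  df
}

#' @rdname read_sample_sheet
#' @param df Sample sheet to write.
#' @export
write_sample_sheet <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract fatty-acid percentages from a sample sheet
#'
#' @param samples Sample sheet.
#' @return Numeric matrix samples x fatty acids (names without the `fa_`
#'   prefix).
#' @export
fa_matrix <- function(samples) {
  fa <- grep("^fa_", names(samples), value = TRUE)
  if (!length(fa)) stop("sample sheet has no fa_ columns")
  m <- as.matrix(samples[fa])
  colnames(m) <- sub("^fa_", "", fa)
  rownames(m) <- samples$sample_id
  m
}

#' Extract leukocyte proportions from a sample sheet
#'
#' @param samples Sample sheet.
#' @return Numeric matrix samples x cell types.
#' @export
cell_matrix <- function(samples) {
  cells <- grep("^cell_", names(samples), value = TRUE)
  if (!length(cells)) stop("sample sheet has no cell_ columns")
  m <- as.matrix(samples[cells])
  colnames(m) <- sub("^cell_", "", cells)
  rownames(m) <- samples$sample_id
  m
}

# ---- CpG island intervals -------------------------------------------------

#' Construct a merged CpG-island interval set
#'
#' Intervals are 0-based half-open. Input intervals are sorted and
#' overlapping or abutting intervals merged, so the stored set is
#' disjoint and ordered within each chromosome.
#'
#' @param chrom,start,end Parallel vectors describing intervals.
#' @return A `data.frame` of class `island_set` with columns `chrom`,
#'   `start`, `end`.
#' @export
island_set <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("island intervals need end > start")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    merged <- lapply(split(df, df$chrom), function(d) {
      s <- d$start; e <- d$end
      keep_s <- s[1L]; keep_e <- e[1L]
      out_s <- integer(); out_e <- integer()
      if (nrow(d) > 1L) for (i in 2L:nrow(d)) {
        if (s[i] <= keep_e) keep_e <- max(keep_e, e[i]) # abutting merges too
        else { out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
               keep_s <- s[i]; keep_e <- e[i] }
      }
      data.frame(chrom = d$chrom[1L], start = c(out_s, keep_s),
                 end = c(out_e, keep_e), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, merged)
    rownames(df) <- NULL
  }
  class(df) <- c("island_set", "data.frame")
  df
}

#' Read CpG-island intervals from a BED file
#'
#' BED3+ (0-based half-open); extra columns ignored. Unsorted input is
#' accepted and sorted; overlapping/abutting intervals are merged.
#'
#' @param path Path to a BED file. An empty file yields an empty set (all
#'   probes will classify as open sea).
#' @return An `island_set`.
#' @export
read_island_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines)) return(island_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("BED lines need at least 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) stop("non-integer BED coordinates")
  island_set(chrom, start, end)
}

#' @rdname read_island_bed
#' @param islands `island_set` to write.
#' @export
write_island_bed <- function(islands, path) {
  write.table(islands[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- probe annotation -----------------------------------------------------

.COMPARTMENTS <- c("promoter", "utr5", "first_exon", "body", "utr3", "intergenic")

.validate_annotation <- function(df) {
  req <- c("probe_id", "chrom", "pos", "gene", "compartment")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe IDs in annotation")
  if (any(df$pos < 0)) stop("positions must be >= 0 (0-based)")
  if (!all(df$compartment %in% .COMPARTMENTS))
    stop("unknown gene compartment label")
  df$gene[is.na(df$gene)] <- ""
  inter <- df$compartment == "intergenic"
  if (any(inter != (df$gene == "")))
    stop("compartment 'intergenic' must coincide with an empty gene field")
  df
}

#' Read a probe manifest (CSV, 0-based positions)
#'
#' Columns: `probe_id`, `chrom`, `pos` (0-based), `gene` (empty for
#' intergenic), `compartment` (promoter/utr5/first_exon/body/utr3/
#' intergenic).
#'
#' @param path Path to CSV.
#' @return Validated annotation `data.frame`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = c(gene = "character"))
  .validate_annotation(df)
}

#' @rdname read_probe_annotation
#' @param annotation Annotation table to write.
#' @export
write_probe_annotation <- function(annotation, path) {
  write.csv(annotation, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text probe list (one ID per line)
#'
#' @param path Path; blank lines and `#` comments ignored.
#' @return Character vector of probe IDs.
#' @export
read_probe_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read per-probe, per-sample detection p-values
#'
#' Same TSV layout as the beta matrix; values in `[0, 1]`.
#'
#' @param path Path to TSV.
#' @return Numeric matrix probes x samples.
#' @export
read_detection_p <- function(path) {
  m <- .read_matrix_tsv(path)
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("detection p-values outside [0, 1]")
  m
}

# ---- results tables -------------------------------------------------------

.result_schema <- function(results) {
  has_assoc <- all(.ASSOC_COLS %in% names(results))
  has_paired <- all(.PAIRED_COLS %in% names(results))
  only_assoc <- has_assoc && !("bmi_class" %in% names(results))
  only_paired <- has_paired && !("covariate" %in% names(results))
  if (inherits(results, "association_result") || only_assoc) return("association")
  if (inherits(results, "paired_result") || only_paired) return("paired")
  stop("results must be a homogeneous association_result or paired_result table")
}

#' Write a dmCpG results table to TSV
#'
#' Deterministic output: rows ordered by probe ID, floats at 6
#' significant digits, a leading `#` comment recording the package
#' version and any parameters. Association and paired result tables are
#' written with their own fixed column orders; mixed tables are an error.
#'
#' @param results An `association_result` or `paired_result` data frame
#'   (as produced by [call_dm_for_covariate()] / [call_paired_dm()]).
#' @param path Output path.
#' @param params Optional named list echoed into the comment header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = NULL) {
  schema <- .result_schema(results)
  cols <- if (schema == "association") .ASSOC_COLS else .PAIRED_COLS
  df <- as.data.frame(results)[, cols, drop = FALSE]
  df <- df[order(df$probe_id), , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  hdr <- sprintf("# prandem %s; schema=%s%s", as.character(packageVersion("prandem")),
                 schema,
                 if (length(params)) paste0("; ", paste(names(params), unlist(params),
                                                        sep = "=", collapse = "; "))
                 else "")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Path to TSV.
#' @return Data frame with class `association_result` or `paired_result`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  schema <- .result_schema(df)
  class(df) <- c(if (schema == "association") "association_result" else "paired_result",
                 "data.frame")
  df
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("GMT lines need name, description, >= 1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets
}
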