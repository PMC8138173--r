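# Seeded generator of EPIC-like paired cohorts with planted, fully
# recorded effects. Draw order is fixed (subjects -> fatty acids -> cell
# proportions -> annotation -> baselines -> planted effects -> noise) on
# a single RNG stream, so a seed reproduces a cohort byte for byte.

# blood fatty-acid percent means/SDs used by the generator (percent of
# total measured FA, before renormalization)
.FA_SIM <- data.frame(
  name = c("C14:0", "PA", "C18:0",
           "C16:1", "EA", "OA", "C20:1",
           "LA", "EDA", "DGLA", "AA", "EPA", "C22:4n-6", "C22:5n-3", "DHA"),
  group = c(rep("SFA", 3), rep("MUFA", 4), rep("PUFA", 8)),
  mean = c(1.0, 22, 7, 2.0, 0.3, 22, 0.3, 28, 0.3, 1.5, 9, 1.0, 0.4, 0.8, 2.5),
  sd = c(0.3, 2.5, 1.0, 0.6, 0.1, 2.5, 0.1, 3.0, 0.1, 0.4, 1.5, 0.4, 0.15,
         0.25, 0.7),
  stringsAsFactors = FALSE
)

.CELL_MEANS <- c(CD4T = 0.15, CD8T = 0.10, NK = 0.05, Bcell = 0.07,
                 Mono = 0.08, Gran = 0.55)

.logit2 <- function(b) log2(b / (1 - b))
.expit2 <- function(m) 1 / (1 + 2^(-m))

#' Simulation configuration
#'
#' Defaults emulate the target study design: 12 male subjects, 4 per BMI
#' class, measured twice (fasting and postprandial), with a bimodal
#' baseline methylome, i.i.d. M-scale noise, Dirichlet leukocyte
#' fractions, and percent-normalized fatty-acid profiles correlated
#' within saturation group.
#'
#' @param seed Mandatory integer seed.
#' @param n_per_class Subjects per BMI class (default 4; 12 subjects).
#' @param n_probes Number of probes (default 20000).
#' @param n_bmi_probes Probes planted with a BMI association (default 200).
#' @param n_fa_probes Probes planted with a fatty-acid association
#'   (default 100, on `fa_covariate`).
#' @param fa_covariate Fatty acid carrying the planted association
#'   (default `"PA"`).
#' @param n_shift_probes Probes planted with a prandial-state beta shift
#'   (default 150), applied in PS only within `shift_class` and assigned
#'   preferentially to island/promoter probes with low baseline beta.
#' @param shift_class BMI class receiving the prandial shift (default
#'   `"Ow"`).
#' @param shift_delta Beta offset of the prandial shift (default 0.2).
#' @param target_r Target M-scale correlation of planted association
#'   probes (default 0.9).
#' @param target_delta_beta Target extreme-group delta-beta of planted
#'   association probes (default 0.2, absolute; sign set per probe by
#'   `prop_hyper`).
#' @param prop_hyper Fraction of planted association probes with positive
#'   direction (default 0.5).
#' @param baseline_weights Mixture weights of the low/mid/high baseline
#'   beta components, Beta(2,20) / Beta(5,5) / Beta(20,2).
#' @param subject_sd_m M-scale SD of the per-subject, per-probe random
#'   effect (default 0.25). This component is shared between a subject's
#'   fasting and postprandial samples, so it contributes to
#'   between-subject (correlation) variance but cancels in paired
#'   contrasts — the variance decomposition that makes paired designs
#'   powerful.
#' @param noise_sd_m M-scale SD of the within-subject residual noise,
#'   drawn independently per state (default 0.12, the order of
#'   technical-replicate variation on methylation arrays).
#' @param cell_concentration Dirichlet concentration of leukocyte
#'   fractions (default 200).
#' @param confound_gamma_sd SD of per-probe loadings on the centered
#'   granulocyte fraction (default 0 = no cell confounding).
#' @param cell_state_shift Added to the granulocyte mean fraction in PS
#'   (default 0), creating prandial cell-composition confounding.
#' @param cell_bmi_slope Granulocyte mean fraction change per BMI unit
#'   (default 0), creating covariate cell-composition confounding.
#' @param fa_rho Within-saturation-group correlation of fatty acids
#'   (default 0.5).
#' @param fa_state_rho Correlation of a subject's fatty-acid profile
#'   between fasting and postprandial states (default 0.9; blood FA
#'   composition is largely a subject trait).
#' @param frac_sex_probes Fraction of probes placed on chrX/chrY
#'   (default 0.02).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_per_class = 4L, n_probes = 20000L,
                       n_bmi_probes = 200L, n_fa_probes = 100L,
                       fa_covariate = "PA",
                       n_shift_probes = 150L, shift_class = "Ow",
                       shift_delta = 0.2,
                       target_r = 0.9, target_delta_beta = 0.2,
                       prop_hyper = 0.5,
                       baseline_weights = c(low = 0.4, mid = 0.2, high = 0.4),
                       subject_sd_m = 0.25,
                       noise_sd_m = 0.12,
                       cell_concentration = 200,
                       confound_gamma_sd = 0,
                       cell_state_shift = 0,
                       cell_bmi_slope = 0,
                       fa_rho = 0.5,
                       fa_state_rho = 0.9,
                       frac_sex_probes = 0.02) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  stopifnot(n_per_class >= 2L, n_probes > 0L,
            n_bmi_probes >= 0L, n_fa_probes >= 0L, n_shift_probes >= 0L,
            n_bmi_probes + n_fa_probes + n_shift_probes <= n_probes,
            abs(target_delta_beta) <= 0.5,
            fa_covariate %in% .MEASURED_FA,
            shift_class %in% .BMI_CLASSES)
  structure(as.list(environment()), class = "sim_config")
}

#' Preset simulation configurations
#'
#' * `null`: no planted effects, no confounding — calibration runs.
#' * `paperlike`: planted BMI/FA associations (subject traits, present in
#'   both states) and an overweight-only prandial shift, mirroring the
#'   qualitative structure of the target study.
#' * `confounded`: no planted effects, but leukocyte composition both
#'   shifts between states and tracks BMI while probes load on the
#'   granulocyte fraction — for testing cell-composition adjustment.
#'
#' @param preset One of `"null"`, `"paperlike"`, `"confounded"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("null", "paperlike", "confounded"), seed, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    null = list(n_bmi_probes = 0L, n_fa_probes = 0L, n_shift_probes = 0L),
    paperlike = list(),
    confounded = list(n_bmi_probes = 0L, n_fa_probes = 0L, n_shift_probes = 0L,
                      confound_gamma_sd = 3, cell_state_shift = 0.10,
                      cell_bmi_slope = 0.01))
  do.call(sim_config, c(list(seed = seed), utils::modifyList(args, list(...))))
}

# solve the M-scale slope so the noise-free extreme-group delta-beta hits
# the target; returns c(slope, noise_sd) or stops if unreachable
.solve_planted_slope <- function(m0, x_centered, top, bot, target_db, target_r,
                                 probe_id) {
  f <- function(b) mean(.expit2(m0 + b * x_centered[top])) -
    mean(.expit2(m0 + b * x_centered[bot])) - target_db
  lim <- 200
  root <- tryCatch({
    if (target_db > 0) uniroot(f, c(1e-9, lim), tol = 1e-10)$root
    else uniroot(f, c(-lim, -1e-9), tol = 1e-10)$root
  }, error = function(e) NA_real_)
  if (is.na(root))
    stop(sprintf("planted delta-beta %g unreachable from baseline for probe %s",
                 target_db, probe_id))
  s <- abs(root) * sd(x_centered) * sqrt(1 / target_r^2 - 1)
  c(slope = root, noise_sd = s)
}

#' Generate a synthetic probe annotation and island layout
#'
#' Lays regularly spaced CpG islands (with jittered lengths) on a small
#' set of synthetic chromosomes and places probes at construction-known
#' island/shore/shelf/open-sea offsets (~30/25/15/30%), so every probe's
#' true island relation is recomputable from its coordinates. Gene
#' compartments get realistic proportions; intergenic probes carry an
#' empty gene.
#'
#' Draws from the current RNG stream (seed it, or use [generate_cohort()]
#' which seeds for you).
#'
#' @param n_probes Number of probes.
#' @param frac_sex_probes Fraction of probes on chrX/chrY.
#' @return List with `annotation` (including the constructed
#'   `island_relation` column) and `islands` (an [island_set()]).
#' @export
generate_annotation <- function(n_probes, frac_sex_probes = 0.02) {
  stopifnot(n_probes > 0L)
  auto_p <- (1 - frac_sex_probes) / 3
  chrom_p <- c(chr1 = auto_p, chr2 = auto_p, chr3 = auto_p,
               chrX = frac_sex_probes * 0.75, chrY = frac_sex_probes * 0.25)
  chroms <- sample(names(chrom_p), n_probes, replace = TRUE, prob = chrom_p)
  spacing <- 25000L
  tab <- table(factor(chroms, levels = names(chrom_p)))
  n_isl_per_chrom <- setNames(pmax(4L, as.integer(ceiling(tab / 15))),
                              names(chrom_p))
  isl <- do.call(rbind, lapply(names(chrom_p), function(ch) {
    k <- n_isl_per_chrom[[ch]]
    len <- 500L + floor(runif(k) * 1500)      # island lengths 500-2000 bp
    start <- spacing * seq_len(k)
    data.frame(chrom = ch, start = start, end = start + len,
               stringsAsFactors = FALSE)
  }))
  islands <- island_set(isl$chrom, isl$start, isl$end)

  relation <- sample(c("island", "shore", "shelf", "open_sea"), n_probes,
                     replace = TRUE, prob = c(0.30, 0.25, 0.15, 0.30))
  pos <- integer(n_probes)
  for (i in seq_len(n_probes)) {
    cand <- islands[islands$chrom == chroms[i], , drop = FALSE]
    k <- sample.int(nrow(cand), 1L)
    s <- cand$start[k]; e <- cand$end[k]
    side <- sample(c(1L, -1L), 1L)
    pos[i] <- switch(relation[i],
      island = s + floor(runif(1) * (e - s)),
      shore = if (side > 0L) e + floor(runif(1) * 2000)
              else s - 1L - floor(runif(1) * 2000),
      shelf = if (side > 0L) e + 2000L + floor(runif(1) * 2000)
              else s - 2001L - floor(runif(1) * 2000),
      open_sea = e + 4000L + floor(runif(1) * (spacing - (e - s) - 8200L))
    )
  }
  compartment <- sample(.COMPARTMENTS, n_probes, replace = TRUE,
                        prob = c(0.12, 0.05, 0.05, 0.33, 0.05, 0.40))
  n_genes <- max(200L, n_probes %/% 10L)
  gene_pool <- sprintf("GENE%05d", seq_len(n_genes))
  gene <- ifelse(compartment == "intergenic", "",
                 sample(gene_pool, n_probes, replace = TRUE))
  ann <- data.frame(probe_id = sprintf("cg%08d", seq_len(n_probes)),
                    chrom = chroms, pos = pos, gene = gene,
                    compartment = compartment, island_relation = relation,
                    stringsAsFactors = FALSE)
  list(annotation = .validate_annotation(ann), islands = islands)
}

#' Generate a paired synthetic cohort with planted effects
#'
#' Produces fasting and postprandial `methylation_dataset`s for the same
#' subjects, an annotation table with island layout, and a truth table of
#' every planted effect (enabling sensitivity/specificity scoring).
#'
#' Baseline beta comes from a 3-component mixture (low Beta(2,20), mid
#' Beta(5,5), high Beta(20,2)) reproducing array bimodality; unplanted
#' probes are i.i.d. noise on the M scale around their baseline in both
#' states. BMI/FA-planted probes carry a subject-trait effect in both
#' states, `M = m0 + slope * covariate + noise`, with the slope solved
#' numerically so the noise-free extreme-group delta-beta hits the target
#' and the noise SD set so the population M-scale correlation equals
#' `target_r`. Prandial-shift probes get a beta offset in PS only, in the
#' configured class, on island/promoter probes with low baseline beta.
#' Optional confounding makes leukocyte composition track BMI and/or the
#' prandial state while probes load on the granulocyte fraction.
#'
#' @param config A [sim_config()].
#' @return List with `fs`, `ps` (datasets), `annotation`, `islands`,
#'   `truth` (data frame, one row per planted probe), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npc <- config$n_per_class
  n_sub <- 3L * npc
  subjects <- sprintf("S%02d", seq_len(n_sub))
  bmi_class <- rep(.BMI_CLASSES, each = npc)
  bmi <- c(runif(npc, 18.5, 24.9), runif(npc, 25, 29.9), runif(npc, 30, 40))
  age <- runif(n_sub, 25, 45)

  # fatty acids: a per-subject trait (correlated within saturation group)
  # plus a smaller state-specific deviation, so FS and PS profiles of one
  # subject are strongly correlated, then percent normalization
  draw_fa_z <- function() {
    z <- matrix(0, n_sub, nrow(.FA_SIM))
    for (g in unique(.FA_SIM$group)) {
      idx <- which(.FA_SIM$group == g)
      zg <- rnorm(n_sub)
      for (j in idx)
        z[, j] <- sqrt(config$fa_rho) * zg + sqrt(1 - config$fa_rho) * rnorm(n_sub)
    }
    z
  }
  z_trait <- draw_fa_z()
  rs <- config$fa_state_rho
  fa_from_z <- function(z) {
    out <- matrix(0, n_sub, nrow(.FA_SIM),
                  dimnames = list(subjects, .FA_SIM$name))
    for (j in seq_len(nrow(.FA_SIM)))
      out[, j] <- pmax(.FA_SIM$mean[j] + .FA_SIM$sd[j] * z[, j],
                       0.05 * .FA_SIM$mean[j])
    out / rowSums(out) * 100
  }
  fa_fs <- fa_from_z(sqrt(rs) * z_trait + sqrt(1 - rs) * draw_fa_z())
  fa_ps <- fa_from_z(sqrt(rs) * z_trait + sqrt(1 - rs) * draw_fa_z())

  # leukocyte fractions: Dirichlet around per-subject means; the optional
  # BMI- and state-linked granulocyte effects are applied on the
  # normalized (sum-to-1) scale so the configured shifts arrive undiluted,
  # with the other cell types scaled down proportionally
  draw_cells <- function(state) {
    t(vapply(seq_len(n_sub), function(i) {
      mu <- .CELL_MEANS
      gran <- mu[["Gran"]] + config$cell_bmi_slope * (bmi[i] - 27) +
        if (state == "PS") config$cell_state_shift else 0
      gran <- min(max(gran, 0.05), 0.90)
      mu <- mu * (1 - gran) / (1 - mu[["Gran"]])
      mu["Gran"] <- gran
      g <- rgamma(length(mu), shape = config$cell_concentration * mu)
      g / sum(g)
    }, numeric(length(.CELL_MEANS))))
  }
  cells_fs <- draw_cells("FS"); cells_ps <- draw_cells("PS")
  colnames(cells_fs) <- colnames(cells_ps) <- .CELL_TYPES

  gen <- generate_annotation(config$n_probes, config$frac_sex_probes)
  ann <- gen$annotation; islands <- gen$islands
  probe_ids <- ann$probe_id
  np <- config$n_probes

  comp <- sample(c("low", "mid", "high"), np, replace = TRUE,
                 prob = config$baseline_weights)
  beta0 <- numeric(np)
  beta0[comp == "low"] <- rbeta(sum(comp == "low"), 2, 20)
  beta0[comp == "mid"] <- rbeta(sum(comp == "mid"), 5, 5)
  beta0[comp == "high"] <- rbeta(sum(comp == "high"), 20, 2)
  beta0 <- pmin(pmax(beta0, 1e-4), 1 - 1e-4)
  m0 <- .logit2(beta0)

  # planted-probe assignment; association probes use mid-baseline
  # autosomal probes (keeps the delta-beta target reachable), prandial
  # shifts prefer low-baseline island/promoter probes
  autosomal <- !(ann$chrom %in% c("chrX", "chrY"))
  mid_pool <- which(comp == "mid" & autosomal)
  n_assoc <- config$n_bmi_probes + config$n_fa_probes
  if (length(mid_pool) < n_assoc)
    stop("not enough mid-baseline probes to host the planted associations")
  assoc_idx <- sample(mid_pool, n_assoc)
  bmi_idx <- assoc_idx[seq_len(config$n_bmi_probes)]
  fa_idx <- setdiff(assoc_idx, bmi_idx)

  promoterish <- ann$compartment %in% c("promoter", "utr5", "first_exon")
  shift_pool <- setdiff(
    which(ann$island_relation == "island" & promoterish & beta0 < 0.3 & autosomal),
    assoc_idx)
  if (length(shift_pool) < config$n_shift_probes)
    shift_pool <- setdiff(which(ann$island_relation == "island" & beta0 < 0.3 &
                                  autosomal), assoc_idx)
  if (length(shift_pool) < config$n_shift_probes)
    stop("not enough low-baseline island probes to host the prandial shift")
  shift_idx <- sample(shift_pool, config$n_shift_probes)

  # planted slopes/noise for association probes (fasting state)
  xc_bmi <- bmi - mean(bmi)
  top_bmi <- bmi_class == "Ob"; bot_bmi <- bmi_class == "N"
  x_fa <- fa_fs[, config$fa_covariate]
  xc_fa <- x_fa - mean(x_fa)
  x_fa_ps <- fa_ps[, config$fa_covariate]
  xc_fa_ps <- x_fa_ps - mean(x_fa_ps)
  gs <- n_sub %/% 3L
  ord_fa <- order(x_fa)
  bot_fa <- seq_len(n_sub) %in% ord_fa[seq_len(gs)]
  top_fa <- seq_len(n_sub) %in% ord_fa[seq.int(n_sub - gs + 1L, n_sub)]

  truth <- data.frame(probe_id = character(), effect_kind = character(),
                      covariate = character(), target_r = numeric(),
                      target_delta_beta = numeric(), direction = character(),
                      noise_sd = numeric(), stringsAsFactors = FALSE)
  slope <- rep(0, np)
  # across-subject noise splits into a per-subject effect (shared between
  # states) and within-subject residuals; planted probes get their solved
  # total SD, with the within-subject part held at noise_sd_m
  subject_sd <- rep(config$subject_sd_m, np)
  noise_sd <- rep(config$noise_sd_m, np)
  plant_assoc <- function(idx, kind, covname, xc, top, bot) {
    for (i in idx) {
      dir_sign <- if (runif(1) < config$prop_hyper) 1 else -1
      sol <- .solve_planted_slope(m0[i], xc, top, bot,
                                  dir_sign * config$target_delta_beta,
                                  config$target_r, probe_ids[i])
      slope[i] <<- sol[["slope"]]
      subject_sd[i] <<- sqrt(max(sol[["noise_sd"]]^2 - config$noise_sd_m^2, 0))
      truth <<- rbind(truth, data.frame(
        probe_id = probe_ids[i], effect_kind = kind, covariate = covname,
        target_r = dir_sign * config$target_r,
        target_delta_beta = dir_sign * config$target_delta_beta,
        direction = if (dir_sign > 0) "hyper" else "hypo",
        noise_sd = sol[["noise_sd"]], stringsAsFactors = FALSE))
    }
  }
  plant_assoc(bmi_idx, "bmi_assoc", "BMI", xc_bmi, top_bmi, bot_bmi)
  plant_assoc(fa_idx, "fa_assoc", config$fa_covariate, xc_fa, top_fa, bot_fa)
  if (config$n_shift_probes > 0L) {
    truth <- rbind(truth, data.frame(
      probe_id = probe_ids[shift_idx], effect_kind = "prandial_shift",
      covariate = config$shift_class, target_r = NA_real_,
      target_delta_beta = config$shift_delta, direction = "hyper",
      noise_sd = config$noise_sd_m, stringsAsFactors = FALSE))
  }

  gamma <- if (config$confound_gamma_sd > 0) rnorm(np, 0, config$confound_gamma_sd)
           else rep(0, np)
  gran_fs <- cells_fs[, "Gran"] - mean(.CELL_MEANS["Gran"])
  gran_ps <- cells_ps[, "Gran"] - mean(.CELL_MEANS["Gran"])

  # planted association effects are subject traits: present in both
  # states (BMI identical, fatty acids via each state's own values)
  u_subject <- matrix(rnorm(np * n_sub), np, n_sub) * subject_sd
  make_m <- function(gran_centered, xc_fa_state) {
    eps <- matrix(rnorm(np * n_sub), np, n_sub) * noise_sd
    m <- m0 + u_subject + eps + outer(gamma, gran_centered)
    m[bmi_idx, ] <- m[bmi_idx, ] + outer(slope[bmi_idx], xc_bmi)
    m[fa_idx, ] <- m[fa_idx, ] + outer(slope[fa_idx], xc_fa_state)
    m
  }
  m_fs <- make_m(gran_fs, xc_fa)
  m_ps <- make_m(gran_ps, xc_fa_ps)
  beta_fs <- .expit2(m_fs)
  beta_ps <- .expit2(m_ps)
  if (config$n_shift_probes > 0L) {
    in_class <- bmi_class == config$shift_class
    beta_ps[shift_idx, in_class] <- beta_ps[shift_idx, in_class] +
      config$shift_delta
  }
  clamp <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)
  beta_fs <- clamp(beta_fs); beta_ps <- clamp(beta_ps)
  dimnames(beta_fs) <- list(probe_ids, paste0(subjects, "_FS"))
  dimnames(beta_ps) <- list(probe_ids, paste0(subjects, "_PS"))

  sheet <- function(state, fa, cells) {
    df <- data.frame(sample_id = paste0(subjects, "_", state),
                     subject_id = subjects, prandial_state = state,
                     bmi = bmi, bmi_class = bmi_class, age = age,
                     stringsAsFactors = FALSE)
    fa_df <- as.data.frame(fa); names(fa_df) <- paste0("fa_", colnames(fa))
    cell_df <- as.data.frame(cells); names(cell_df) <- paste0("cell_", colnames(cells))
    out <- cbind(df, fa_df, cell_df)
    class(out) <- c("sample_sheet", "data.frame")
    rownames(out) <- NULL
    out
  }
  fs <- methylation_dataset(beta_fs, sheet("FS", fa_fs, cells_fs))
  ps <- methylation_dataset(beta_ps, sheet("PS", fa_ps, cells_ps))
  list(fs = fs, ps = ps, annotation = ann, islands = islands,
       truth = truth, config = config)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `beta.tsv` (both states side by side), `samples.csv`,
#' `annotation.csv`, `islands.bed` and `truth.tsv` under `dir`.
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta <- cbind(cohort$fs$beta, cohort$ps$beta)
  write_beta_matrix(beta, file.path(dir, "beta.tsv"), digits = 8L)
  samples <- rbind(cohort$fs$samples, cohort$ps$samples)
  write_sample_sheet(samples, file.path(dir, "samples.csv"))
  write_probe_annotation(
    cohort$annotation[, c("probe_id", "chrom", "pos", "gene", "compartment")],
    file.path(dir, "annotation.csv"))
  write_island_bed(cohort$islands, file.path(dir, "islands.bed"))
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
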