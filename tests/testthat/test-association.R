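test_that("Shapiro-Wilk gate accepts normal-looking and rejects outlier vectors", {
  quantiles12 <- c(-1.64, -1.11, -0.79, -0.53, -0.31, -0.10,
                   0.10, 0.31, 0.53, 0.79, 1.11, 1.64)
  sw <- shapiro_normal(quantiles12)
  expect_true(sw$is_normal)
  expect_equal(sw$p, shapiro.test(quantiles12)$p.value) # reference oracle

  outlier <- c(rep(0, 11), 100)
  expect_false(shapiro_normal(outlier)$is_normal)
  expect_lt(shapiro_normal(outlier)$p, 0.05)

  expect_error(shapiro_normal(rep(1, 4)), "constant")
})

test_that("adaptive correlation picks Pearson/Spearman and matches oracles", {
  set.seed(11)
  x <- qnorm((1:12 - 0.5) / 12) * 2 + 10 # normal-passing x
  y <- 2 * x + 1
  ct <- adaptive_cor_test(x, y)
  expect_equal(ct$method, "pearson")
  expect_equal(ct$r, 1.0)

  # monotone nonlinear with a non-normal vector -> spearman, rho = 1
  xo <- c(rep(0, 11), 100) + (1:12) * 1e-3
  yo <- exp(xo / 20)
  cto <- adaptive_cor_test(xo, yo)
  expect_equal(cto$method, "spearman")
  expect_equal(cto$r, 1.0)

  # spearman branch equals brute-force rank-then-Pearson, exact
  xs <- 1:12
  ys <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11)
  cts <- adaptive_cor_test(xs, ys, method = "spearman")
  rho_oracle <- cor(rank(xs), rank(ys))
  expect_equal(cts$r, rho_oracle, tolerance = 1e-12)
  t_or <- rho_oracle * sqrt((12 - 2) / (1 - rho_oracle^2))
  expect_equal(cts$p, 2 * pt(-abs(t_or), 10), tolerance = 1e-12)

  # property: rank-then-Pearson oracle on random vectors
  for (i in 1:50) {
    xr <- rnorm(12); yr <- rnorm(12)
    expect_equal(adaptive_cor_test(xr, yr, method = "spearman")$r,
                 cor(rank(xr), rank(yr)), tolerance = 1e-12)
  }

  expect_error(adaptive_cor_test(rep(1, 12), rnorm(12)), "constant")
  expect_error(adaptive_cor_test(1:3, 1:3), "n >= 4")
})

test_that("correlation is invariant to M shifts and covariate rescaling", {
  set.seed(12)
  x <- rnorm(12, 25, 4); y <- rnorm(12)
  a <- adaptive_cor_test(x, y)
  b <- adaptive_cor_test(x, y + 5)
  expect_equal(a[c("r", "p")], b[c("r", "p")])
  cs <- adaptive_cor_test(x, y, method = "spearman")
  cs2 <- adaptive_cor_test(x * 100 + 3, y, method = "spearman")
  expect_equal(cs[c("r", "p")], cs2[c("r", "p")])
  cp2 <- adaptive_cor_test(x * 100 + 3, y, method = "pearson")
  expect_equal(adaptive_cor_test(x, y, method = "pearson")$r, cp2$r)
})

test_that("covariate values: BMI passthrough, FA sums, exclusions", {
  sheet <- make_sheet()
  expect_equal(unname(covariate_values(sheet, covariate_spec("BMI"))), sheet$bmi)

  sfa <- covariate_spec("SFA")
  expect_equal(unname(covariate_values(sheet, sfa)),
               sheet$`fa_C14:0` + sheet$fa_PA + sheet$`fa_C18:0`)
  pa <- covariate_values(sheet, covariate_spec("PA"))
  expect_equal(unname(pa), sheet$fa_PA)

  expect_error(covariate_spec("C18:3"), "excluded")
  expect_error(covariate_spec("glucose"), "excluded")
  expect_error(covariate_spec("nonsense", kind = "individual_fa"), "unknown")
})

test_that("delta-beta extremes: class means for BMI, tertiles for FA", {
  sheet <- make_sheet()
  beta_row <- ifelse(sheet$bmi_class == "Ob", 0.45,
                     ifelse(sheet$bmi_class == "N", 0.30, 0.99))
  expect_equal(delta_beta_extremes(beta_row, sheet, covariate_spec("BMI")), 0.15)
  expect_equal(delta_beta_extremes(rep(0.4, 12), sheet, covariate_spec("BMI")), 0)

  # FA covariate 1..12 with beta = covariate/100:
  # mean(top 4 ranks) - mean(bottom 4 ranks) = 0.105 - 0.025 = 0.08
  sheet2 <- sheet
  sheet2$fa_PA <- 1:12
  other <- setdiff(grep("^fa_", names(sheet2), value = TRUE), "fa_PA")
  sheet2[other] <- 1
  beta_cov <- sheet2$fa_PA / 100
  expect_equal(delta_beta_extremes(beta_cov, sheet2, covariate_spec("PA")), 0.08)
})

test_that("cell-composition adjustment reduces to the unadjusted fit and finds signal", {
  set.seed(13)
  x <- rnorm(12, 25, 4)
  y <- 0.3 * x + rnorm(12)
  props <- matrix(rep(c(0.2, 0.3, 0.5), each = 12), 12) # constant across samples
  p_adj <- adjust_cell_composition(y, x, props)
  expect_equal(p_adj, cor.test(x, y)$p.value, tolerance = 1e-10)

  props2 <- t(replicate(12, { g <- rgamma(6, 20); g / sum(g) }))
  # exact M = covariate: lm warns about a perfect fit, p is effectively 0
  expect_lt(suppressWarnings(adjust_cell_composition(x, x, props2)), 1e-6)

  # null calibration: M depends only on cells, covariate independent
  set.seed(14)
  reps <- 2000L
  rej <- mean(replicate(reps, {
    props3 <- t(replicate(12, { g <- rgamma(6, 50); g / sum(g) }))
    m <- 5 * props3[, 6] + rnorm(12, 0, 0.2)
    adjust_cell_composition(m, rnorm(12), props3) < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("dmCpG calling applies the dual criterion with correct direction", {
  sheet <- make_sheet()
  # noiseless planted probe: beta = 0.30 + 0.02 * (BMI - 20)
  planted <- 0.30 + 0.02 * (sheet$bmi - 20)
  flat <- rep(0.5, 12)
  near_flat <- 0.5 + 1e-4 * scale(sheet$age)[, 1] # non-constant, null
  ds <- make_dataset(list(planted, near_flat, flat))
  expect_message(res <- call_dm_for_covariate(ds, covariate_spec("BMI")),
                 "constant")
  expect_equal(nrow(res), 2L) # constant probe excluded
  row <- res[res$probe_id == "cg00001", ]
  expect_true(row$is_dmcpg)
  expect_equal(row$direction, "hyper")
  # beta exactly linear in BMI: monotone perfect association (Pearson on
  # the logit scale is near 1; the Spearman branch would be exactly 1)
  expect_gt(row$r, 0.99)
  db_expect <- mean(planted[sheet$bmi_class == "Ob"]) -
    mean(planted[sheet$bmi_class == "N"])
  expect_equal(row$delta_beta, db_expect)
  expect_gt(row$delta_beta, 0.1)

  # all-near-constant cohort yields no calls
  expect_false(res$is_dmcpg[res$probe_id == "cg00002"])
})

test_that("dual criterion is a subset of p-only; directions partition the calls", {
  co <- generate_cohort(sim_config(seed = 5, n_probes = 600, n_bmi_probes = 30,
                                   n_fa_probes = 0, n_shift_probes = 0))
  res <- call_dm_for_covariate(co$fs, covariate_spec("BMI"))
  p_only <- res$probe_id[res$p < 0.05]
  dual <- res$probe_id[res$is_dmcpg]
  expect_true(all(dual %in% p_only))
  dm <- res[res$is_dmcpg, ]
  expect_true(all(dm$direction %in% c("hypo", "hyper")))
  dp <- direction_proportions(res)
  expect_equal(sum(dp), 100)

  # probe-by-probe re-implementation of the calling rule (brute force)
  sheet <- co$fs$samples
  x <- sheet$bmi
  x_norm <- shapiro.test(x)$p.value >= 0.05
  for (i in seq_len(nrow(res))) {
    b <- co$fs$beta[res$probe_id[i], ]
    m <- log2(b / (1 - b))
    use_pearson <- x_norm && shapiro.test(m)$p.value >= 0.05
    ct <- if (use_pearson) cor.test(x, m)
          else suppressWarnings(cor.test(x, m, method = "spearman", exact = FALSE))
    db <- mean(b[sheet$bmi_class == "Ob"]) - mean(b[sheet$bmi_class == "N"])
    expect_equal(res$method[i], if (use_pearson) "pearson" else "spearman")
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(res$delta_beta[i], db, tolerance = 1e-12)
    expect_identical(res$is_dmcpg[i], unname(ct$p.value < 0.05 && abs(db) > 0.10))
  }
})
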