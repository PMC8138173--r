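test_that("overlap percentages follow the denominator policy", {
  a <- c("p1", "p2", "p3")
  b <- c("p2", "p3", "p4", "p5")
  expect_equal(overlap(a, a, "min_count")$percent, 100)
  expect_equal(overlap(a, c("q1", "q2"), "b_count")$percent, 0)
  ov <- overlap(a, b, "min_count")
  expect_equal(ov$shared, 2L)
  expect_equal(ov$percent, 100 * 2 / 3)
  expect_equal(overlap(a, b, "b_count")$percent, 50)
  expect_equal(overlap(a, b, "a_count")$shared, overlap(b, a, "a_count")$shared)
  expect_error(overlap(a, character(), "b_count"), "denominator")
})

test_that("direction proportions partition the set", {
  res <- data.frame(direction = c("hypo", "hypo", "hypo", "hyper"))
  expect_equal(direction_proportions(res),
               c(pct_hypo = 75, pct_hyper = 25))
  expect_equal(direction_proportions(data.frame(direction = rep("hyper", 5))),
               c(pct_hypo = 0, pct_hyper = 100))
  expect_error(direction_proportions(res[0, , drop = FALSE]), "empty")
})

test_that("Mann-Whitney comparison matches full rank-assignment enumeration", {
  expect_equal(compare_overlap_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # complete separation of 4 vs 4: exact two-sided p = 2/70
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  res <- compare_overlap_groups(a, b)
  combos <- combn(8, 4)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[1:4]) - 4 * 5 / 2
  u_all <- apply(combos, 2, function(idx) sum(seq_len(8)[idx]) - 4 * 5 / 2)
  p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(p_enum, 2 / 70)
  expect_equal(res$p, p_enum)

  # symmetry under group swap
  set.seed(31)
  x <- runif(5) * 100; y <- runif(6) * 100
  expect_equal(compare_overlap_groups(x, y)$p, compare_overlap_groups(y, x)$p)

  # random cases vs enumeration (combined n <= 12, no ties)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    v <- sample(1000, na + nb) / 7
    pa <- v[seq_len(na)]; pb <- v[-seq_len(na)]
    cmb <- combn(na + nb, na)
    r_all <- apply(cmb, 2, function(idx) sum(rank(v)[idx]))
    r_obs <- sum(rank(v)[seq_len(na)])
    p_en <- min(1, 2 * min(mean(r_all <= r_obs), mean(r_all >= r_obs)))
    expect_equal(compare_overlap_groups(pa, pb)$p, p_en, tolerance = 1e-12)
  }
})

test_that("FS/PS count comparison computes mean ratios and a paired p", {
  same <- compare_counts_fs_ps(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$mean_ratio, 1)
  expect_equal(same$p, 1) # zero differences
  expect_equal(compare_counts_fs_ps(c(10, 20, 30), c(5, 10, 15))$mean_ratio, 2)
  fs <- c(10, 20, 30, 40, 50); ps <- c(5, 5, 10, 10, 25)
  expect_equal(compare_counts_fs_ps(fs, ps)$mean_ratio, 3)
  expect_error(compare_counts_fs_ps(c(1, 2, 3), c(0, 0, 1)), "fewer than 3")
})

test_that("island geography follows the half-open 2 kb shore / 2 kb shelf rule", {
  isl <- island_set("chr1", 10000, 11000)
  cls <- function(p) classify_island_relation("chr1", p, isl)
  expect_equal(cls(10500), "island")
  expect_equal(cls(10000), "island") # start is inside (half-open)
  expect_equal(cls(11000), "shore")  # end is outside
  expect_equal(cls(12999), "shore")
  expect_equal(cls(13000), "shelf")
  expect_equal(cls(14999), "shelf")
  expect_equal(cls(15000), "open_sea")
  expect_equal(cls(9999), "shore")   # left flank, last base before start
  expect_equal(cls(8000), "shore")
  expect_equal(cls(7999), "shelf")
  expect_equal(cls(6000), "shelf")
  expect_equal(cls(5999), "open_sea")

  # brute-force per-base scan over the whole window
  pos <- 5000:16000
  brute <- vapply(pos, function(p) {
    if (p >= 10000 && p < 11000) return("island")
    d <- if (p >= 11000) p - 11000 else 10000 - p - 1
    if (d < 2000) "shore" else if (d < 4000) "shelf" else "open_sea"
  }, "")
  expect_equal(classify_island_relation(rep("chr1", length(pos)), pos, isl), brute)
})

test_that("island classifier agrees with a brute-force scan on random layouts", {
  set.seed(32)
  brute_classify <- function(p, starts, ends) {
    if (any(p >= starts & p < ends)) return("island")
    d <- min(ifelse(p >= ends, p - ends, starts - p - 1))
    if (d < 2000) "shore" else if (d < 4000) "shelf" else "open_sea"
  }
  for (rep_i in 1:100) {
    k <- sample(1:4, 1)
    starts <- sort(sample(0:50000, k))
    ends <- starts + sample(200:3000, k, replace = TRUE)
    isl <- island_set(rep("chrZ", k), starts, ends)
    pos <- sample(0:60000, 200)
    got <- classify_island_relation(rep("chrZ", 200), pos, isl)
    want <- vapply(pos, brute_classify, "", starts = isl$start, ends = isl$end)
    expect_equal(got, want)
  }
})

test_that("context distribution: chi-square GOF against background proportions", {
  ann <- data.frame(probe_id = sprintf("cg%04d", 1:1000),
                    chrom = "chr1", pos = seq_len(1000) * 10, gene = "G1",
                    compartment = rep(c("promoter", "body"), c(500, 500)),
                    stringsAsFactors = FALSE)
  bg <- ann$probe_id

  # observed (90, 10) against background proportions (0.5, 0.5):
  # chi2 = (90-50)^2/50 + (10-50)^2/50 = 64
  dm <- c(ann$probe_id[1:90], ann$probe_id[501:510])
  cd <- context_distribution(dm, ann, bg, "compartment")
  expect_equal(cd$chi2, 64)
  expect_equal(cd$df, 1L)
  expect_lt(cd$p, 1e-14)
  expect_equal(cd$p, pchisq(64, 1, lower.tail = FALSE))

  # dmset proportional to background -> chi2 = 0, p = 1
  dm0 <- c(ann$probe_id[1:50], ann$probe_id[501:550])
  cd0 <- context_distribution(dm0, ann, bg, "compartment")
  expect_equal(cd0$chi2, 0)
  expect_equal(cd0$p, 1)

  # additivity over a partition of the dmset
  part1 <- dm[1:40]; part2 <- dm[41:100]
  c1 <- context_distribution(part1, ann, bg, "compartment")
  c2 <- context_distribution(part2, ann, bg, "compartment")
  expect_equal(c1$dm_counts + c2$dm_counts, cd$dm_counts)

  expect_error(context_distribution(character(), ann, bg), "empty")
  expect_error(context_distribution("cgXXXX", ann, bg), "within")
})

test_that("GOF p-values are uniform under random subsampling of the background", {
  set.seed(33)
  ann <- data.frame(probe_id = sprintf("cg%05d", 1:5000), chrom = "chr1",
                    pos = 1:5000, gene = "G",
                    compartment = sample(c("promoter", "body", "utr3"), 5000,
                                         replace = TRUE, prob = c(.3, .5, .2)),
                    stringsAsFactors = FALSE)
  ps <- replicate(400, {
    dm <- sample(ann$probe_id, 150)
    context_distribution(dm, ann, ann$probe_id, "compartment")$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("beta-quartile bins are left-closed with a closed top bin", {
  sheet <- make_sheet()
  vals <- c(0.1, 0.3, 0.6, 0.9)
  rows <- lapply(vals, function(v) rep(v, 12))
  ds <- make_dataset(rows)
  n_only <- subset_dataset(ds, samples = sheet$sample_id[sheet$bmi_class == "N"])
  qd <- quartile_distribution(rownames(ds$beta), n_only)
  expect_equal(unname(qd), c(1L, 1L, 1L, 1L))

  ds2 <- make_dataset(lapply(1:4, function(i) rep(0.5, 12)))
  qd2 <- quartile_distribution(rownames(ds2$beta),
                               subset_dataset(ds2, samples = sheet$sample_id[1:4]))
  expect_equal(unname(qd2), c(0L, 0L, 4L, 0L))

  ds3 <- make_dataset(list(rep(0.25, 12)))
  qd3 <- quartile_distribution("cg00001", ds3)
  expect_equal(unname(qd3), c(0L, 1L, 0L, 0L))

  expect_error(quartile_distribution("missing", ds3), "absent")
})

test_that("hypergeometric enrichment matches the explicit tail sum, BH is monotone", {
  # universe 20, dm 5, target 8, overlap 4
  universe <- sprintf("g%02d", 1:20)
  target <- universe[1:8]
  dm <- c(universe[1:4], universe[20])
  p_oracle <- sum(sapply(4:5, function(k)
    choose(8, k) * choose(12, 5 - k) / choose(20, 5)))
  enr <- gene_set_enrichment(dm, list(T1 = target), universe)
  expect_equal(enr$p, p_oracle, tolerance = 1e-12)
  expect_equal(enr$overlap, 4L)

  # maximal enrichment
  uni2 <- sprintf("g%04d", 1:1000)
  enr2 <- gene_set_enrichment(uni2[1:10], list(S = uni2[1:10]), uni2)
  expect_equal(enr2$p, 1 / choose(1000, 10), tolerance = 1e-9)
  expect_true(enr2$significant)

  # disjoint set: tail at overlap 0 is large, not significant
  enr3 <- gene_set_enrichment(uni2[1:10], list(S = uni2[900:950]), uni2)
  expect_false(enr3$significant)

  # BH: q monotone in p-rank and q >= p
  set.seed(34)
  sets <- lapply(1:8, function(i) sample(uni2, 50))
  names(sets) <- paste0("S", 1:8)
  enr4 <- gene_set_enrichment(sample(uni2, 100), sets, uni2)
  expect_true(all(diff(enr4$q) >= -1e-12))
  expect_true(all(enr4$q >= enr4$p - 1e-12))
})
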