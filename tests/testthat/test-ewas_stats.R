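test_that("group means, delta and antisymmetry behave as printed tables demand", {
  bm <- make_bm(cases = matrix(c(0.55, 0.55, 0.55), 1),
                controls = matrix(c(0.01, 0.01, 0.01), 1),
                probe_ids = "cg12630522")
  st <- probe_group_stats(bm, "cg12630522")
  expect_equal(st$delta_beta, 0.54)
  expect_equal(st$mean_cases, 0.55)
  expect_equal(st$mean_controls, 0.01)

  # identical groups: delta 0
  bm0 <- make_bm(matrix(c(0.3, 0.4), 1), matrix(c(0.3, 0.4), 1))
  expect_equal(probe_group_stats(bm0, "cg00001")$delta_beta, 0)

  # swapping group labels negates delta and flips the t sign
  set.seed(31)
  x <- matrix(runif(8), 1); y <- matrix(runif(8), 1)
  bm1 <- make_bm(x, y); bm2 <- make_bm(y, x)
  expect_equal(probe_group_stats(bm1, "cg00001")$delta_beta,
               -probe_group_stats(bm2, "cg00001")$delta_beta)
  expect_equal(probe_t_test(bm1, "cg00001")$t_stat,
               -probe_t_test(bm2, "cg00001")$t_stat)

  # missing values are excluded, not treated as zero
  bmna <- make_bm(matrix(c(0.5, NA, 0.5), 1), matrix(c(0.1, 0.1, NA), 1))
  st <- probe_group_stats(bmna, "cg00001")
  expect_equal(st$mean_cases, 0.5)
  expect_equal(st$n_cases_used, 2)
  expect_equal(st$n_controls_used, 2)
})

test_that("probe t-test matches stats::t.test to 1e-12 for both variants", {
  set.seed(41)
  for (rep in 1:20) {
    n1 <- sample(3:20, 1); n2 <- sample(3:30, 1)
    x <- matrix(runif(n1), 1); y <- matrix(runif(n2), 1)
    bm <- make_bm(x, y)
    for (variant in c("welch", "student")) {
      mine <- probe_t_test(bm, "cg00001", variant)
      ref <- t.test(as.numeric(x), as.numeric(y),
                    var.equal = (variant == "student"))
      expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$p_nominal, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    }
  }
})

test_that("t-test degenerate and guard cases follow the stated conventions", {
  # element-wise equal groups: t = 0, P = 1
  bm <- make_bm(matrix(c(0.2, 0.3, 0.4), 1), matrix(c(0.2, 0.3, 0.4), 1))
  tt <- probe_t_test(bm, "cg00001")
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$p_nominal, 1)

  # zero variance in both groups, equal means: P = 1 by convention
  bm0 <- make_bm(matrix(c(0.3, 0.3), 1), matrix(c(0.3, 0.3), 1))
  expect_equal(probe_t_test(bm0, "cg00001")$p_nominal, 1)

  # clear separation: P below any practical alpha, still > 0
  set.seed(42)
  bms <- make_bm(matrix(abs(rnorm(5, 0, 1e-4)), 1),
                 matrix(1 - abs(rnorm(5, 0, 1e-4)), 1))
  p <- probe_t_test(bms, "cg00001")$p_nominal
  expect_lt(p, 1e-10)
  expect_gt(p, 0)

  # fewer than 2 values in a group: refuse, never a silent P = 1
  bmna <- make_bm(matrix(c(0.5, NA, NA), 1), matrix(c(0.1, 0.2, 0.3), 1))
  expect_error(probe_t_test(bmna, "cg00001"), "fewer than 2")
})

test_that("Bonferroni correction multiplies, caps at 1, and dominates the nominal P", {
  expect_equal(bonferroni(1e-5, 100), 1e-3)
  expect_equal(bonferroni(0.5, 10), 1)
  set.seed(51)
  p <- runif(200, 1e-12, 1)
  m <- sample(1:1e6, 1)
  pb <- bonferroni(p, m)
  expect_true(all(pb >= p))
  uncapped <- pb < 1
  expect_equal(pb[uncapped] / p[uncapped], rep(m, sum(uncapped)))
  expect_error(bonferroni(0.5, 0), "m_tests")
})

test_that("smoothed P equals a brute-force windowed mean, boundaries included", {
  # constant vector is a fixed point; radius 0 is the identity
  rows <- tibble::tibble(chromosome = "chr1", position = 1:20,
                         neglog10_p = rep(2.5, 20))
  expect_equal(smooth_p(rows, 3)$neglog10_p_smoothed, rep(2.5, 20))
  rows$neglog10_p <- runif(20)
  expect_equal(smooth_p(rows, 0)$neglog10_p_smoothed, rows$neglog10_p)

  # a single interior spike of height h averages to h/7 at radius 3
  spike <- tibble::tibble(chromosome = "chr1", position = 1:15,
                          neglog10_p = c(rep(0, 7), 21, rep(0, 7)))
  sm <- smooth_p(spike, 3)$neglog10_p_smoothed
  expect_equal(sm[8], 21 / 7)
  expect_equal(sm[1], 0)

  # oracle equivalence across radii and chromosome boundaries
  set.seed(61)
  rows <- tibble::tibble(
    chromosome = rep(c("chr1", "chr2", "chr3"), c(17, 4, 29)),
    position = c(sort(sample(1e5, 17)), sort(sample(1e5, 4)),
                 sort(sample(1e5, 29))),
    neglog10_p = rexp(50))
  for (r in 0:5) {
    expect_equal(smooth_p(rows, r)$neglog10_p_smoothed,
                 brute_smooth(rows$neglog10_p, rows$chromosome, r),
                 info = sprintf("radius %d", r))
  }
  expect_error(smooth_p(rows[c(2, 1, 3:50), ], 3), "sorted")
  expect_error(smooth_p(rows, -1), "radius")
})

test_that("PCA QC separates constructed clusters and conserves variance", {
  set.seed(71)
  n_probes <- 100; n_samp <- 24
  base <- matrix(runif(n_probes * n_samp, 0.4, 0.6), n_probes,
                 dimnames = list(sprintf("cg%03d", 1:n_probes),
                                 sprintf("s%02d", 1:n_samp)))
  grp2 <- 13:24
  base[1:30, grp2] <- base[1:30, grp2] + 0.3   # offset at 30% of probes
  meta <- data.frame(sample_id = colnames(base),
                     group = rep(c("case", "control"), each = 12))
  bm <- beta_matrix(base, meta)
  pca <- pca_qc(bm, k = 5)
  ev1 <- pca$scores[, "EV1"]
  expect_true(max(ev1[1:12]) < min(ev1[grp2]) ||
                max(ev1[grp2]) < min(ev1[1:12]))
  expect_true(all(diff(pca$eigenvalues) <= 1e-10))

  # rank-1 data: one component carries >= 99.9% of the variance
  r1 <- outer(runif(50), seq(0, 1, length.out = 10)) * 0.5 + 0.2
  dimnames(r1) <- list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:10))
  bm1 <- beta_matrix(r1, data.frame(sample_id = colnames(r1),
                                    group = rep(c("case", "control"), 5)))
  p1 <- pca_qc(bm1, k = 1)
  expect_gte(p1$prop_variance[1], 0.999)

  # total variance conserved at full rank
  pf <- pca_qc(bm, k = n_samp - 1)
  centered <- base - rowMeans(base)
  expect_equal(sum(pf$eigenvalues), sum(centered^2) / (n_samp - 1))

  # sample order permutation leaves scores unchanged up to sign
  perm <- sample(n_samp)
  bmp <- beta_matrix(base[, perm], meta[perm, ])
  pp <- pca_qc(bmp, k = 3)
  for (k in 1:3) {
    a <- pca$scores[, k]; b <- pp$scores[match(colnames(base),
                                               rownames(pp$scores)), k]
    expect_true(isTRUE(all.equal(a, b)) || isTRUE(all.equal(a, -b)))
  }
})

test_that("PCA can be restricted to one chromosome", {
  cfg <- sim_config(n_probes = 300, n_chromosomes = 2, seed = 23)
  sim <- simulate_methylome(cfg)
  pg <- pca_qc(sim$beta, k = 3, manifest = sim$manifest,
               chromosome = "chr1")
  expect_length(pg$eigenvalues, 3)
  expect_error(pca_qc(sim$beta, k = 3, manifest = sim$manifest,
                      chromosome = "chrX"), "no probes")
  expect_error(pca_qc(sim$beta, k = 3, chromosome = "chr1"), "manifest")
})

test_that("run_ewas keeps every probe, flags untested ones, and finds the island", {
  cfg <- sim_config(n_probes = 400, seed = 37)
  sim <- simulate_methylome(cfg)
  v <- sim$beta$values
  # make one open-sea probe untestable (a single case value left)
  poison <- which(sim$manifest$island_relation == "open_sea")[1]
  poison <- which(rownames(v) == sim$manifest$probe_id[poison])
  v[poison, sim$beta$sample_meta$group == "case"] <- NA
  v[poison, which(sim$beta$sample_meta$group == "case")[1]] <- 0.5
  bm <- beta_matrix(v, sim$beta$sample_meta)
  ew <- run_ewas(bm, sim$manifest, sim$islands)

  expect_equal(nrow(ew), 400)
  expect_equal(attr(ew, "m_tests"), 399)
  expect_equal(sum(ew$tested), 399)
  flagged <- ew[!ew$tested, ]
  expect_true(is.na(flagged$p_nominal))

  # every truth-epimutated probe clears Bonferroni significance
  truth_epi <- sim$truth_probes$probe_id[sim$truth_probes$epimutated]
  expect_true(all(ew$p_bonferroni[ew$probe_id %in% truth_epi] < 0.05))
  expect_true(all(ew$p_bonferroni >= ew$p_nominal, na.rm = TRUE))
  expect_equal(ew$neglog10_p, -log10(ew$p_nominal))

  mt <- manhattan_table(ew, highlight_threshold = 1e-10)
  expect_equal(nrow(mt), 400)
  expect_true(all(ew$probe_id[mt$highlight] %in%
                    ew$probe_id[ew$p_nominal < 1e-10]))
})

test_that("open-sea nominal P-values are uniform under the null", {
  # KS at alpha = 0.01 over five independent null simulations: a single
  # fixed draw can land in the 1% tail by chance, so require rejection in
  # at most 2 of 5 replicates (probability ~1e-5 under uniformity; a
  # genuinely miscalibrated engine rejects in all five)
  rejected <- vapply(43:47, function(s) {
    cfg <- sim_config(n_probes = 2000, epimutated_island_ids = character(0),
                      seed = s)
    sim <- simulate_methylome(cfg)
    ew <- run_ewas(sim$beta, sim$manifest, sim$islands)
    p_open <- ew$p_nominal[ew$island_relation == "open_sea"]
    suppressWarnings(ks.test(p_open, "punif"))$p.value < 0.01
  }, logical(1))
  expect_lte(sum(rejected), 2)
})
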