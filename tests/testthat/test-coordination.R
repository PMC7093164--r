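test_that("pearson_r matches hand cases and the brute-force formula", {
  expect_equal(pearson_r(1:4, 1:4), 1)
  expect_equal(pearson_r(1:4, c(4, 3, 2, 1)), -1)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)

  expect_true(is.na(pearson_r(rep(2, 5), 1:5)))
  expect_error(pearson_r(1:4, 1:5), "unequal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r equals the brute-force oracle on 1,000 random pairs", {
  set.seed(101)
  max_diff <- 0
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5 * x
    max_diff <- max(max_diff, abs(pearson_r(x, y) - oracle_pearson(x, y)))
  }
  expect_lt(max_diff, 1e-12)
})

test_that("high-expression filter is inclusive at the boundary", {
  vals <- rbind(G1 = rep(100, 4), G2 = rep(70, 4), G3 = rep(69.9, 4))
  colnames(vals) <- sprintf("S%d", 1:4)
  design <- sample_design(
    c(S1 = "NOR", S2 = "NOR", S3 = "NOR", S4 = "NOR",
      S5 = "FRA", S6 = "FRA", S7 = "FRA"), "NOR")
  mat <- cbind(vals, matrix(1, 3, 3,
                            dimnames = list(NULL, c("S5", "S6", "S7"))))
  cfg <- coord_config(min_reads = 70)
  expect_identical(filter_high_expression(mat, design, cfg), c("G1", "G2"))
  expect_identical(
    filter_high_expression(mat, design, coord_config(min_reads = 0)),
    c("G1", "G2", "G3"))
  expect_warning(
    filter_high_expression(mat, design, coord_config(min_reads = 1e6)),
    "no gene")
})

test_that("filter at the empirical 90th percentile keeps exactly 50/500", {
  set.seed(42)
  n_ref <- 8
  vals <- matrix(rgamma(500 * 16, shape = 2, scale = 40), nrow = 500,
                 dimnames = list(sprintf("G%03d", 1:500),
                                 sprintf("S%02d", 1:16)))
  design <- sample_design(
    stats::setNames(rep(c("NOR", "FRA"), each = 8), colnames(vals)), "NOR")
  # independent oracle: recompute reference means directly
  ref_means <- rowMeans(vals[, 1:n_ref])
  thr <- quantile(ref_means, 0.9)
  expect_identical(sum(ref_means >= thr), 50L)
  keep <- filter_high_expression(vals, design,
                                 coord_config(min_reads = thr))
  expect_length(keep, 50)
  expect_setequal(keep, names(ref_means)[ref_means >= thr])
})

test_that("pairwise_correlation is symmetric with unit diagonal", {
  set.seed(7)
  mat <- matrix(rpois(20 * 12, 50), nrow = 20,
                dimnames = list(sprintf("G%02d", 1:20),
                                sprintf("S%02d", 1:12)))
  mat["G02", ] <- mat["G01", ]   # identical rows
  mat["G03", 1:6] <- 5           # constant in reference group
  mat["G03", 7:12] <- 9
  design <- sample_design(
    stats::setNames(rep(c("NOR", "FRA"), each = 6), colnames(mat)), "NOR")
  cm <- pairwise_correlation(mat, rownames(mat), design, "reference")
  expect_identical(cm$values, t(cm$values))
  expect_equal(cm$values["G01", "G02"], 1)
  expect_identical(cm$undefined_genes, "G03")
  expect_true(all(is.na(cm$values["G03", ])))
  defined <- setdiff(rownames(mat), "G03")
  expect_equal(unname(diag(cm$values)[defined]), rep(1, 19))
  expect_true(all(abs(cm$values[defined, defined]) <= 1))
  # scalar route and matrix route agree
  expect_equal(cm$values["G01", "G05"],
               pearson_r(mat["G01", 1:6], mat["G05", 1:6]),
               tolerance = 1e-12)
  expect_error(pairwise_correlation(mat, "NOPE", design, "reference"),
               "NOPE")
})

test_that("copula block correlation matches a Monte-Carlo oracle", {
  cfg <- sim_config(n_genes = 10, n_samples_ref = 50, n_samples_cond = 3,
                    n_modules = 1, module_size = 10, latent_rho = 0.8,
                    coherence_amplification = 1, n_seed_genes = 10,
                    n_rewired = 0, rng_seed = 7)
  sim <- simulate_dataset(cfg)
  design <- simulated_design(sim)
  cm <- pairwise_correlation(simulated_counts(sim), rownames(sim$ref),
                             design, "reference")
  observed <- mean(cm$values[upper.tri(cm$values)])

  # oracle: per-pair Monte-Carlo of the copula-implied count correlation
  set.seed(999)
  mu <- sim$mu
  nmc <- 20000
  f <- rnorm(nmc)
  implied <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    zi <- sqrt(0.8) * f + sqrt(0.2) * rnorm(nmc)
    zj <- sqrt(0.8) * f + sqrt(0.2) * rnorm(nmc)
    ci <- qnbinom(pnorm(zi), size = sim$nb_size, mu = mu[i])
    cj <- qnbinom(pnorm(zj), size = sim$nb_size, mu = mu[j])
    implied <- c(implied, cor(ci, cj))
  }
  expect_lt(abs(observed - mean(implied)), 0.1)
})

test_that("coherence_summary summarises off-diagonal defined entries", {
  cm <- structure(list(
    gene_ids = c("A", "B"),
    values = matrix(c(1, 0.6, 0.6, 1), 2,
                    dimnames = list(c("A", "B"), c("A", "B"))),
    group = "NOR", undefined_genes = character()),
    class = "correlation_matrix")
  s <- coherence_summary(cm)
  expect_equal(s$mean_r, 0.6)

  v <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  v[1, 2] <- v[2, 1] <- 0.2
  v[1, 3] <- v[3, 1] <- -0.2
  v[2, 3] <- v[3, 2] <- NA
  cm$values <- v
  s <- coherence_summary(cm)
  expect_equal(s$mean_r, 0)
  expect_equal(s$mean_abs_r, 0.2)
  expect_identical(s$n_pairs, 2L)

  cm$values[upper.tri(v) | lower.tri(v)] <- NA
  expect_error(coherence_summary(cm), "undefined")
})

test_that("coherence amplification raises condition-group mean |R|", {
  # needs >= ~10 modules: between-module factor noise otherwise swamps
  # the amplification signal at desk scale
  diffs <- vapply(0:9, function(s) {
    sim <- simulate_dataset(sim_config(
      n_genes = 1000, n_samples_ref = 50, n_samples_cond = 50,
      n_modules = 10, module_size = 50, n_seed_genes = 100,
      n_rewired = 0, rng_seed = s))
    design <- simulated_design(sim)
    mat <- simulated_counts(sim)
    seeds <- sim$truth$seed_genes
    ref <- coherence_summary(
      pairwise_correlation(mat, seeds, design, "reference"))
    cond <- coherence_summary(
      pairwise_correlation(mat, seeds, design, "condition"))
    cond$mean_abs_r - ref$mean_abs_r
  }, numeric(1L))
  # directional claim at the distribution level; the per-replicate count
  # is asserted at full scale in test-acceptance.R
  expect_gt(mean(diffs), 0)
})

test_that("transcriptome_profiles excludes self and shares the background", {
  set.seed(3)
  mat <- matrix(rpois(5 * 8, 30), nrow = 5,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:8)))
  design <- sample_design(
    stats::setNames(rep(c("NOR", "FRA"), each = 4), colnames(mat)), "NOR")
  pr <- transcriptome_profiles(mat, "G1", design)
  expect_identical(pr$reference$G1$background_gene_ids,
                   c("G2", "G3", "G4", "G5"))
  expect_identical(pr$reference$G1$background_gene_ids,
                   pr$condition$G1$background_gene_ids)

  # constant in the condition group only -> dropped from both backgrounds
  mat["G4", 5:8] <- 7
  expect_message(pr <- transcriptome_profiles(mat, "G1", design),
                 "zero variance")
  expect_identical(pr$reference$G1$background_gene_ids, c("G2", "G3", "G5"))
  expect_identical(pr$condition$G1$background_gene_ids, c("G2", "G3", "G5"))

  expect_warning(pr <- transcriptome_profiles(mat, c("G1", "G1"), design),
                 "duplicated")
  expect_length(pr$reference, 1)
})

test_that("composite_correlation handles identity, negation and errors", {
  bg <- paste0("B", 1:6)
  r <- c(0.9, -0.3, 0.1, 0.5, -0.7, 0.2)
  p_ref <- make_profile("S", "NOR", bg, r)
  p_same <- make_profile("S", "FRA", bg, r)
  p_neg <- make_profile("S", "FRA", bg, -r)

  expect_equal(composite_correlation(p_ref, p_same)$pc, 1, tolerance = 1e-12)
  expect_equal(composite_correlation(p_ref, p_neg)$pc, -1, tolerance = 1e-12)

  p_other <- make_profile("T", "FRA", bg, r)
  expect_error(composite_correlation(p_ref, p_other), "mismatched seed")

  # undefined: < 3 common positions
  p_na <- make_profile("S", "FRA", bg, c(0.1, 0.2, NA, NA, NA, NA))
  rec <- composite_correlation(p_ref, p_na)
  expect_true(is.na(rec$pc))
  expect_identical(rec$n_common_background, 2L)

  # symmetry property on random profiles
  set.seed(11)
  for (i in 1:20) {
    a <- make_profile("S", "NOR", bg, runif(6, -1, 1))
    b <- make_profile("S", "FRA", bg, runif(6, -1, 1))
    expect_equal(composite_correlation(a, b)$pc,
                 composite_correlation(b, a)$pc, tolerance = 1e-12)
  }
})

test_that("identical condition group gives Pc = 1 for every seed", {
  set.seed(5)
  half <- matrix(rpois(40 * 5, 80) + rnorm(200, 0, 0.1)^2, nrow = 40,
                 dimnames = list(sprintf("G%02d", 1:40),
                                 sprintf("N%d", 1:5)))
  mat <- cbind(half, half)
  colnames(mat) <- c(sprintf("N%d", 1:5), sprintf("F%d", 1:5))
  design <- sample_design(
    stats::setNames(rep(c("NOR", "FRA"), each = 5), colnames(mat)), "NOR")
  pr <- transcriptome_profiles(mat, rownames(mat)[1:10], design)
  for (s in names(pr$reference)) {
    rec <- composite_correlation(pr$reference[[s]], pr$condition[[s]])
    expect_equal(rec$pc, 1, tolerance = 1e-12)
  }
})

test_that("sample-order permutation within a group changes nothing", {
  sim <- simulate_dataset(small_sim_config(rng_seed = 4))
  design <- simulated_design(sim)
  mat <- simulated_counts(sim)
  seeds <- sim$truth$seed_genes[1:5]

  set.seed(99)
  perm <- c(sample(colnames(sim$ref)), sample(colnames(sim$cond)))
  mat_p <- mat[, perm]

  pr <- transcriptome_profiles(mat, seeds, design)
  pr_p <- transcriptome_profiles(mat_p, seeds, design)
  for (s in seeds) {
    expect_equal(pr$reference[[s]]$r_values, pr_p$reference[[s]]$r_values,
                 tolerance = 1e-12)
    rec <- composite_correlation(pr$reference[[s]], pr$condition[[s]])
    rec_p <- composite_correlation(pr_p$reference[[s]], pr_p$condition[[s]])
    expect_equal(rec$pc, rec_p$pc, tolerance = 1e-12)
    set1 <- extract_correlated_set(pr$condition[[s]])
    set2 <- extract_correlated_set(pr_p$condition[[s]])
    expect_identical(set1$genes, set2$genes)
  }
})

test_that("rank_by_pc sorts ascending with lexicographic ties, NA last", {
  mk <- function(g, pc) structure(
    list(seed_gene = g, pc = pc, n_common_background = 9L),
    class = "pc_record")
  recs <- list(mk("GB", 0.3), mk("GA", -0.1), mk("GC", 0.5),
               mk("GE", 0.2), mk("GD", 0.2), mk("GF", NA_real_))
  ranking <- rank_by_pc(recs, coord_config(bottom_k = 1, top_k = 2))
  expect_identical(ranking$records$seed_gene,
                   c("GA", "GD", "GE", "GB", "GC", "GF"))
  expect_identical(ranking$bottom, "GA")
  expect_identical(ranking$top, c("GC", "GB"))
  expect_false("GF" %in% c(ranking$bottom, ranking$top))

  expect_error(rank_by_pc(list(mk("GA", NA_real_))), "undefined")
})

test_that("rewired seeds sink to the bottom of the Pc ranking", {
  cfg <- sim_config(n_genes = 1000, n_samples_ref = 50, n_samples_cond = 50,
                    n_modules = 5, module_size = 50, n_seed_genes = 100,
                    n_rewired = 10, rng_seed = 11)
  sim <- simulate_dataset(cfg)
  design <- simulated_design(sim)
  pr <- transcriptome_profiles(simulated_counts(sim),
                               sim$truth$seed_genes, design)
  recs <- lapply(sim$truth$seed_genes, function(s) {
    composite_correlation(pr$reference[[s]], pr$condition[[s]])
  })
  ranking <- rank_by_pc(recs)
  bottom20 <- head(ranking$records$seed_gene, 20)
  expect_true(all(sim$truth$rewired %in% bottom20))
})

test_that("extract_correlated_set applies a strict R > cutoff", {
  prof <- make_profile("S", "NOR", paste0("B", 1:4),
                       c(0.6, 0.5, 0.51, -0.9))
  gs <- extract_correlated_set(prof, coord_config(r_cutoff = 0.5))
  expect_identical(gs$genes, c("B1", "B3"))
  expect_equal(gs$r, c(0.6, 0.51))

  # cutoff above every value -> empty set allowed
  gs0 <- extract_correlated_set(prof, coord_config(r_cutoff = 0.99))
  expect_length(gs0$genes, 0)
})

test_that("unrewired seeds keep more of their correlated set than rewired", {
  overlap <- function(sim, seed) {
    design <- simulated_design(sim)
    pr <- transcriptome_profiles(simulated_counts(sim), seed, design)
    jaccard(extract_correlated_set(pr$reference[[seed]])$genes,
            extract_correlated_set(pr$condition[[seed]])$genes)
  }
  j_unrew <- c()
  j_rew <- c()
  for (s in 1:10) {
    sim <- simulate_dataset(small_sim_config(rng_seed = s, n_rewired = 3))
    rew <- sim$truth$rewired[1]
    unrew <- setdiff(sim$truth$seed_genes, sim$truth$rewired)[1]
    j_rew <- c(j_rew, overlap(sim, rew))
    j_unrew <- c(j_unrew, overlap(sim, unrew))
  }
  expect_gt(mean(j_unrew), mean(j_rew))
})
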