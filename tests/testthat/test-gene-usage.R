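test_that("usage profiles normalise counts over the requested segment", {
  rec <- toy_repertoire(c("ARDYW", "GKSYF"))$records
  rec$v_call <- c("IGHV3-23*01", "IGHV1-2*02")
  rep0 <- repertoire(rec, "s1")
  prof <- usage_profile(rep0, "V", "subgroup")
  expect_equal(prof$frequencies, c(IGHV1 = 0.5, IGHV3 = 0.5))
  expect_equal(sum(prof$frequencies), 1)

  # single-gene repertoire
  prof1 <- usage_profile(toy_repertoire("ARDYW"), "V", "gene")
  expect_equal(unname(prof1$frequencies), 1)
  expect_equal(names(prof1$frequencies), "IGHV3-23")

  # reference labels extend the axis at zero
  prof2 <- usage_profile(rep0, "V", "subgroup",
                         reference_labels = c("IGHV4", "IGHV6"))
  expect_equal(prof2$frequencies[["IGHV4"]], 0)
  expect_equal(sum(prof2$frequencies), 1)

  # no light-chain V calls -> empty-result error
  expect_error(usage_profile(rep0, "V", "gene", loci = c("IGK", "IGL")),
               class = "bcrcompare_empty_result_error")
})

test_that("kappa/lambda ratio is a percentage over light-chain records", {
  rec <- toy_repertoire(c("QQSYSTF", "QQSYSTF", "QQSYSTF", "QSWDSSF"))$records
  rec$locus <- c("IGK", "IGK", "IGK", "IGL")
  rec$v_call <- c(rep("IGKV1-39*01", 3), "IGLV2-14*01")
  rec$d_call <- NA_character_
  rec$j_call <- c(rep("IGKJ2*01", 3), "IGLJ3*01")
  rep0 <- repertoire(rec, "s1")
  expect_equal(kappa_lambda_ratio(rep0), c(kappa = 75, lambda = 25))

  rec$locus <- rep("IGK", 4)
  expect_equal(kappa_lambda_ratio(repertoire(rec, "s1")),
               c(kappa = 100, lambda = 0))

  expect_error(kappa_lambda_ratio(toy_repertoire("ARDYW")),
               class = "bcrcompare_empty_result_error")
})

test_that("z-normalisation gives column mean 0 and sample-sd scaling", {
  p <- function(subject, f) {
    structure(list(subject_id = subject, frequencies = f, n_sequences = 10,
                   segment = "V", level = "gene"), class = "usage_profile")
  }
  z <- z_normalise(list(p("a", c(g1 = 0.4, g2 = 0.6)),
                        p("b", c(g1 = 0.6, g2 = 0.4))))
  expect_equal(z[, "g1"], c(a = -1, b = 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)

  # identical profiles: zero-variance columns become all-zero, and are logged
  z0 <- z_normalise(list(p("a", c(g1 = 0.5, g2 = 0.5)),
                         p("b", c(g1 = 0.5, g2 = 0.5))))
  expect_true(all(z0 == 0))
  expect_setequal(attr(z0, "zero_variance"), c("g1", "g2"))

  expect_error(z_normalise(list(p("a", c(g1 = 1)))), regexp = "2 profiles")
})

test_that("hierarchical clustering recovers separated profile groups", {
  set.seed(42)
  blob <- rbind(
    matrix(rnorm(40, mean = 0, sd = 0.05), nrow = 4),
    matrix(rnorm(40, mean = 1, sd = 0.05), nrow = 4)
  )
  rownames(blob) <- paste0("s", 1:8)
  cl <- cluster_profiles(blob)
  expect_equal(adjusted_rand(cl$cut2, rep(1:2, each = 4)), 1)

  # two rows: each its own cluster
  expect_equal(sort(unname(cluster_profiles(blob[1:2, ])$cut2)), c(1, 2))

  # duplicated rows merge first at height zero
  dup <- blob[c(1, 1, 5), ]
  tree <- cluster_profiles(dup)$tree
  expect_equal(tree$height[1], 0)
  expect_setequal(-tree$merge[1, ], c(1, 2))

  bad <- blob
  bad[1, 1] <- NaN
  expect_error(cluster_profiles(bad), regexp = "non-finite")
})

test_that("adjusted Rand index matches its contingency-table definition", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # invariant to relabelling
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  # one-block vs an even split on 4 items is exactly chance level
  expect_equal(adjusted_rand(rep(1, 4), c(1, 1, 2, 2)), 0)
  # symmetric, bounded above by 1, agrees with an independent implementation
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
    expect_lte(adjusted_rand(a, b), 1)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand(1:3, 1:4), regexp = "length")
})

test_that("species with disjoint germline genes separate perfectly under subsampling", {
  hu <- sim_study("human")
  mo <- sim_study("mouse", seed = 12)
  reps <- c(hu, mo)
  labels <- rep(c("human", "mouse"), each = 4)
  sep <- separability_test(reps, labels, subsample_n = 105, n_repeats = 25,
                           seed = 3, segment = "V", level = "gene")
  expect_equal(sep$fraction_perfect, 1)
  expect_length(sep$ari, 25)

  # deterministic given the seed
  sep2 <- separability_test(reps, labels, subsample_n = 105, n_repeats = 5,
                            seed = 99)
  sep3 <- separability_test(reps, labels, subsample_n = 105, n_repeats = 5,
                            seed = 99)
  expect_identical(sep2$ari, sep3$ari)

  # infeasible subsample depth names the offending subject
  expect_error(
    separability_test(reps, labels, subsample_n = 10^6, n_repeats = 2),
    regexp = hu[[1]]$subject_id
  )
})

test_that("separability grows with the usage gap between simulated groups", {
  # interpolate kymouse D usage towards human's: larger gap, better separation
  base <- species_preset("human")
  ky <- species_preset("kymouse")
  frac_perfect <- vapply(c(0.15, 0.5, 1), function(w) {
    p <- base
    p$heavy$d_usage <- (1 - w) * base$heavy$d_usage + w * ky$heavy$d_usage
    reps_a <- simulate_repertoire(
      simulation_config(base, 3, 700, seed = 21, chains = "heavy"))
    reps_b <- simulate_repertoire(
      simulation_config(p, 3, 700, seed = 22, chains = "heavy"))
    separability_test(c(reps_a, reps_b), rep(c("a", "b"), each = 3),
                      subsample_n = 105, n_repeats = 20, seed = 5,
                      segment = "D", level = "subgroup")$fraction_perfect
  }, numeric(1))
  expect_true(all(diff(frac_perfect) >= 0))
  expect_gt(frac_perfect[3], frac_perfect[1])
})

test_that("per-gene rank-sum tests flag disjoint categories and spare identical ones", {
  p <- function(subject, f) {
    structure(list(subject_id = subject, frequencies = f, n_sequences = 50,
                   segment = "D", level = "subgroup"),
              class = "usage_profile")
  }
  # identical groups: nothing significant
  same <- lapply(1:3, function(i) p(paste0("a", i),
                                    c(IGHD1 = 0.3, IGHD2 = 0.7)))
  res_same <- usage_difference_tests(same, same)
  expect_true(all(res_same$p_adjusted >= 0.99))

  # one category with disjoint support across 5 vs 5 subjects reaches the
  # smallest achievable two-sided rank-sum p-value, 2 / choose(10, 5)
  ga <- lapply(1:5, function(i) p(paste0("a", i),
                                  c(IGHD1 = 0.30 + i / 100,
                                    IGHD2 = 0.70 - i / 100)))
  gb <- lapply(1:5, function(i) p(paste0("b", i),
                                  c(IGHD1 = 0.10 + i / 100,
                                    IGHD2 = 0.90 - i / 100)))
  res <- usage_difference_tests(ga, gb)
  expect_equal(res$p[res$category == "IGHD1"], 2 / choose(10, 5),
               tolerance = 1e-12)

  expect_error(usage_difference_tests(ga[1], gb), regexp = ">= 2 subjects")
})

test_that("simulated human vs kymouse repertoires differ in IGHD2 usage", {
  hu <- sim_study("human", 5, 800, seed = 31)
  ky <- sim_study("kymouse", 5, 800, seed = 32)
  pa <- lapply(hu, usage_profile, segment = "D", level = "subgroup")
  pb <- lapply(ky, usage_profile, segment = "D", level = "subgroup")
  res <- usage_difference_tests(pa, pb)
  row <- res[res$category == "IGHD2", ]
  expect_lt(row$p_adjusted, 0.05)
  expect_gt(row$mean_a, row$mean_b) # humans use IGHD2 more
})

test_that("subsampled richness approaches the coupon-collector expectation", {
  # uniform 10-gene repertoire
  genes <- sprintf("IGHV3-%d*01", 1:10)
  rec <- toy_repertoire(rep("ARDYW", 2000))$records
  rec$v_call <- rep(genes, each = 200)
  rep0 <- repertoire(rec, "u")
  r <- richness_at_depth(rep0, depth = 105, n_repeats = 40, seed = 8)
  expect_lt(abs(r - 10 * (1 - (9 / 10)^105)), 0.05)

  # depth = repertoire size: exact distinct count, zero variance
  expect_equal(richness_at_depth(rep0, depth = 2000, n_repeats = 3), 10)
  # single-gene repertoire
  single <- toy_repertoire(rep("ARDYW", 50))
  expect_equal(richness_at_depth(single, depth = 20), 1)
  expect_error(richness_at_depth(single, depth = 51), regexp = "exceeds")

  # V x J combinatorial richness is bounded by the product of the margins
  sim <- sim_study("human")[[1]]
  vj <- richness_at_depth(sim, 105, segment = "VJ", n_repeats = 10)
  v <- richness_at_depth(sim, 105, segment = "V", n_repeats = 10)
  j <- richness_at_depth(sim, 105, segment = "J", n_repeats = 10)
  expect_lte(vj, v * j)
  expect_gte(vj, max(v, j))
})
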