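test_that("category usage profiles are proportions and feed the usage machinery", {
  tab <- tibble::tibble(
    subject_id = "s1", species = "human", cdr3_aa_length = 10,
    category_id = c("X", "X", "Y"), category_origin = "human"
  )
  prof <- category_usage_profile(tab, "s1")
  expect_equal(prof$frequencies, c(X = 2 / 3, Y = 1 / 3))
  expect_error(category_usage_profile(tab, "nobody"), regexp = "unknown")

  single <- category_usage_profile(
    dplyr::mutate(tab, category_id = "X"), "s1")
  expect_equal(unname(single$frequencies), 1)

  # the shared usage_profile type flows through z_normalise unchanged
  tab2 <- dplyr::mutate(tab, subject_id = "s2",
                        category_id = c("X", "Y", "Y"))
  z <- z_normalise(list(prof, category_usage_profile(tab2, "s2")))
  expect_equal(unname(colMeans(z)), c(0, 0))
})

test_that("usage-distance analysis separates murine from human-like subjects", {
  ann <- sim_annotations()
  subjects <- unique(ann$subject_id)
  labels <- setNames(
    ifelse(ann$species[match(subjects, ann$subject_id)] == "mouse",
           "murine", "human_like"),
    subjects
  )
  uda <- usage_distance_analysis(ann, labels)
  expect_equal(uda$ari, 1)
  expect_equal(uda$dist, t(uda$dist))
  expect_equal(unname(diag(uda$dist)), rep(0, length(subjects)))
  expect_setequal(unique(uda$comparisons$type),
                  c("within_human_like", "within_murine",
                    "between_human_like_murine"))

  # two identical subjects merge first
  tab <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", species = "human",
                   cdr3_aa_length = 10,
                   category_id = c("X", "X", "Y"), category_origin = "human"),
    tibble::tibble(subject_id = "b", species = "human",
                   cdr3_aa_length = 10,
                   category_id = c("X", "X", "Y"), category_origin = "human"),
    tibble::tibble(subject_id = "c", species = "mouse",
                   cdr3_aa_length = 10,
                   category_id = c("Y", "Y", "Z"), category_origin = "mouse")
  )
  uda2 <- usage_distance_analysis(tab)
  first_pair <- sort(uda2$tree$labels[-uda2$tree$merge[1, ]])
  expect_equal(first_pair, c("a", "b"))
  expect_equal(uda2$tree$height[1], 0)
})

test_that("species-origin composition reflects the group's template bias", {
  tab <- tibble::tibble(
    subject_id = "s1", species = "human", cdr3_aa_length = 10,
    category_id = c("H1", "H2", "H2"), category_origin = "human"
  )
  expect_equal(species_origin_bias(tab), c(human = 1))

  tab2 <- tibble::tibble(
    subject_id = "s1", species = "human", cdr3_aa_length = 10,
    category_id = c("H1", "H1", "H1", "M1"),
    category_origin = c("human", "human", "human", "mouse")
  )
  # distinct-cluster counting: one human + one mouse cluster
  expect_equal(species_origin_bias(tab2),
               c(human = 0.5, mouse = 0.5))
  # sequence-weighted counting sees the abundances
  expect_equal(species_origin_bias(tab2, weighted = TRUE),
               c(human = 0.75, mouse = 0.25))

  ann <- sim_annotations()
  by_species <- function(sp) {
    species_origin_bias(ann, unique(ann$subject_id[ann$species == sp]))
  }
  mouse_bias <- by_species("mouse")
  expect_gt(mouse_bias[["mouse"]], max(mouse_bias[["human"]],
                                       mouse_bias[["other"]]))
  human_bias <- by_species("human")
  expect_gt(human_bias[["human"]], max(human_bias[["mouse"]],
                                       human_bias[["other"]]))
})

test_that("enrichment ratios are calibrated against the background", {
  bg <- synthetic_background()
  # all-human observations at a length where the background is 50% human
  bg50 <- tibble::tibble(
    category_id = c("A", "B"), origin = c("human", "mouse"),
    cdr3_aa_length = 10, frequency = c(0.5, 0.5)
  )
  obs <- tibble::tibble(
    subject_id = "s", species = "human", cdr3_aa_length = 10,
    category_id = "A", category_origin = "human"
  )[rep(1, 100), ]
  en <- enrichment_by_length(obs, bg50, "human")
  expect_equal(en$ratio, 2)
  expect_equal(en$p, 2 * 0.5^100, tolerance = 1e-12)
  expect_true(en$significant)

  # a length stratum absent from the observations is absent from the output
  expect_false(5 %in% en$cdr3_aa_length)
  # background must cover every observed length
  expect_error(
    enrichment_by_length(dplyr::mutate(obs, cdr3_aa_length = 11), bg50,
                         "human"),
    regexp = "cover")

  # ratio = Inf flag when the background proportion is zero
  bg0 <- dplyr::mutate(bg50, frequency = c(0, 1))
  expect_equal(enrichment_by_length(obs, bg0, "human")$ratio, Inf)
})

test_that("null-sampled tables keep the nominal 1% false-positive level", {
  bg <- synthetic_background()
  hits <- 0L
  tests <- 0L
  for (s in 1:50) {
    null_tab <- simulate_annotation_table(c(human = 1), 400,
                                          background = bg, bias = 1,
                                          seed = 5000 + s)
    en <- enrichment_by_length(null_tab, bg, "human")
    hits <- hits + sum(en$significant)
    tests <- tests + sum(!is.na(en$p))
  }
  expect_lte(hits / tests, 0.02)
})

test_that("greedy leader clustering follows the hand-traced behaviour", {
  d <- as.matrix(dist(c(0, 0.5, 1, 1.5)))
  got <- greedy_cluster(d, 0.6)
  expect_equal(as.integer(got), c(1, 1, 2, 2))
  expect_equal(attr(got, "representatives"), c(1L, 3L))

  # cutoff beyond the diameter: a single cluster
  expect_equal(unique(as.integer(greedy_cluster(d, 10))), 1L)
  # cutoff below the minimum spacing: all singletons
  expect_equal(as.integer(greedy_cluster(d, 0.1)), 1:4)

  asym <- d
  asym[1, 2] <- asym[1, 2] + 1e-6
  expect_error(greedy_cluster(asym, 0.6), regexp = "asymmetric")
  expect_error(greedy_cluster(d - 0.1, 0.6), regexp = "non-negative")

  # deterministic given input order
  expect_identical(as.integer(greedy_cluster(d, 0.6)),
                   as.integer(greedy_cluster(d, 0.6)))
})

test_that("length-balanced subsampling is feasible, equal and reproducible", {
  ann <- sim_annotations()
  # restrict to a well-populated window so balancing is feasible
  lengths <- 9:14
  sub1 <- length_balanced_subsample(ann, 5, n_subsamples = 3, seed = 7,
                                    lengths = lengths)
  sub2 <- length_balanced_subsample(ann, 5, n_subsamples = 3, seed = 7,
                                    lengths = lengths)
  expect_identical(sub1, sub2)
  counts <- dplyr::count(sub1[[1]], subject_id, cdr3_aa_length)
  expect_true(all(counts$n == 5))
  expect_setequal(unique(counts$cdr3_aa_length), lengths)

  expect_error(
    length_balanced_subsample(ann, 10^5, n_subsamples = 1,
                              lengths = lengths),
    regexp = "infeasible")

  # balanced subsamples of a deeper table keep the murine/human-like
  # separation at every repeat
  deep <- sim_annotations_deep()
  subjects <- unique(deep$subject_id)
  labels <- setNames(
    ifelse(deep$species[match(subjects, deep$subject_id)] == "mouse",
           "murine", "human_like"),
    subjects
  )
  aris <- vapply(
    length_balanced_subsample(deep, 40, n_subsamples = 20, seed = 17,
                              lengths = 9:14),
    function(tab) usage_distance_analysis(tab, labels)$ari,
    numeric(1)
  )
  expect_true(all(aris == 1))
})
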