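test_that("the 90% identity rule is inclusive and keyed on V, J and length", {
  # two length-10 CDR3s differing at one position: identity exactly 0.90
  r <- toy_repertoire(c("AAAAAAAAAA", "AAAAAAAAAB"))
  ca <- assign_clonotypes(r)
  expect_equal(length(unique(ca$assignment$clone_id)), 1)

  # same CDR3, different IGHJ: different clones
  rec <- toy_repertoire(c("AAAAAAAAAA", "AAAAAAAAAA"))$records
  rec$j_call <- c("IGHJ4*01", "IGHJ6*01")
  ca2 <- assign_clonotypes(repertoire(rec, "x"))
  expect_equal(length(unique(ca2$assignment$clone_id)), 2)

  # different length CDR3s never cluster
  r3 <- toy_repertoire(c("AAAAAAAAAA", "AAAAAAAAA"))
  expect_equal(nrow(assign_clonotypes(r3)$clones), 2)
})

test_that("single linkage closes identity chains; complete linkage does not", {
  # A-B and B-C at 0.9 identity, A-C at 0.8
  r <- toy_repertoire(c("AAAAAAAAAA", "AAAAAAAAAB", "AAAAAAAABB"))
  single <- assign_clonotypes(r)
  expect_equal(length(unique(single$assignment$clone_id)), 1)
  complete <- assign_clonotypes(r, linkage = "complete")
  expect_equal(length(unique(complete$assignment$clone_id)), 2)
})

test_that("clonotyping equals brute-force transitive closure on simulated fixtures", {
  sim <- sim_study("kymouse", seed = 13)[[1]]
  h <- heavy_records(sim)[1:180, ]
  fix <- repertoire(h, "fix")
  for (threshold in c(0.8, 0.9)) {
    mine <- assign_clonotypes(fix, threshold)$assignment$clone_id
    oracle <- oracle_clonotypes(h, threshold)
    expect_equal(adjusted_rand(mine, oracle), 1)
  }
})

test_that("threshold 1.0 clonotyping equals exact (V, J, CDR3) grouping", {
  sim <- sim_study("human")[[1]]
  h <- heavy_records(sim)[1:200, ]
  fix <- repertoire(h, "fix")
  mine <- assign_clonotypes(fix, 1.0)$assignment$clone_id
  exact <- paste(strip_gene <- sub("\\*.*$", "", h$v_call),
                 sub("\\*.*$", "", h$j_call), h$junction_aa)
  expect_equal(adjusted_rand(mine, as.integer(factor(exact))), 1)
})

test_that("clone count is monotone non-increasing as the threshold drops", {
  sim <- sim_study("kymouse", seed = 13)[[1]]
  fix <- repertoire(heavy_records(sim)[1:200, ], "fix")
  counts <- vapply(c(1.0, 0.95, 0.9, 0.8, 0.6), function(t) {
    nrow(assign_clonotypes(fix, t)$clones)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clone members share V, J and CDR3 length; every record maps once", {
  sim <- sim_study("human")[[1]]
  fix <- repertoire(heavy_records(sim)[1:300, ], "fix")
  ca <- assign_clonotypes(fix)
  expect_equal(nrow(ca$assignment), 300)
  expect_equal(anyDuplicated(ca$assignment$sequence_id), 0)
  joined <- merge(ca$assignment, fix$records, by = "sequence_id")
  per_clone <- split(joined, joined$clone_id)
  ok <- vapply(per_clone, function(cl) {
    length(unique(sub("\\*.*$", "", cl$v_call))) == 1 &&
      length(unique(sub("\\*.*$", "", cl$j_call))) == 1 &&
      length(unique(nchar(cl$junction_aa))) == 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("exact CDRH3 sets deduplicate junction interiors", {
  r <- toy_repertoire(c("ARDYW", "ARDYW", "GKSYF", "GKSYF", "YYYGW"))
  expect_setequal(exact_cdrh3_set(r), c("ARDYW", "GKSYF", "YYYGW"))
  # clonal redundancy means fewer distinct CDRH3s than reads
  sim <- sim_kymouse_20k()
  expect_lt(length(exact_cdrh3_set(sim)), nrow(sim$records))
})

test_that("pairwise overlap honours its denominator conventions", {
  rA <- toy_repertoire(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"),
                       subject = "A")
  rB <- toy_repertoire(c("CCCCCCCCCC", "DDDDDDDDDD", "EEEEEEEEEE"),
                       subject = "B")
  om_mean <- pairwise_overlap(list(rA, rB))
  expect_equal(om_mean["A", "B"], 100 * (2 / 3 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(om_mean, t(om_mean))
  expect_equal(diag(om_mean), c(A = 100, B = 100))
  expect_equal(pairwise_overlap(list(rA, rB), convention = "min")["A", "B"],
               100 * 2 / 3, tolerance = 1e-12)
  expect_equal(
    pairwise_overlap(list(rA, rB), convention = "jaccard")["A", "B"], 50)

  # identical repertoires: 100 under every convention and unit
  for (conv in c("mean", "min", "jaccard")) {
    expect_equal(
      pairwise_overlap(list(rA, repertoire(rA$records, "A2")),
                       convention = conv)["A", "A2"], 100)
  }
  # disjoint sets
  rC <- toy_repertoire(c("FFFFFFFFFF", "GGGGGGGGGG"), subject = "C")
  expect_equal(pairwise_overlap(list(rA, rC))["A", "C"], 0)
})

test_that("clonotype sharing counts near-identical cross-subject CDR3s", {
  # one mismatch between the two subjects' CDR3s: same clone when pooled
  rA <- toy_repertoire(c("AAAAAAAAAA", "CCCCCCCCCC"), subject = "A")
  rB <- toy_repertoire(c("AAAAAAAAAB", "GGGGGGGGGG"), subject = "B")
  om <- pairwise_overlap(list(rA, rB), unit = "clonotype")
  expect_equal(om["A", "B"], 100 * (1 / 2 + 1 / 2) / 2)
  # exact-match sharing misses it
  expect_equal(pairwise_overlap(list(rA, rB), unit = "cdrh3")["A", "B"], 0)

  # adding a shared item to both sets never decreases overlap
  add <- function(r, cdr3, id) {
    rec <- toy_repertoire(cdr3, subject = id)$records
    rec$sequence_id <- paste0(id, "_extra")
    repertoire(dplyr::bind_rows(r$records, rec), r$subject_id)
  }
  before <- pairwise_overlap(list(rA, rB), unit = "cdrh3")["A", "B"]
  after <- pairwise_overlap(list(add(rA, "WWWWWWWWWW", "A"),
                                 add(rB, "WWWWWWWWWW", "B")),
                            unit = "cdrh3")["A", "B"]
  expect_gte(after, before)
})

test_that("stratified downsampling preserves the clone-size spectrum", {
  # one large clone (60 identical reads) plus 40 singleton clones
  big <- toy_repertoire(rep("AAAAAAAAAA", 60), subject = "s")
  singles <- toy_repertoire(
    withr::with_seed(3, vapply(1:40, function(i) {
      paste(sample(c("C", "D", "E", "F", "G", "H", "K"), 14,
                   replace = TRUE), collapse = "")
    }, "")), subject = "s", v = "IGHV1-2*01")
  rec <- dplyr::bind_rows(big$records, singles$records)
  rec$sequence_id <- sprintf("s_%03d", seq_len(nrow(rec)))
  rep0 <- repertoire(rec, "s")

  ca <- assign_clonotypes(rep0)
  big_share_pre <- max(ca$clones$size) / nrow(rec)

  chisq_dist <- function(post_share, pre_share) {
    p <- c(post_share, 1 - post_share)
    q <- c(pre_share, 1 - pre_share)
    sum((p - q)^2 / q)
  }
  strat <- numeric(20)
  unif <- numeric(20)
  for (s in 1:20) {
    ds <- stratified_downsample(rep0, 30, seed = s, assignment = ca)
    in_big <- grepl("AAAAAAAAAA", ds$records$junction_aa)
    strat[s] <- chisq_dist(mean(in_big), big_share_pre)
    u_idx <- withr::with_seed(1000 + s, sample.int(nrow(rec), 30))
    unif[s] <- chisq_dist(mean(grepl("AAAAAAAAAA",
                                     rec$junction_aa[u_idx])),
                          big_share_pre)
  }
  expect_lt(mean(strat), mean(unif))

  # full-size target is the identity up to order
  full <- stratified_downsample(rep0, nrow(rec), seed = 1, assignment = ca)
  expect_setequal(full$records$sequence_id, rec$sequence_id)
  # single-clone repertoire: any sample trivially preserves structure
  ds1 <- stratified_downsample(big, 10, seed = 2)
  expect_equal(nrow(ds1$records), 10)
  expect_error(stratified_downsample(big, 1000), regexp = "exceeds")
})
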