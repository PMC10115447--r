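# Germline gene usage profiling and separability analysis.

# per-record germline labels for one segment at gene or subgroup level;
# NAs (no call) are dropped
segment_labels <- function(records, segment = c("V", "D", "J"),
                           level = c("gene", "subgroup"),
                           loci = "IGH") {
  segment <- match.arg(segment)
  level <- match.arg(level)
  rec <- records[records$locus %in% loci, , drop = FALSE]
  col <- switch(segment, V = "v_call", D = "d_call", J = "j_call")
  if (!col %in% names(rec)) return(character(0))
  calls <- rec[[col]]
  labs <- if (level == "gene") strip_allele(calls) else call_subgroup(calls)
  labs[!is.na(labs) & nzchar(labs)]
}

#' Germline gene usage profile of a repertoire
#'
#' Computes the frequency of each germline gene (or gene subgroup) among the
#' records carrying a call for the requested segment. Frequencies are per
#' sequence as stored: collapse with [collapse_unique()] first to profile
#' unique sequences.
#'
#' @param rep a [repertoire].
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param level `"gene"` or `"subgroup"`.
#' @param loci loci to include; `"IGH"` (default) or `c("IGK", "IGL")` for
#'   light chains.
#' @param reference_labels optional labels to force onto the axis with
#'   frequency 0 when unobserved.
#' @return a `usage_profile`: subject id, named frequency vector summing to
#'   1, and the number of sequences used.
#' @export
usage_profile <- function(rep, segment = c("V", "D", "J"),
                          level = c("gene", "subgroup"), loci = "IGH",
                          reference_labels = NULL) {
  stopifnot(is_repertoire(rep))
  segment <- match.arg(segment)
  level <- match.arg(level)
  labs <- segment_labels(rep$records, segment, level, loci)
  if (length(labs) == 0) {
    abort(sprintf("no records with a %s call in subject %s",
                  segment, rep$subject_id),
          class = "bcrcompare_empty_result_error")
  }
  counts <- table(labs)
  axis <- union(names(counts), reference_labels)
  freq <- setNames(numeric(length(axis)), axis)
  freq[names(counts)] <- as.numeric(counts) / length(labs)
  freq <- freq[order(names(freq))]
  structure(
    list(subject_id = rep$subject_id, frequencies = freq,
         n_sequences = length(labs), segment = segment, level = level),
    class = "usage_profile"
  )
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> %s: %s %s over %d sequences, %d categories\n",
              x$subject_id, x$segment, x$level, x$n_sequences,
              length(x$frequencies)))
  invisible(x)
}

#' Kappa/lambda light-chain usage ratio
#'
#' @param rep a [repertoire] containing light-chain records.
#' @return named numeric `c(kappa = , lambda = )` in percent, summing to 100.
#' @export
kappa_lambda_ratio <- function(rep) {
  stopifnot(is_repertoire(rep))
  lr <- light_records(rep)
  if (nrow(lr) == 0) {
    abort(sprintf("no light-chain records in subject %s", rep$subject_id),
          class = "bcrcompare_empty_result_error")
  }
  k <- sum(lr$locus == "IGK")
  c(kappa = 100 * k / nrow(lr), lambda = 100 * (nrow(lr) - k) / nrow(lr))
}

# stack usage profiles (or a ready matrix) into a subjects x categories
# frequency matrix on the shared (union) axis, unobserved categories at 0
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "usage_profile")))
  axis <- sort(unique(unlist(lapply(profiles,
                                    function(p) names(p$frequencies)))))
  mat <- matrix(0, nrow = length(profiles), ncol = length(axis),
                dimnames = list(vapply(profiles, `[[`, "", "subject_id"),
                                axis))
  for (i in seq_along(profiles)) {
    f <- profiles[[i]]$frequencies
    mat[i, names(f)] <- f
  }
  mat
}

#' Z-normalise usage profiles across subjects
#'
#' Centres and scales each category (column) to mean 0 and sample (n-1)
#' standard deviation 1 across subjects. Zero-variance categories are set to
#' all-zero and recorded in the `"zero_variance"` attribute.
#'
#' @param profiles list of `usage_profile` objects (>= 2) or a subjects x
#'   categories frequency matrix.
#' @return Z-score matrix (subjects x categories).
#' @export
z_normalise <- function(profiles) {
  mat <- profile_matrix(profiles)
  if (nrow(mat) < 2) {
    abort("z_normalise() needs at least 2 profiles")
  }
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  flat <- sdv <= 0 | !is.finite(sdv)
  z <- sweep(mat, 2, mu, "-")
  z[, !flat] <- sweep(z[, !flat, drop = FALSE], 2, sdv[!flat], "/")
  z[, flat] <- 0
  attr(z, "zero_variance") <- colnames(mat)[flat]
  z
}

#' Hierarchically cluster usage profiles
#'
#' Agglomerative clustering on Euclidean distances between rows, with the
#' two-group cut used for separability analyses.
#'
#' @param mat numeric matrix, typically from [z_normalise()].
#' @param linkage agglomeration method (default `"average"`, i.e. UPGMA).
#' @return list with the `hclust` tree, the 2-cluster cut labels and the
#'   distance object.
#' @export
cluster_profiles <- function(mat, linkage = "average") {
  if (!is.matrix(mat) || nrow(mat) < 2) {
    abort("cluster_profiles() needs a matrix with >= 2 rows")
  }
  if (any(!is.finite(mat))) {
    abort("cluster_profiles(): matrix contains non-finite values")
  }
  d <- stats::dist(mat)
  tree <- stats::hclust(d, method = linkage)
  list(tree = tree, cut2 = stats::cutree(tree, k = 2), dist = d)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items:
#' 1 for identical partitions (up to relabelling), ~0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("adjusted_rand(): label vectors differ in length")
  }
  n <- length(labels_a)
  if (n < 2) abort("adjusted_rand() needs >= 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps^0.5) {
    return(1)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Gene-usage separability of repertoire groups under subsampling
#'
#' Repeats the protocol: subsample each repertoire (without replacement) to a
#' common depth, recompute usage profiles, Z-normalise, cluster
#' hierarchically and compare the two-group cut against the true group
#' labels with the adjusted Rand index. Reports the fraction of repeats with
#' a perfect (ARI = 1) separation.
#'
#' @param reps list of [repertoire] objects.
#' @param true_labels group label per repertoire.
#' @param subsample_n subsample depth (e.g. 105 sequences).
#' @param n_repeats number of subsampling repeats (default 100).
#' @param seed RNG seed.
#' @param segment,level,loci passed to [usage_profile()].
#' @param linkage passed to [cluster_profiles()].
#' @return list with `fraction_perfect`, the per-repeat ARI values and the
#'   protocol parameters.
#' @export
separability_test <- function(reps, true_labels, subsample_n,
                              n_repeats = 100, seed = 1,
                              segment = "V", level = "gene", loci = "IGH",
                              linkage = "average") {
  stopifnot(length(reps) == length(true_labels), length(reps) >= 2)
  eligible <- lapply(reps, function(r) {
    rec <- r$records[r$records$locus %in% loci, , drop = FALSE]
    col <- switch(segment, V = "v_call", D = "d_call", J = "j_call")
    rec[!is.na(rec[[col]]), , drop = FALSE]
  })
  sizes <- vapply(eligible, nrow, 0L)
  if (any(sizes < subsample_n)) {
    small <- vapply(reps[sizes < subsample_n], `[[`, "", "subject_id")
    abort(sprintf("subsample_n = %d exceeds repertoire size of: %s",
                  subsample_n, paste(small, collapse = ", ")))
  }
  ari <- with_seed(seed, vapply(seq_len(n_repeats), function(r) {
    profs <- lapply(seq_along(reps), function(i) {
      rec <- eligible[[i]][sample.int(sizes[i], subsample_n), , drop = FALSE]
      usage_profile(set_records(reps[[i]], rec), segment, level, loci)
    })
    cl <- cluster_profiles(z_normalise(profs), linkage)
    adjusted_rand(cl$cut2, true_labels)
  }, numeric(1)))
  list(
    fraction_perfect = mean(ari >= 1 - 1e-12),
    ari = ari,
    n_repeats = n_repeats,
    subsample_n = subsample_n,
    seed = seed,
    segment = segment,
    level = level
  )
}

#' Per-category usage difference tests between two groups of subjects
#'
#' For every category on the shared axis, a two-sided Wilcoxon rank-sum
#' (Mann-Whitney U) test of per-subject frequencies, with Benjamini-Hochberg
#' adjustment across categories.
#'
#' @param group_a,group_b lists of `usage_profile` objects (>= 2 subjects
#'   each; a warning is issued below 3).
#' @return tibble with per-category statistic, p-value and BH-adjusted
#'   p-value.
#' @export
usage_difference_tests <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("usage_difference_tests() needs >= 2 subjects per group")
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    warn("fewer than 3 subjects in a group; rank-sum tests will be weak")
  }
  mat <- profile_matrix(c(group_a, group_b))
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  res <- lapply(colnames(mat), function(cat) {
    x <- mat[ia, cat]
    y <- mat[ib, cat]
    if (length(unique(c(x, y))) == 1) {
      # a constant category carries no evidence either way
      return(tibble::tibble(category = cat, statistic = NA_real_, p = 1,
                            mean_a = mean(x), mean_b = mean(y)))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    tibble::tibble(category = cat, statistic = unname(ht$statistic),
                   p = ht$p.value,
                   mean_a = mean(x), mean_b = mean(y))
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Subsampled gene richness of a repertoire
#'
#' Mean number of distinct germline categories observed in repeated
#' without-replacement subsamples of a fixed depth. With `segment = "VJ"`
#' counts distinct V-J gene combinations (combinatorial diversity).
#'
#' @param rep a [repertoire].
#' @param depth subsample size.
#' @param n_repeats number of subsamples.
#' @param seed RNG seed.
#' @param segment `"V"`, `"D"`, `"J"` or `"VJ"`.
#' @param level `"gene"` or `"subgroup"`.
#' @param loci loci to include.
#' @return mean distinct-category count across repeats.
#' @export
richness_at_depth <- function(rep, depth, n_repeats = 20, seed = 1,
                              segment = "V", level = "gene", loci = "IGH") {
  stopifnot(is_repertoire(rep))
  if (segment == "VJ") {
    rec <- rep$records[rep$records$locus %in% loci, , drop = FALSE]
    v <- if (level == "gene") strip_allele(rec$v_call) else
      call_subgroup(rec$v_call)
    j <- if (level == "gene") strip_allele(rec$j_call) else
      call_subgroup(rec$j_call)
    labs <- paste(v, j, sep = "|")[!is.na(v) & !is.na(j)]
  } else {
    labs <- segment_labels(rep$records, segment, level, loci)
  }
  if (depth > length(labs)) {
    abort(sprintf("depth %d exceeds the %d eligible records of subject %s",
                  depth, length(labs), rep$subject_id))
  }
  with_seed(seed, mean(vapply(seq_len(n_repeats), function(r) {
    length(unique(sample(labs, depth)))
  }, numeric(1))))
}
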