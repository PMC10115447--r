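# Comparison of repertoires by usage of per-sequence categorical structural
# annotations (CDRH3 structural cluster IDs / canonical classes). The
# annotations themselves are an input contract -- a table with one category
# per sequence -- decoupled from any structure-prediction software.

#' Synthetic structural-template background
#'
#' Builds a synthetic background of length-specific structural categories
#' (emulating a clustered CDRH3 template database): per CDR3 length, a fixed
#' number of categories of human, murine and other origin, with heavy-tailed
#' database frequencies summing to 1 within each length stratum. The
#' origin mix approximates a template database in which ~41% of structures
#' are murine and ~37% human.
#'
#' @param lengths CDR3 amino-acid lengths covered (default 4:16).
#' @param per_length categories per origin per length stratum.
#' @param seed seed for the (fixed) frequency draw.
#' @return tibble with `category_id`, `origin`, `cdr3_aa_length`,
#'   `frequency` (summing to 1 within each length).
#' @export
synthetic_background <- function(lengths = 4:16,
                                 per_length = c(human = 11, mouse = 12,
                                                other = 7),
                                 seed = 20230327) {
  rows <- list()
  for (len in lengths) {
    origin <- rep(names(per_length), per_length)
    ids <- sprintf("SC_L%02d_%s%02d", len, toupper(substr(origin, 1, 1)),
                   unlist(lapply(per_length, seq_len)))
    rows[[as.character(len)]] <- tibble::tibble(
      category_id = ids, origin = origin, cdr3_aa_length = len
    )
  }
  bg <- dplyr::bind_rows(rows)
  freq <- with_seed(seed, stats::rgamma(nrow(bg), shape = 0.6))
  bg$frequency <- freq
  bg |>
    dplyr::group_by(.data$cdr3_aa_length) |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    dplyr::ungroup()
}

# species-specific CDR3 length distributions inside the structural window
species_length_probs <- function(species, lengths) {
  mu <- switch(species, human = 12.8, kymouse = 12.2, mouse = 11.0,
               abort("unknown species"))
  p <- stats::dnorm(lengths, mean = mu, sd = 2.2)
  p / sum(p)
}

#' Simulate per-sequence structural annotation tables
#'
#' Emulates the inputs of a structural-cluster usage analysis: for each
#' subject, CDR3 lengths are drawn from a species-specific distribution and
#' a structural category is drawn from the background frequencies at that
#' length, tilted towards the subject species' own-origin templates
#' (human-origin for human and humanised subjects, murine-origin for mice).
#'
#' @param n_subjects named integer vector, subjects per species, e.g.
#'   `c(human = 10, kymouse = 7, mouse = 5)`.
#' @param n_per_subject sequences per subject.
#' @param background background table from [synthetic_background()].
#' @param bias multiplicative tilt applied to own-origin template
#'   frequencies (1 = sample straight from the background).
#' @param seed RNG seed.
#' @return tibble with `subject_id`, `species`, `cdr3_aa_length`,
#'   `category_id`, `category_origin`.
#' @export
simulate_annotation_table <- function(n_subjects, n_per_subject = 300,
                                      background = synthetic_background(),
                                      bias = 4, seed = 1) {
  stopifnot(all(names(n_subjects) %in% c("human", "kymouse", "mouse")))
  lengths <- sort(unique(background$cdr3_aa_length))
  bg_by_len <- split(background, background$cdr3_aa_length)
  seeds <- derive_seeds(seed, sum(n_subjects))
  rows <- list()
  s_idx <- 0L
  for (species in names(n_subjects)) {
    own <- if (species == "mouse") "mouse" else "human"
    lp <- species_length_probs(species, lengths)
    for (s in seq_len(n_subjects[[species]])) {
      s_idx <- s_idx + 1L
      subject <- sprintf("%s_%02d", species, s)
      rows[[subject]] <- with_seed(seeds[s_idx], {
        len_draw <- sample(lengths, n_per_subject, replace = TRUE,
                           prob = lp)
        counts <- table(factor(len_draw, levels = lengths))
        picks <- lapply(lengths[counts > 0], function(len) {
          bg <- bg_by_len[[as.character(len)]]
          w <- bg$frequency * ifelse(bg$origin == own, bias, 1)
          k <- counts[[as.character(len)]]
          idx <- sample.int(nrow(bg), k, replace = TRUE, prob = w)
          tibble::tibble(
            cdr3_aa_length = len,
            category_id = bg$category_id[idx],
            category_origin = bg$origin[idx]
          )
        })
        out <- dplyr::bind_rows(picks)
        out$subject_id <- subject
        out$species <- species
        out[, c("subject_id", "species", "cdr3_aa_length", "category_id",
                "category_origin")]
      })
    }
  }
  dplyr::bind_rows(rows)
}

#' Category usage profile of one subject
#'
#' Proportions of each annotation category among a subject's sequences; the
#' result is a `usage_profile` and feeds [z_normalise()] and
#' [cluster_profiles()] unchanged.
#'
#' @param annotations annotation table (columns `subject_id`, `category_id`, ...).
#' @param subject subject id present in the table.
#' @return a `usage_profile`.
#' @export
category_usage_profile <- function(annotations, subject) {
  rows <- annotations[annotations$subject_id == subject, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("unknown subject: %s", subject))
  }
  counts <- table(rows$category_id)
  freq <- as.numeric(counts) / nrow(rows)
  names(freq) <- names(counts)
  structure(
    list(subject_id = subject, frequencies = freq[order(names(freq))],
         n_sequences = nrow(rows), segment = "category",
         level = "category"),
    class = "usage_profile"
  )
}

#' Usage-distance analysis of categorical annotation profiles
#'
#' Euclidean distances between subjects in Z-normalised category
#' proportions, hierarchical clustering with the two-group cut scored
#' against the true species labels (adjusted Rand index), and the pairwise
#' distances stratified by comparison type (within- vs between-species).
#'
#' @param annotations annotation table covering >= 3 subjects and >= 2 species.
#' @param true_labels named group label per subject (defaults to the species
#'   column); the ARI compares the 2-cut against these labels.
#' @param linkage agglomeration method.
#' @return list: `dist` (subject x subject matrix), `tree`, `cut2`, `ari`,
#'   and `comparisons` (tibble of pairwise distances with comparison type).
#' @export
usage_distance_analysis <- function(annotations, true_labels = NULL,
                                    linkage = "average") {
  subjects <- unique(annotations$subject_id)
  if (length(subjects) < 3) {
    abort("usage_distance_analysis() needs >= 3 subjects")
  }
  if (is.null(true_labels)) {
    true_labels <- setNames(
      annotations$species[match(subjects, annotations$subject_id)], subjects
    )
  }
  profiles <- lapply(subjects, category_usage_profile,
                     annotations = annotations)
  z <- z_normalise(profiles)
  if (ncol(z) == 0) abort("shared category axis is empty")
  cl <- cluster_profiles(z, linkage)
  dmat <- as.matrix(cl$dist)
  ari <- adjusted_rand(cl$cut2, true_labels[subjects])
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  comparisons <- tibble::tibble(
    subject_a = subjects[pairs[, 1]],
    subject_b = subjects[pairs[, 2]],
    group_a = unname(true_labels[subjects[pairs[, 1]]]),
    group_b = unname(true_labels[subjects[pairs[, 2]]]),
    distance = dmat[pairs]
  )
  comparisons$type <- ifelse(
    comparisons$group_a == comparisons$group_b,
    paste0("within_", comparisons$group_a),
    paste0("between_", pmin(comparisons$group_a, comparisons$group_b), "_",
           pmax(comparisons$group_a, comparisons$group_b))
  )
  list(dist = dmat, tree = cl$tree, cut2 = cl$cut2, ari = ari,
       comparisons = comparisons)
}

#' Species-origin composition of the categories a group uses
#'
#' Proportion of each template origin among the structural categories used
#' by a subject group. By default each distinct category counts once
#' (matching "structural clusters used"); `weighted = TRUE` weights by
#' sequence usage instead.
#'
#' @param annotations annotation table with `category_origin`.
#' @param subjects subject ids forming the group (default: all).
#' @param weighted count sequences instead of distinct categories.
#' @return named proportion vector over origins.
#' @export
species_origin_bias <- function(annotations, subjects = NULL, weighted = FALSE) {
  rows <- if (is.null(subjects)) annotations else
    annotations[annotations$subject_id %in% subjects, , drop = FALSE]
  if (nrow(rows) == 0) abort("no rows for the requested subjects")
  missing_origin <- is.na(rows$category_origin)
  if (mean(missing_origin) > 0.10) {
    warn(sprintf("origin missing for %.1f%% of rows; excluded",
                 100 * mean(missing_origin)))
  }
  rows <- rows[!missing_origin, , drop = FALSE]
  if (!weighted) {
    rows <- dplyr::distinct(rows, .data$category_id, .data$category_origin)
  }
  tab <- table(rows$category_origin)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Length-stratified enrichment of an origin versus the background
#'
#' For each CDR3 length, the ratio of the observed proportion of sequences
#' annotated with templates of the given origin to that origin's proportion
#' in the background database at the same length, with a two-sided exact
#' binomial test against the background proportion. Under pure background
#' sampling the ratios are ~1 and nothing is significant at the 1% level.
#'
#' @param annotations annotation table for the subjects of interest.
#' @param background background table ([synthetic_background()] layout).
#' @param origin origin to test (e.g. `"human"`).
#' @param alpha significance level (default 0.01).
#' @return tibble per length: observed/background proportions, `ratio`
#'   (`Inf` flagged when the background proportion is 0), binomial `p`,
#'   `significant`.
#' @export
enrichment_by_length <- function(annotations, background, origin = "human",
                                 alpha = 0.01) {
  bg_prop <- background |>
    dplyr::group_by(.data$cdr3_aa_length) |>
    dplyr::summarise(
      background_prop = sum(.data$frequency[.data$origin == !!origin]),
      .groups = "drop"
    )
  missing_len <- setdiff(unique(annotations$cdr3_aa_length),
                         bg_prop$cdr3_aa_length)
  if (length(missing_len) > 0) {
    abort(paste0("background does not cover CDR3 length(s): ",
                 paste(sort(missing_len), collapse = ", ")))
  }
  obs <- annotations |>
    dplyr::group_by(.data$cdr3_aa_length) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_origin = sum(.data$category_origin == !!origin),
      .groups = "drop"
    ) |>
    dplyr::left_join(bg_prop, by = "cdr3_aa_length")
  obs$observed_prop <- obs$n_origin / obs$n
  obs$ratio <- ifelse(
    obs$background_prop > 0, obs$observed_prop / obs$background_prop,
    ifelse(obs$observed_prop > 0, Inf, NA_real_)
  )
  obs$p <- mapply(function(x, n, p0) {
    if (p0 <= 0 || p0 >= 1) return(NA_real_)
    stats::binom.test(x, n, p = p0)$p.value
  }, obs$n_origin, obs$n, obs$background_prop)
  obs$significant <- !is.na(obs$p) & obs$p < alpha
  obs
}

#' Greedy leader clustering of a distance matrix
#'
#' Iterates items in input order: an item joins the first existing cluster
#' whose representative (founder) lies within `cutoff`, otherwise it founds
#' a new cluster. Deterministic given the input order; callers should fix
#' the order (e.g. sort by id) for reproducibility.
#'
#' @param distances square symmetric non-negative matrix with zero diagonal.
#' @param cutoff joining threshold (e.g. 0.6 for an RMSD cut-off in
#'   angstroms).
#' @return integer cluster assignment, with attribute `"representatives"`
#'   (founder index per cluster).
#' @export
greedy_cluster <- function(distances, cutoff) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    abort("greedy_cluster() needs a square matrix")
  }
  if (max(abs(distances - t(distances))) > 1e-9) {
    abort("greedy_cluster(): matrix is asymmetric beyond 1e-9")
  }
  if (any(distances < 0) || any(abs(diag(distances)) > 1e-9)) {
    abort("greedy_cluster(): distances must be non-negative with zero diagonal")
  }
  n <- nrow(distances)
  assignment <- integer(n)
  reps_idx <- integer(0)
  for (i in seq_len(n)) {
    hit <- which(distances[i, reps_idx] <= cutoff)
    if (length(hit) > 0) {
      assignment[i] <- hit[1]
    } else {
      reps_idx <- c(reps_idx, i)
      assignment[i] <- length(reps_idx)
    }
  }
  attr(assignment, "representatives") <- reps_idx
  assignment
}

#' Length-balanced subsamples of an annotation table
#'
#' Draws subsamples containing equal numbers of sequences of each retained
#' CDR3 length from every subject, removing length-composition differences
#' before downstream clustering.
#'
#' @param annotations annotation table.
#' @param n_per_length sequences per length per subject in each subsample.
#' @param n_subsamples number of subsamples (default 100).
#' @param seed RNG seed.
#' @param lengths retained length window (default 4:16).
#' @return list of subsampled annotation tables.
#' @export
length_balanced_subsample <- function(annotations, n_per_length,
                                      n_subsamples = 100, seed = 1,
                                      lengths = 4:16) {
  annotations <- annotations[annotations$cdr3_aa_length %in% lengths, ,
                             drop = FALSE]
  avail <- annotations |>
    dplyr::count(.data$subject_id, .data$cdr3_aa_length)
  grid <- tidyr::expand_grid(
    subject_id = unique(annotations$subject_id),
    cdr3_aa_length = lengths
  ) |>
    dplyr::left_join(avail, by = c("subject_id", "cdr3_aa_length")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  short <- grid[grid$n < n_per_length, , drop = FALSE]
  if (nrow(short) > 0) {
    worst <- short[which.min(short$n), ]
    abort(sprintf(
      "n_per_length = %d infeasible: subject %s has %d sequences of length %d",
      n_per_length, worst$subject_id, worst$n, worst$cdr3_aa_length))
  }
  groups <- split(seq_len(nrow(annotations)),
                  paste(annotations$subject_id, annotations$cdr3_aa_length))
  seeds <- derive_seeds(seed, n_subsamples)
  lapply(seq_len(n_subsamples), function(r) {
    idx <- with_seed(seeds[r], unlist(lapply(groups, function(g) {
      g[sample.int(length(g), n_per_length)]
    }), use.names = FALSE))
    annotations[sort(idx), , drop = FALSE]
  })
}
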