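# Clonotype assignment, CDRH3 sharing and clonal-structure-preserving
# downsampling.

# interior of the junction (IMGT CDR3): junction minus both anchor residues
cdr3_aa <- function(junction_aa) {
  substr(junction_aa, 2L, nchar(junction_aa) - 1L)
}

# pairwise Hamming fraction-mismatch matrix for equal-length strings
hamming_dist_matrix <- function(strings) {
  m <- length(strings)
  L <- nchar(strings[1])
  C <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  matches <- matrix(0, m, m)
  for (pos in seq_len(L)) {
    matches <- matches + outer(C[, pos], C[, pos], "==")
  }
  (L - matches) / L
}

#' Assign clonotypes
#'
#' Groups heavy-chain sequences into clonotypes: records sharing IGHV gene,
#' IGHJ gene (alleles stripped) and CDR3 amino-acid length are clustered so
#' that two CDR3s join one clone when their amino-acid identity is at least
#' `identity_threshold` (Hamming identity on the length-matched CDR3s),
#' with single-linkage closure by default.
#'
#' @param reps a [repertoire] or list of repertoires (pooled; records keep
#'   their subject of origin).
#' @param identity_threshold minimum CDR3 amino-acid identity (inclusive);
#'   default 0.90.
#' @param linkage `"single"` (default, transitive closure) or `"complete"`.
#' @return a `clonotype_assignment`: `$assignment` maps every usable record
#'   (sequence_id, subject_id) to a clone id; `$clones` is the clone table
#'   (v_gene, j_gene, cdr3_aa_length, size, n_subjects, representative CDR3).
#'   Records missing a key field are dropped with a logged count
#'   (`$n_dropped`).
#' @export
assign_clonotypes <- function(reps, identity_threshold = 0.90,
                              linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (is_repertoire(reps)) reps <- list(reps)
  stopifnot(all(vapply(reps, is_repertoire, TRUE)))
  rec <- dplyr::bind_rows(lapply(reps, function(r) {
    h <- heavy_records(r)
    h$subject_id <- r$subject_id
    h[, intersect(c("sequence_id", "subject_id", "v_call", "j_call",
                    "junction_aa"), names(h))]
  }))
  usable <- !is.na(rec$v_call) & !is.na(rec$j_call) &
    !is.na(rec$junction_aa) & nchar(rec$junction_aa) >= 3
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    inform(sprintf("assign_clonotypes: dropped %d record(s) missing V/J/CDR3",
                   n_dropped))
  }
  rec <- rec[usable, , drop = FALSE]
  if (nrow(rec) == 0) {
    abort("no records usable for clonotyping",
          class = "bcrcompare_empty_result_error")
  }
  rec$v_gene <- strip_allele(rec$v_call)
  rec$j_gene <- strip_allele(rec$j_call)
  rec$cdr3 <- cdr3_aa(rec$junction_aa)
  rec$len <- nchar(rec$cdr3)
  part_key <- paste(rec$v_gene, rec$j_gene, rec$len, sep = "|")

  clone_of <- integer(nrow(rec))
  next_id <- 0L
  # iterate partitions in input order so clone ids are deterministic
  for (key in unique(part_key)) {
    idx <- which(part_key == key)
    cdr3s <- rec$cdr3[idx]
    uniq <- unique(cdr3s)
    if (length(uniq) == 1) {
      member <- rep(1L, length(idx))
    } else {
      d <- hamming_dist_matrix(uniq)
      tree <- stats::hclust(stats::as.dist(d), method = linkage)
      member_u <- stats::cutree(tree, h = 1 - identity_threshold + 1e-9)
      # renumber clusters by first appearance for determinism
      member_u <- match(member_u, unique(member_u))
      member <- member_u[match(cdr3s, uniq)]
    }
    clone_of[idx] <- next_id + member
    next_id <- next_id + max(member)
  }
  rec$clone_id <- clone_of

  clones <- rec |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      v_gene = dplyr::first(.data$v_gene),
      j_gene = dplyr::first(.data$j_gene),
      cdr3_aa_length = dplyr::first(.data$len),
      size = dplyr::n(),
      n_subjects = dplyr::n_distinct(.data$subject_id),
      representative = dplyr::first(.data$cdr3),
      .groups = "drop"
    )
  structure(
    list(
      assignment = rec[, c("sequence_id", "subject_id", "clone_id")],
      clones = clones,
      identity_threshold = identity_threshold,
      linkage = linkage,
      n_dropped = n_dropped
    ),
    class = "clonotype_assignment"
  )
}

#' @export
print.clonotype_assignment <- function(x, ...) {
  cat(sprintf(
    "<clonotype_assignment> %d records in %d clones (identity >= %.2f, %s linkage)\n",
    nrow(x$assignment), nrow(x$clones), x$identity_threshold, x$linkage))
  invisible(x)
}

#' Set of exact CDRH3 amino-acid sequences
#'
#' @param rep a [repertoire].
#' @return character vector of distinct CDR3 (junction-interior) amino-acid
#'   strings over the heavy-chain records.
#' @export
exact_cdrh3_set <- function(rep) {
  stopifnot(is_repertoire(rep))
  h <- heavy_records(rep)
  h <- h[!is.na(h$junction_aa) & nchar(h$junction_aa) >= 3, , drop = FALSE]
  unique(cdr3_aa(h$junction_aa))
}

#' Pairwise sharing of CDRH3s or clonotypes between repertoires
#'
#' For each pair of repertoires, counts shared items -- exact CDR3
#' amino-acid matches, or clonotypes under a joint clustering of the pooled
#' pair (a clone is shared when it contains members from both subjects) --
#' and expresses them as a percentage under the chosen denominator
#' convention: `"mean"` (default) averages the two directional fractions,
#' `"min"` divides by the smaller set, `"jaccard"` by the union.
#'
#' @param reps list of >= 2 repertoires.
#' @param unit `"cdrh3"` or `"clonotype"`.
#' @param convention denominator convention.
#' @param identity_threshold CDR3 identity threshold for clonotype sharing.
#' @return symmetric subject x subject matrix of shared percentages
#'   (diagonal 100).
#' @export
pairwise_overlap <- function(reps, unit = c("cdrh3", "clonotype"),
                             convention = c("mean", "min", "jaccard"),
                             identity_threshold = 0.90) {
  unit <- match.arg(unit)
  convention <- match.arg(convention)
  stopifnot(length(reps) >= 2, all(vapply(reps, is_repertoire, TRUE)))
  if (unit == "clonotype" &&
      any(vapply(reps, function(r) nrow(heavy_records(r)) == 0, TRUE))) {
    abort("clonotype overlap needs heavy-chain records in every repertoire")
  }
  ids <- vapply(reps, `[[`, "", "subject_id")
  n <- length(reps)
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  combine <- function(fa, fb, shared, na, nb) {
    switch(convention,
           mean = 100 * (fa + fb) / 2,
           min = 100 * shared / min(na, nb),
           jaccard = 100 * shared / (na + nb - shared))
  }
  if (unit == "cdrh3") {
    sets <- lapply(reps, exact_cdrh3_set)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shared <- length(intersect(sets[[i]], sets[[j]]))
        na <- length(sets[[i]]); nb <- length(sets[[j]])
        val <- combine(shared / na, shared / nb, shared, na, nb)
        out[i, j] <- out[j, i] <- val
      }
    }
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        joint <- assign_clonotypes(list(reps[[i]], reps[[j]]),
                                   identity_threshold)
        per_clone <- joint$assignment |>
          dplyr::distinct(.data$clone_id, .data$subject_id)
        tab <- table(per_clone$clone_id, per_clone$subject_id)
        in_i <- tab[, ids[i]] > 0
        in_j <- tab[, ids[j]] > 0
        shared <- sum(in_i & in_j)
        na <- sum(in_i); nb <- sum(in_j)
        val <- combine(shared / na, shared / nb, shared, na, nb)
        out[i, j] <- out[j, i] <- val
      }
    }
  }
  attr(out, "unit") <- unit
  attr(out, "convention") <- convention
  out
}

# largest-remainder integer allocation of `n` across strata with the given
# weights
allocate_proportional <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Downsample a repertoire preserving its clonal structure
#'
#' Stratified sampling: heavy-chain records are stratified by the size of
#' their clone (from [assign_clonotypes()]) and each stratum contributes in
#' proportion to its share of records, so the post-sample clone-size
#' spectrum matches the original in expectation (unlike uniform record
#' sampling, which erodes large clones' share of a small sample).
#'
#' @param rep a [repertoire].
#' @param n_target number of records to keep (<= available heavy records).
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @param assignment optional precomputed [assign_clonotypes()] result for
#'   `rep`.
#' @return a [repertoire] of `n_target` heavy-chain records.
#' @export
stratified_downsample <- function(rep, n_target, seed = 1,
                                  assignment = NULL) {
  stopifnot(is_repertoire(rep))
  h <- heavy_records(rep)
  if (n_target > nrow(h)) {
    abort(sprintf("n_target %d exceeds the %d heavy records of subject %s",
                  n_target, nrow(h), rep$subject_id))
  }
  assignment <- assignment %||% assign_clonotypes(rep)
  clone <- assignment$assignment$clone_id[
    match(h$sequence_id, assignment$assignment$sequence_id)]
  size <- assignment$clones$size[match(clone, assignment$clones$clone_id)]
  size[is.na(size)] <- 1L
  strata <- split(seq_len(nrow(h)), size)
  counts <- vapply(strata, length, 0L)
  take <- allocate_proportional(n_target, counts)
  # proportional allocation can exceed a stratum only through rounding of
  # empty remainders; clamp and backfill from the largest strata
  take <- pmin(take, counts)
  deficit <- n_target - sum(take)
  while (deficit > 0) {
    room <- which(take < counts)
    pick <- room[order(counts[room] - take[room], decreasing = TRUE)][1]
    take[pick] <- take[pick] + 1L
    deficit <- deficit - 1L
  }
  idx <- with_seed(seed, unlist(lapply(seq_along(strata), function(k) {
    if (take[k] == 0) return(integer(0))
    s <- strata[[k]]
    s[sample.int(length(s), take[k])]
  })))
  set_records(rep, h[sort(idx), , drop = FALSE],
              note = sprintf("stratified downsample to %d records (seed %d)",
                             n_target, seed))
}
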