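# Junction anatomy and the five-factor bootstrap decomposition of CDRH3
# length differences.

#' Junction anatomy of heavy-chain records
#'
#' Extracts, per record, the five components of CDR3 length: the germline V
#' tail (`v_cdr3_nt`), VD insertions (`np1`), the aligned D segment
#' (`d_align`), DJ insertions (`np2`) and the germline J head (`j_cdr3_nt`),
#' all in nucleotides. Explicit AIRR fields (`np1_length`, `np2_length`, and
#' the contribution columns) are preferred; `np1`/`np2` are otherwise
#' derived from 1-based inclusive alignment coordinates
#' (`np1 = d_sequence_start - v_sequence_end - 1`, and correspondingly for
#' `np2`). Records without a D call get `d_align = 0`, the whole insertion
#' assigned to `np1`, and `no_d = TRUE` (keeping the conservation identity
#' `cdr3_nt = v + np1 + d + np2 + j`).
#'
#' @param rep a [repertoire] (heavy-chain records are used).
#' @return tibble with columns `v_cdr3_nt`, `np1`, `d_align`, `np2`,
#'   `j_cdr3_nt`, `cdr3_nt_length`, `no_d`.
#' @export
junction_anatomy <- function(rep) {
  stopifnot(is_repertoire(rep))
  h <- heavy_records(rep)
  if (nrow(h) == 0) {
    abort("no heavy-chain records", class = "bcrcompare_empty_result_error")
  }
  get_int <- function(col) {
    if (col %in% names(h)) as.integer(h[[col]]) else
      rep(NA_integer_, nrow(h))
  }
  np1 <- get_int("np1_length")
  np2 <- get_int("np2_length")
  v_end <- get_int("v_sequence_end")
  d_start <- get_int("d_sequence_start")
  d_end <- get_int("d_sequence_end")
  j_start <- get_int("j_sequence_start")
  derive1 <- is.na(np1) & !is.na(v_end) & !is.na(d_start)
  np1[derive1] <- d_start[derive1] - v_end[derive1] - 1L
  derive2 <- is.na(np2) & !is.na(d_end) & !is.na(j_start)
  np2[derive2] <- j_start[derive2] - d_end[derive2] - 1L

  d_align <- get_int("d_align_nt")
  no_d <- is.na(h$d_call) | !nzchar(ifelse(is.na(h$d_call), "", h$d_call))
  # no D assigned: zero-length D, single combined insertion kept in np1
  d_align[no_d] <- 0L
  np1[no_d & is.na(np1) & !is.na(v_end) & !is.na(j_start)] <-
    (j_start - v_end - 1L)[no_d & is.na(np1) & !is.na(v_end) &
                             !is.na(j_start)]
  np2[no_d & is.na(np2)] <- 0L

  v_c <- get_int("v_cdr3_nt")
  j_c <- get_int("j_cdr3_nt")
  cdr3_nt <- 3L * get_int("cdr3_aa_length")
  if (all(is.na(cdr3_nt)) && "junction_aa" %in% names(h)) {
    cdr3_nt <- 3L * (nchar(h$junction_aa) - 2L)
  }
  anatomy <- tibble::tibble(
    v_cdr3_nt = v_c, np1 = np1, d_align = d_align, np2 = np2,
    j_cdr3_nt = j_c, cdr3_nt_length = cdr3_nt, no_d = no_d
  )
  if (all(is.na(anatomy$np1)) && all(is.na(anatomy$np2))) {
    abort("junction anatomy not computable: no insertion fields or coordinates",
          class = "bcrcompare_annotation_error")
  }
  anatomy
}

#' Bootstrap estimate of a difference in means
#'
#' Point estimate `mean(a) - mean(b)` with a percentile 95% confidence
#' interval over `n_reps` bootstrap resamples (each group resampled with
#' replacement) and a two-sided sign-crossing p-value: twice the proportion
#' of resampled differences on the opposite side of zero from the point
#' estimate, floored at `1/n_reps`.
#'
#' @param a,b numeric samples (>= 2 values, no NAs counted).
#' @param n_reps bootstrap replicates (default 5000).
#' @param seed RNG seed.
#' @param units label for reporting (e.g. `"nt"`, `"aa"`).
#' @return a `bootstrap_estimate`: estimate, `ci` (lo, hi), `p`, `n_reps`,
#'   `seed`, `units`.
#' @export
bootstrap_mean_difference <- function(a, b, n_reps = 5000, seed = 1,
                                      units = "nt") {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("bootstrap_mean_difference() needs >= 2 values per sample")
  }
  est <- mean(a) - mean(b)
  boot <- with_seed(seed, {
    boot_means(a, n_reps) - boot_means(b, n_reps)
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  p <- if (est == 0) 1 else {
    max(1 / n_reps, min(1, 2 * mean(sign(boot) != sign(est))))
  }
  structure(
    list(estimate = est, ci = ci, p = p, n_reps = n_reps, seed = seed,
         units = units, n_a = length(a), n_b = length(b)),
    class = "bootstrap_estimate"
  )
}

# bootstrap distribution of the sample mean, chunked to bound memory
boot_means <- function(x, B) {
  n <- length(x)
  out <- numeric(B)
  chunk <- max(1L, floor(5e6 / n))
  done <- 0L
  while (done < B) {
    k <- min(chunk, B - done)
    m <- matrix(sample(x, n * k, replace = TRUE), nrow = n)
    out[(done + 1):(done + k)] <- colMeans(m)
    done <- done + k
  }
  out
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("<bootstrap_estimate> %.3f %s (95%% CI %.3f, %.3f; p %s)\n",
              x$estimate, x$units, x$ci[1], x$ci[2],
              format.pval(x$p, eps = 1 / x$n_reps)))
  invisible(x)
}

#' Decompose a CDRH3 length difference into five junction factors
#'
#' Pools heavy-chain sequences per group and, for each of the five CDR3
#' length components (germline V tail, VD insertions, aligned D segment, DJ
#' insertions, germline J head), bootstraps the group mean difference in
#' nucleotides; the total CDR3 length difference is also bootstrapped in
#' amino acids. Positive estimates mean the component is longer in group A.
#'
#' @param group_a,group_b lists of [repertoire] objects (or single
#'   repertoires).
#' @param n_reps bootstrap replicates per factor.
#' @param seed master seed; each factor draws from a derived child seed.
#' @param exclude_no_d drop records without a D call from the factor
#'   samples instead of counting them as `d_align = 0` with a combined
#'   insertion.
#' @return list with one `bootstrap_estimate` per factor (`v_cdr3_nt`,
#'   `np1`, `d_align`, `np2`, `j_cdr3_nt`), the `total_aa` estimate, and a
#'   tidy `summary` tibble.
#' @export
decompose_length_difference <- function(group_a, group_b, n_reps = 5000,
                                        seed = 1, exclude_no_d = FALSE) {
  pool <- function(group) {
    if (is_repertoire(group)) group <- list(group)
    an <- dplyr::bind_rows(lapply(group, junction_anatomy))
    if (exclude_no_d) an <- an[!an$no_d, , drop = FALSE]
    an
  }
  an_a <- pool(group_a)
  an_b <- pool(group_b)
  factors <- c("v_cdr3_nt", "np1", "d_align", "np2", "j_cdr3_nt")
  seeds <- derive_seeds(seed, length(factors) + 1L)
  out <- list()
  for (k in seq_along(factors)) {
    f <- factors[k]
    if (mean(is.na(an_a[[f]])) > 0.5 || mean(is.na(an_b[[f]])) > 0.5) {
      warn(sprintf("factor %s missing in >50%% of a group; skipped", f))
      next
    }
    out[[f]] <- bootstrap_mean_difference(an_a[[f]], an_b[[f]],
                                          n_reps = n_reps, seed = seeds[k],
                                          units = "nt")
  }
  out$total_aa <- bootstrap_mean_difference(
    an_a$cdr3_nt_length / 3, an_b$cdr3_nt_length / 3,
    n_reps = n_reps, seed = seeds[length(seeds)], units = "aa"
  )
  out$summary <- dplyr::bind_rows(lapply(
    names(out)[vapply(out, inherits, TRUE, "bootstrap_estimate")],
    function(nm) {
      e <- out[[nm]]
      tibble::tibble(factor = nm, estimate = e$estimate, ci_lo = e$ci[1],
                     ci_hi = e$ci[2], p = e$p, units = e$units)
    }
  ))
  out
}

#' Zero-insertion fractions of a repertoire
#'
#' @param rep a [repertoire].
#' @return named numeric: fraction of heavy-chain records with no VD
#'   insertion, no DJ insertion, and neither.
#' @export
zero_insertion_fractions <- function(rep) {
  an <- junction_anatomy(rep)
  an <- an[!is.na(an$np1) & !is.na(an$np2), , drop = FALSE]
  c(
    vd_zero = mean(an$np1 == 0),
    dj_zero = mean(an$np2 == 0),
    both_zero = mean(an$np1 == 0 & an$np2 == 0)
  )
}
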