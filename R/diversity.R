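# Shannon diversity of CDRH3 and clonotype abundance distributions.

#' Shannon entropy of an abundance distribution
#'
#' H = -sum(p_i * ln(p_i)) in natural-log units (nats), with 0 * ln(0) = 0.
#' Counts are normalised to proportions first.
#'
#' @param abundances non-negative counts or proportions with at least one
#'   positive entry.
#' @return Shannon entropy in nats; 0 <= H <= ln(number of categories).
#' @examples
#' shannon_entropy(rep(1, 4)) # ln(4)
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.0397
#' @export
shannon_entropy <- function(abundances) {
  if (length(abundances) == 0 || any(abundances < 0) ||
      sum(abundances) <= 0) {
    abort("shannon_entropy() needs non-negative abundances, not all zero")
  }
  p <- abundances / sum(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}

# per-unit abundance counts over heavy-chain records: for "cdrh3" the number
# of records per distinct CDR3 string; for "clonotype" the clone sizes
unit_abundances <- function(rep, unit = c("cdrh3", "clonotype"),
                            assignment = NULL) {
  unit <- match.arg(unit)
  h <- heavy_records(rep)
  h <- h[!is.na(h$junction_aa) & nchar(h$junction_aa) >= 3, , drop = FALSE]
  if (nrow(h) == 0) {
    abort("no heavy-chain records with a CDR3",
          class = "bcrcompare_empty_result_error")
  }
  if (unit == "cdrh3") {
    cdr3 <- cdr3_aa(h$junction_aa)
    tibble::tibble(unit_id = cdr3, cdr3_aa_length = nchar(cdr3)) |>
      dplyr::count(.data$unit_id, .data$cdr3_aa_length, name = "abundance")
  } else {
    assignment <- assignment %||% assign_clonotypes(rep)
    dplyr::transmute(assignment$clones,
                     unit_id = as.character(.data$clone_id),
                     cdr3_aa_length = .data$cdr3_aa_length,
                     abundance = .data$size)
  }
}

#' Shannon diversity of a repertoire
#'
#' Entropy of the CDRH3 (or clonotype) abundance distribution over
#' heavy-chain records.
#'
#' @param rep a [repertoire].
#' @param unit `"cdrh3"` or `"clonotype"`.
#' @return Shannon entropy in nats.
#' @export
repertoire_diversity <- function(rep, unit = c("cdrh3", "clonotype")) {
  ab <- unit_abundances(rep, unit)
  shannon_entropy(ab$abundance)
}

#' Per-CDRH3-length Shannon diversity profile
#'
#' Entropy of the unit-abundance distribution within each CDR3 amino-acid
#' length stratum. Strata containing fewer than 2 units have H = 0 and are
#' flagged `degenerate`.
#'
#' @param rep a [repertoire].
#' @param unit `"cdrh3"` or `"clonotype"`.
#' @return tibble with `cdr3_aa_length`, `n_units`, `H` and `degenerate`.
#' @export
per_length_diversity <- function(rep, unit = c("cdrh3", "clonotype")) {
  ab <- unit_abundances(rep, unit)
  ab |>
    dplyr::group_by(.data$cdr3_aa_length) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      H = if (dplyr::n() < 2) 0 else shannon_entropy(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = .data$n_units < 2) |>
    dplyr::arrange(.data$cdr3_aa_length)
}

#' Unique units per sequence sampled
#'
#' Ratio of the number of distinct CDRH3s (or clonotypes) to the number of
#' heavy-chain sequences -- a depth-normalised richness measure.
#'
#' @param rep a [repertoire].
#' @param unit `"cdrh3"` or `"clonotype"`.
#' @return a value in (0, 1].
#' @export
unique_per_sequence_ratio <- function(rep, unit = c("cdrh3", "clonotype")) {
  ab <- unit_abundances(rep, unit)
  nrow(ab) / sum(ab$abundance)
}
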