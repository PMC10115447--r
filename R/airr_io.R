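#' Parse an immunoglobulin gene call
#'
#' Splits a gene/allele designation such as `"IGHV3-23*01"` into locus,
#' segment, subgroup (gene family), gene and allele. Multi-gene ambiguous
#' calls (comma-separated) keep the first listed call with `ambiguous = TRUE`.
#'
#' @param call_string gene call text beginning `IGH`, `IGK` or `IGL`.
#' @return list with elements `locus`, `segment`, `subgroup`, `gene`,
#'   `allele` (`NA` when absent) and `ambiguous`.
#' @examples
#' parse_gene_call("IGHV3-23*01")
#' parse_gene_call("IGKV1-39")
#' @export
parse_gene_call <- function(call_string) {
  if (length(call_string) != 1 || is.na(call_string) ||
      !nzchar(call_string)) {
    abort("parse_gene_call() expects a single non-empty string",
          class = "bcrcompare_parse_error")
  }
  parts <- strsplit(call_string, ",", fixed = TRUE)[[1]]
  first <- trimws(parts[[1]])
  m <- regexec("^(IG[HKL])([VDJ])([0-9]+)", first)
  groups <- regmatches(first, m)[[1]]
  if (length(groups) == 0) {
    abort(paste0("unparseable gene call: ", call_string),
          class = "bcrcompare_parse_error")
  }
  allele_split <- strsplit(first, "*", fixed = TRUE)[[1]]
  list(
    locus = groups[2],
    segment = groups[3],
    subgroup = paste0(groups[2], groups[3], groups[4]),
    gene = allele_split[1],
    allele = if (length(allele_split) > 1) allele_split[2] else NA_character_,
    ambiguous = length(parts) > 1
  )
}

# vectorised helpers used throughout; alleles are stripped before any
# frequency computation
strip_allele <- function(calls) {
  first <- sub(",.*$", "", calls)
  sub("\\*.*$", "", trimws(first))
}

call_subgroup <- function(calls) {
  genes <- strip_allele(calls)
  m <- regexpr("^IG[HKL][VDJ][0-9]+", genes)
  out <- rep(NA_character_, length(genes))
  ok <- m > 0
  out[ok] <- regmatches(genes, m)
  out
}

call_is_ambiguous <- function(calls) grepl(",", calls, fixed = TRUE)

#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Reads a tab-separated AIRR Rearrangement table. Rows with missing
#' `junction_aa` or an unparseable `v_call`/`j_call` are dropped with a
#' logged count (see `attr(, "dropped")`). Multi-gene ambiguous calls keep
#' the first listed call and set `v_ambiguous`/`j_ambiguous`.
#'
#' @param path path to a TSV file with a header row containing at least
#'   `sequence_id`, `v_call`, `j_call` and `junction_aa`.
#' @param species species label for the repertoire.
#' @param subject_id subject label; defaults to the file name.
#' @return a [repertoire], with attribute `dropped` giving the number of
#'   malformed rows removed.
#' @export
read_rearrangements <- function(path, species = "other", subject_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "bcrcompare_io_error")
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tab) == 0) {
    abort(paste0("empty AIRR file: ", path),
          class = "bcrcompare_empty_input_error")
  }
  required <- c("sequence_id", "v_call", "j_call", "junction_aa")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "AIRR file ", path, " lacks mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "bcrcompare_format_error")
  }
  int_cols <- intersect(
    c("np1_length", "np2_length", "v_cdr3_nt", "d_align_nt", "j_cdr3_nt",
      "mutation_count", "duplicate_count", "cdr3_aa_length",
      "v_sequence_end", "d_sequence_start", "d_sequence_end",
      "j_sequence_start"),
    names(tab)
  )
  for (cc in int_cols) tab[[cc]] <- suppressWarnings(as.integer(tab[[cc]]))

  ok <- !is.na(tab$junction_aa) & nzchar(tab$junction_aa) &
    !is.na(call_subgroup(tab$v_call)) & !is.na(call_subgroup(tab$j_call))
  dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0) {
    abort(paste0("no well-formed records in ", path),
          class = "bcrcompare_empty_input_error")
  }
  tab$v_ambiguous <- call_is_ambiguous(tab$v_call)
  tab$j_ambiguous <- call_is_ambiguous(tab$j_call)
  tab$v_call <- sub(",.*$", "", tab$v_call)
  tab$j_call <- sub(",.*$", "", tab$j_call)
  if ("d_call" %in% names(tab)) tab$d_call <- sub(",.*$", "", tab$d_call)
  tab$cdr3_aa_length <- pmax(nchar(tab$junction_aa) - 2L, 0L)
  if (!"duplicate_count" %in% names(tab) ||
      all(is.na(tab$duplicate_count))) {
    tab$duplicate_count <- 1L
  }
  rep <- repertoire(tab, subject_id %||% basename(path), species,
                    provenance = paste0("read from ", basename(path)))
  if (dropped > 0) {
    inform(sprintf("read_rearrangements: dropped %d malformed row(s)",
                   dropped))
  }
  attr(rep, "dropped") <- dropped
  rep
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' @param rep a [repertoire].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rep, path) {
  stopifnot(is_repertoire(rep))
  readr::write_tsv(rep$records, path, progress = FALSE)
  invisible(path)
}

#' Restrict a repertoire to naive sequences
#'
#' The naive compartment is operationalised as IgM sequences with zero
#' nucleotide mutations from germline. Record order is preserved.
#'
#' @param rep a [repertoire] whose records carry `isotype` and
#'   `mutation_count`.
#' @return the filtered [repertoire]; errors (with per-reason counts in the
#'   message) if nothing survives.
#' @export
filter_naive <- function(rep) {
  stopifnot(is_repertoire(rep))
  rec <- rep$records
  if (!all(c("isotype", "mutation_count") %in% names(rec))) {
    abort("filter_naive() needs populated isotype and mutation_count columns",
          class = "bcrcompare_format_error")
  }
  is_igm <- toupper(rec$isotype) %in% c("IGM", "IGHM")
  is_unmutated <- !is.na(rec$mutation_count) & rec$mutation_count == 0L
  keep <- is_igm & is_unmutated
  if (!any(keep)) {
    abort(sprintf(
      "filter_naive(): no records retained (%d non-IgM, %d mutated)",
      sum(!is_igm), sum(is_igm & !is_unmutated)
    ), class = "bcrcompare_empty_result_error")
  }
  set_records(rep, rec[keep, , drop = FALSE],
              note = sprintf("naive filter kept %d/%d", sum(keep), nrow(rec)))
}

#' Collapse a repertoire to unique nucleotide sequences
#'
#' Deduplicates on the full available nucleotide sequence (`sequence` if
#' present, else `junction`), accumulating copies into `duplicate_count`.
#' Total duplicate-count mass is conserved.
#'
#' @param rep a [repertoire].
#' @return the collapsed [repertoire].
#' @export
collapse_unique <- function(rep) {
  stopifnot(is_repertoire(rep))
  rec <- rep$records
  key_col <- if ("sequence" %in% names(rec)) "sequence" else "junction"
  if (!key_col %in% names(rec)) {
    abort("collapse_unique() needs a nucleotide sequence column",
          class = "bcrcompare_format_error")
  }
  # keep the first record per unique sequence; sum copies
  key <- rec[[key_col]]
  first_idx <- !duplicated(key)
  totals <- tapply(rec$duplicate_count, key, sum)
  out <- rec[first_idx, , drop = FALSE]
  out$duplicate_count <- as.integer(totals[out[[key_col]]])
  set_records(rep, out,
              note = sprintf("collapsed %d reads to %d unique sequences",
                             nrow(rec), nrow(out)))
}
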