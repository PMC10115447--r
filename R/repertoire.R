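#' Construct a repertoire object
#'
#' A repertoire is a subject-labelled collection of annotated V(D)J
#' rearrangement records. Records are held as a tibble whose columns follow
#' AIRR Rearrangement naming (`sequence_id`, `v_call`, `d_call`, `j_call`,
#' `junction`, `junction_aa`, `np1_length`, `np2_length`, `duplicate_count`,
#' ...) plus the derived `cdr3_aa_length` (= `nchar(junction_aa) - 2`, the
#' IMGT CDR3 without the two anchor residues).
#'
#' @param records tibble/data.frame of rearrangement records. Must contain at
#'   least `sequence_id`, `v_call`, `j_call` and `junction_aa`.
#' @param subject_id subject label, unique within a study set.
#' @param species one of `"human"`, `"mouse"`, `"kymouse"` or `"other"`.
#' @param provenance free-text note on where the records came from.
#' @return an object of class `repertoire`.
#' @export
repertoire <- function(records, subject_id, species = "other",
                       provenance = "") {
  records <- tibble::as_tibble(records)
  required <- c("sequence_id", "v_call", "j_call", "junction_aa")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "repertoire records are missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "bcrcompare_format_error")
  }
  if (!"locus" %in% names(records)) {
    records$locus <- substr(records$v_call, 1, 3)
  }
  if (!"duplicate_count" %in% names(records)) {
    records$duplicate_count <- 1L
  }
  if (!"cdr3_aa_length" %in% names(records)) {
    records$cdr3_aa_length <- pmax(nchar(records$junction_aa) - 2L, 0L)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      species = match.arg(species, c("human", "mouse", "kymouse", "other")),
      records = records,
      provenance = provenance
    ),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire> subject %s (%s): %d records (%d heavy, %d light)\n",
    x$subject_id, x$species, nrow(x$records),
    sum(x$records$locus == "IGH"), sum(x$records$locus != "IGH")
  ))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.repertoire <- function(x) nrow(x$records)

is_repertoire <- function(x) inherits(x, "repertoire")

# replace records, preserving metadata
set_records <- function(rep, records, note = NULL) {
  rep$records <- tibble::as_tibble(records)
  if (!is.null(note)) {
    rep$provenance <- paste0(
      rep$provenance,
      if (nzchar(rep$provenance)) "; ",
      note
    )
  }
  rep
}

#' Heavy-chain records of a repertoire
#'
#' @param rep a `repertoire`.
#' @return tibble of records with locus `IGH`.
#' @export
heavy_records <- function(rep) {
  stopifnot(is_repertoire(rep))
  dplyr::filter(rep$records, .data$locus == "IGH")
}

#' Light-chain records of a repertoire
#'
#' @param rep a `repertoire`.
#' @return tibble of records with locus `IGK` or `IGL`.
#' @export
light_records <- function(rep) {
  stopifnot(is_repertoire(rep))
  dplyr::filter(rep$records, .data$locus %in% c("IGK", "IGL"))
}
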