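#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats setNames
NULL

# pairwise Hamming identity between equal-length amino-acid strings;
# returns fraction of matching positions
aa_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("aa_identity() requires equal-length strings")
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av == bv)
}

# translate a vector of in-frame nucleotide strings to amino acids
translate_nt <- function(nt) {
  if (length(nt) == 0) return(character(0))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    if.fuzzy.codon = "X"
  ))
}

# local RNG scope: run code under a seed without disturbing the caller's
# random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one master seed (keeps values < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
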