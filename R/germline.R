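# Bundled synthetic germline gene tables for the V(D)J simulator.
#
# Gene labels follow real IGHV/IGHD/IGHJ (and light-chain) nomenclature so
# that parsing and usage-profiling code paths are exercised, but the
# nucleotide strings are synthetic: each gene's CDR3-facing sequence is a
# deterministic pseudo-random string derived from the gene name, not an IMGT
# download. D-gene lengths and J CDR3 contributions are chosen so that
# simulated CDRH3 length distributions land near the printed species means.

# deterministic nucleotide string from a gene name (stable across sessions)
synth_nt <- function(name, len) {
  seed <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L + 7L
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

# heavy-chain V genes: `cdr3_nt` is the germline tail available to the CDR3
# (up to 9 nt used). `weight` is the within-subgroup usage split.
germline_heavy_v <- function(species) {
  if (species %in% c("human", "kymouse")) {
    genes <- tibble::tribble(
      ~gene,        ~subgroup, ~weight,
      "IGHV1-2",    "IGHV1",   0.5,
      "IGHV1-69",   "IGHV1",   0.5,
      "IGHV2-5",    "IGHV2",   1.0,
      "IGHV3-23",   "IGHV3",   0.4,
      "IGHV3-30",   "IGHV3",   0.3,
      "IGHV3-7",    "IGHV3",   0.3,
      "IGHV4-34",   "IGHV4",   0.5,
      "IGHV4-59",   "IGHV4",   0.5,
      "IGHV5-51",   "IGHV5",   1.0,
      "IGHV6-1",    "IGHV6",   1.0,
      "IGHV7-4-1",  "IGHV7",   1.0
    )
  } else {
    genes <- tibble::tribble(
      ~gene,        ~subgroup, ~weight,
      "IGHV1-72",   "IGHV1",   0.6,
      "IGHV1-53",   "IGHV1",   0.4,
      "IGHV2-2",    "IGHV2",   1.0,
      "IGHV3-6",    "IGHV3",   1.0,
      "IGHV5-9",    "IGHV5",   1.0,
      "IGHV6-3",    "IGHV6",   1.0,
      "IGHV8-8",    "IGHV8",   1.0,
      "IGHV14-3",   "IGHV14",  1.0
    )
  }
  genes$cdr3_nt <- vapply(genes$gene, synth_nt, "", len = 9L)
  genes
}

# heavy-chain D genes with full synthetic gene length (nt)
germline_heavy_d <- function(species) {
  if (species %in% c("human", "kymouse")) {
    genes <- tibble::tribble(
      ~gene,       ~subgroup, ~weight, ~len,
      "IGHD1-26",  "IGHD1",   1.0,     19L,
      "IGHD2-2",   "IGHD2",   0.5,     30L,
      "IGHD2-15",  "IGHD2",   0.5,     30L,
      "IGHD3-10",  "IGHD3",   0.5,     30L,
      "IGHD3-22",  "IGHD3",   0.5,     28L,
      "IGHD4-17",  "IGHD4",   1.0,     16L,
      "IGHD5-12",  "IGHD5",   1.0,     22L,
      "IGHD6-19",  "IGHD6",   1.0,     20L,
      "IGHD7-27",  "IGHD7",   1.0,     11L
    )
  } else {
    genes <- tibble::tribble(
      ~gene,      ~subgroup, ~weight, ~len,
      "IGHD1-1",  "IGHD1",   1.0,     19L,
      "IGHD2-3",  "IGHD2",   0.5,     18L,
      "IGHD2-4",  "IGHD2",   0.5,     17L,
      "IGHD3-1",  "IGHD3",   1.0,     13L,
      "IGHD4-1",  "IGHD4",   1.0,     11L
    )
  }
  genes$nt <- mapply(synth_nt, genes$gene, genes$len)
  genes
}

# heavy-chain J genes: `cdr3_nt` is the germline CDR3 prefix the gene
# contributes (before the conserved Trp anchor)
germline_heavy_j <- function(species) {
  if (species %in% c("human", "kymouse")) {
    genes <- tibble::tribble(
      ~gene,    ~subgroup, ~weight, ~contrib,
      "IGHJ1",  "IGHJ1",   1.0,     14L,
      "IGHJ2",  "IGHJ2",   1.0,     15L,
      "IGHJ3",  "IGHJ3",   1.0,     14L,
      "IGHJ4",  "IGHJ4",   1.0,     13L,
      "IGHJ5",  "IGHJ5",   1.0,     14L,
      "IGHJ6",  "IGHJ6",   1.0,     20L
    )
  } else {
    genes <- tibble::tribble(
      ~gene,    ~subgroup, ~weight, ~contrib,
      "IGHJ1",  "IGHJ1",   1.0,     15L,
      "IGHJ2",  "IGHJ2",   1.0,     16L,
      "IGHJ3",  "IGHJ3",   1.0,     15L,
      "IGHJ4",  "IGHJ4",   1.0,     17L
    )
  }
  genes$cdr3_nt <- mapply(synth_nt, genes$gene, genes$contrib)
  genes
}

# light-chain V genes (kappa and lambda); `cdr3_nt` holds up to 21 nt of
# germline CDR3 tail (light CDR3s are mostly germline-encoded)
germline_light_v <- function(species) {
  if (species %in% c("human", "kymouse")) {
    genes <- tibble::tribble(
      ~gene,       ~subgroup, ~weight,
      "IGKV1-39",  "IGKV1",   0.5,
      "IGKV1-5",   "IGKV1",   0.5,
      "IGKV2-28",  "IGKV2",   1.0,
      "IGKV3-20",  "IGKV3",   0.6,
      "IGKV3-15",  "IGKV3",   0.4,
      "IGKV4-1",   "IGKV4",   1.0,
      "IGKV5-2",   "IGKV5",   1.0,
      "IGKV6-21",  "IGKV6",   1.0,
      "IGLV1-44",  "IGLV1",   0.5,
      "IGLV1-51",  "IGLV1",   0.5,
      "IGLV2-14",  "IGLV2",   1.0,
      "IGLV3-21",  "IGLV3",   0.6,
      "IGLV3-1",   "IGLV3",   0.4,
      "IGLV4-69",  "IGLV4",   1.0,
      "IGLV5-45",  "IGLV5",   1.0,
      "IGLV6-57",  "IGLV6",   1.0,
      "IGLV7-43",  "IGLV7",   1.0,
      "IGLV8-61",  "IGLV8",   1.0,
      "IGLV9-49",  "IGLV9",   1.0
    )
  } else {
    genes <- tibble::tribble(
      ~gene,       ~subgroup, ~weight,
      "IGKV1-117", "IGKV1",   1.0,
      "IGKV3-4",   "IGKV3",   1.0,
      "IGKV4-55",  "IGKV4",   1.0,
      "IGKV6-15",  "IGKV6",   1.0,
      "IGKV8-21",  "IGKV8",   1.0,
      "IGLV1-1",   "IGLV1",   1.0,
      "IGLV2-3",   "IGLV2",   1.0
    )
  }
  genes$locus <- substr(genes$gene, 1, 3)
  genes$cdr3_nt <- vapply(genes$gene, synth_nt, "", len = 21L)
  genes
}

germline_light_j <- function(species) {
  if (species %in% c("human", "kymouse")) {
    genes <- tibble::tribble(
      ~gene,    ~subgroup, ~weight, ~contrib,
      "IGKJ1",  "IGKJ1",   1.0,     8L,
      "IGKJ2",  "IGKJ2",   1.0,     8L,
      "IGKJ3",  "IGKJ3",   1.0,     8L,
      "IGKJ4",  "IGKJ4",   1.0,     8L,
      "IGKJ5",  "IGKJ5",   1.0,     8L,
      "IGLJ1",  "IGLJ1",   1.0,     9L,
      "IGLJ2",  "IGLJ2",   1.0,     9L,
      "IGLJ3",  "IGLJ3",   1.0,     9L,
      "IGLJ7",  "IGLJ7",   1.0,     9L
    )
  } else {
    genes <- tibble::tribble(
      ~gene,    ~subgroup, ~weight, ~contrib,
      "IGKJ1",  "IGKJ1",   1.0,     8L,
      "IGKJ2",  "IGKJ2",   1.0,     8L,
      "IGKJ4",  "IGKJ4",   1.0,     8L,
      "IGKJ5",  "IGKJ5",   1.0,     8L,
      "IGLJ1",  "IGLJ1",   1.0,     9L
    )
  }
  genes$locus <- substr(genes$gene, 1, 3)
  genes$cdr3_nt <- mapply(synth_nt, genes$gene, genes$contrib)
  genes
}

# expand subgroup-level usage to gene-level probabilities using the
# within-subgroup weights of a germline table
gene_usage_from_subgroups <- function(genes, subgroup_usage) {
  stopifnot(abs(sum(subgroup_usage) - 1) < 1e-9)
  missing_sub <- setdiff(names(subgroup_usage), genes$subgroup)
  if (length(missing_sub) > 0) {
    abort(paste0("no germline genes for subgroup(s): ",
                 paste(missing_sub, collapse = ", ")))
  }
  w <- genes$weight
  split_w <- tapply(w, genes$subgroup, sum)
  p <- subgroup_usage[genes$subgroup] * w / split_w[genes$subgroup]
  p[is.na(p)] <- 0
  setNames(as.numeric(p / sum(p)), genes$gene)
}
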