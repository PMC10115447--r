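# Shared fixtures, built in code. Expensive simulations are cached for the
# duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one fixed codon per amino acid, so distinct CDR3s get distinct junctions
.codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(cdr3) {
  paste0("TGT",
         paste(.codon[strsplit(cdr3, "")[[1]]], collapse = ""),
         "TGG")
}

# tiny hand-built heavy-chain repertoire from CDR3 amino-acid strings
toy_repertoire <- function(cdr3, v = "IGHV3-23*01", j = "IGHJ4*01",
                           subject = "toy", d = "IGHD3-22*01",
                           isotype = "IGM", mutation_count = 0L) {
  n <- length(cdr3)
  repertoire(tibble::tibble(
    sequence_id = sprintf("%s_%03d", subject, seq_len(n)),
    locus = "IGH",
    isotype = rep_len(isotype, n),
    v_call = rep_len(v, n),
    d_call = rep_len(d, n),
    j_call = rep_len(j, n),
    junction = vapply(cdr3, reverse_translate, ""),
    junction_aa = paste0("C", cdr3, "W"),
    mutation_count = rep_len(mutation_count, n),
    duplicate_count = 1L
  ), subject_id = subject)
}

# 20,000-read heavy-chain simulations used for parameter recovery
sim_human_20k <- function() {
  cached("human20k", simulate_repertoire(
    simulation_config("human", 1, 20000, seed = 101, chains = "heavy")
  )[[1]])
}
sim_kymouse_20k <- function() {
  cached("kymouse20k", simulate_repertoire(
    simulation_config("kymouse", 1, 20000, seed = 102, chains = "heavy")
  )[[1]])
}

# small multi-subject studies for separability / decomposition
sim_study <- function(species, n_subjects = 4, n = 1200, seed = 11) {
  cached(paste0("study_", species, n_subjects, "_", n, "_", seed),
         simulate_repertoire(simulation_config(
           species, n_subjects, n, seed = seed, chains = "heavy"
         )))
}

# light-chain simulation for kappa/lambda recovery
sim_light <- function(species, seed) {
  cached(paste0("light_", species, "_", seed), simulate_repertoire(
    simulation_config(species, 1, 10000, seed = seed, chains = "light")
  )[[1]])
}

# structural annotation scenario (synthetic structural-cluster inputs)
sim_annotations <- function() {
  cached("annotations", simulate_annotation_table(
    c(human = 6, kymouse = 4, mouse = 4), n_per_subject = 300, seed = 5
  ))
}

# deeper annotation table for length-balanced subsampling
sim_annotations_deep <- function() {
  cached("annotations_deep", simulate_annotation_table(
    c(human = 6, kymouse = 4, mouse = 4), n_per_subject = 1500, seed = 5
  ))
}

# independent oracle: clonotype partition by brute-force transitive closure
oracle_clonotypes <- function(records, threshold = 0.90) {
  v <- sub("\\*.*$", "", records$v_call)
  j <- sub("\\*.*$", "", records$j_call)
  cdr3 <- substr(records$junction_aa, 2, nchar(records$junction_aa) - 1)
  n <- nrow(records)
  ident <- function(a, b) {
    if (nchar(a) != nchar(b)) return(0)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    mean(av == bv)
  }
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      linked[i, k] <- v[i] == v[k] && j[i] == j[k] &&
        nchar(cdr3[i]) == nchar(cdr3[k]) &&
        ident(cdr3[i], cdr3[k]) >= threshold - 1e-12
    }
  }
  # transitive closure to a fixpoint
  repeat {
    nxt <- linked | (linked %*% linked > 0)
    if (identical(nxt, linked)) break
    linked <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[linked[i, ]] <- cid
    }
  }
  comp
}
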