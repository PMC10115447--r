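# Seeded V(D)J recombination simulator.
#
# Heavy-chain junctions are assembled as
#   TGT | V tail | N1 | trimmed D | N2 | J head | TGG
# so that the conservation identity
#   cdr3_nt_length = v_cdr3_nt + np1 + d_align + np2 + j_cdr3_nt
# holds exactly for every record. In-frame totals are guaranteed by drawing
# the V-tail contribution from the residue class that completes the frame
# (the support 1..9 nt has all three residues equally represented, so the
# marginal V contribution stays uniform and the insertion/trimming draws are
# untouched by the frame constraint). Stop codons are removed by redrawing
# the non-templated nucleotides; a stop spanning only germline-encoded
# codons, which no redraw can touch, is repaired by a deterministic
# third-base substitution (TAA/TAG -> TAT, TGA -> TGG).

# zero-inflated insertion lengths: zero with probability `zero_prob`,
# otherwise a shifted geometric on {1, 2, ...} with the positive-part mean
# implied by the overall mean
rzinsert <- function(n, ins) {
  pos_mean <- insertion_pos_mean(ins)
  out <- integer(n)
  nonzero <- stats::runif(n) >= ins$zero_prob
  k <- sum(nonzero)
  if (k > 0) {
    out[nonzero] <- 1L + stats::rgeom(k, prob = 1 / pos_mean)
  }
  out
}

# vector of random nucleotide strings with the given lengths
random_nt <- function(lens) {
  out <- character(length(lens))
  total <- sum(lens)
  if (total == 0) return(out)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  idx <- rep.int(seq_along(lens), lens)
  sp <- split(chars, idx)
  out[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = "")
  out
}

# draw a value from `support` (9 consecutive integers) in the residue class
# that makes `rest + value` divisible by 3; uniform over the 3 candidates
draw_frame_completing <- function(rest, support) {
  lo <- min(support)
  offset <- (3 - rest %% 3) %% 3
  base <- lo + ((offset - lo) %% 3)
  base + 3L * sample(0:2, length(rest), replace = TRUE)
}

fix_stop_codons <- function(nt) {
  vapply(nt, function(s) {
    starts <- seq(1, nchar(s), 3)
    codons <- substring(s, starts, starts + 2)
    codons[codons %in% c("TAA", "TAG")] <- "TAT"
    codons[codons == "TGA"] <- "TGG"
    paste(codons, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Sample junction anatomies and sequences from a species preset
#'
#' Draws `n` junctions (gene choices, insertion lengths, trimming, assembled
#' nucleotide and translated amino-acid sequence) from a preset's generative
#' model. Randomness comes from the caller's RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param preset a [species_preset].
#' @param n number of junctions.
#' @param chain `"heavy"` or `"light"`.
#' @param usage optional list of jittered usage distributions overriding the
#'   preset's (fields as in `preset$heavy` / `preset$light`).
#' @param max_tries redraw budget for removing stop codons from the
#'   non-templated insertions.
#' @return tibble with gene calls, junction anatomy fields (`np1_length`,
#'   `np2_length`, `v_cdr3_nt`, `d_align_nt`, `j_cdr3_nt`), `junction`,
#'   `junction_aa` and `cdr3_aa_length`.
#' @export
sample_junctions <- function(preset, n, chain = c("heavy", "light"),
                             usage = NULL, max_tries = 1000) {
  stopifnot(inherits(preset, "species_preset"), n >= 1)
  chain <- match.arg(chain)
  if (chain == "heavy") {
    sample_heavy_junctions(preset, n, usage %||% preset$heavy, max_tries)
  } else {
    sample_light_junctions(preset, n, usage %||% preset$light, max_tries)
  }
}

sample_heavy_junctions <- function(preset, n, usage, max_tries) {
  sp <- preset$germline_species
  v_tab <- germline_heavy_v(sp)
  d_tab <- germline_heavy_d(sp)
  j_tab <- germline_heavy_j(sp)
  v_probs <- gene_usage_from_subgroups(v_tab, usage$v_usage)
  d_probs <- gene_usage_from_subgroups(d_tab, usage$d_usage)
  j_probs <- gene_usage_from_subgroups(j_tab, usage$j_usage)

  vg <- sample(names(v_probs), n, replace = TRUE, prob = v_probs)
  dg <- sample(names(d_probs), n, replace = TRUE, prob = d_probs)
  jg <- sample(names(j_probs), n, replace = TRUE, prob = j_probs)

  np1 <- rzinsert(n, preset$vd_insertion)
  np2 <- rzinsert(n, preset$dj_insertion)
  t1 <- sample(0:preset$trim_max, n, replace = TRUE)
  t2 <- sample(0:preset$trim_max, n, replace = TRUE)
  di <- match(dg, d_tab$gene)
  d_align <- pmax(d_tab$len[di] - t1 - t2, 0L)
  ji <- match(jg, j_tab$gene)
  j_contrib <- j_tab$contrib[ji]

  rest <- np1 + d_align + np2 + j_contrib
  v_contrib <- draw_frame_completing(rest, preset$v_contrib_support)

  vi <- match(vg, v_tab$gene)
  v_nt <- substr(v_tab$cdr3_nt[vi], 10L - v_contrib, 9L)
  d_nt <- substr(d_tab$nt[di], t1 + 1L, d_tab$len[di] - t2)
  j_nt <- j_tab$cdr3_nt[ji]
  n1 <- random_nt(np1)
  n2 <- random_nt(np2)

  assemble <- function(i) {
    paste0("TGT", v_nt[i], n1[i], d_nt[i], n2[i], j_nt[i], "TGG")
  }
  junction <- assemble(seq_len(n))
  aa <- translate_nt(junction)
  bad <- which(grepl("*", aa, fixed = TRUE))
  tries <- 0L
  while (length(bad) > 0 && tries < max_tries) {
    redraw <- bad[np1[bad] + np2[bad] > 0L]
    if (length(redraw) == 0) break
    n1[redraw] <- random_nt(np1[redraw])
    n2[redraw] <- random_nt(np2[redraw])
    junction[bad] <- assemble(bad)
    aa[bad] <- translate_nt(junction[bad])
    keep_bad <- grepl("*", aa[bad], fixed = TRUE)
    if (tries > 20L && all(keep_bad)) break  # stops not reachable by redraw
    bad <- bad[keep_bad]
    tries <- tries + 1L
  }
  if (length(bad) > 0) {
    junction[bad] <- fix_stop_codons(junction[bad])
    aa[bad] <- translate_nt(junction[bad])
  }
  tibble::tibble(
    locus = "IGH",
    v_call = paste0(vg, "*01"),
    d_call = paste0(dg, "*01"),
    j_call = paste0(jg, "*01"),
    junction = junction,
    junction_aa = aa,
    cdr3_aa_length = nchar(aa) - 2L,
    np1_length = np1,
    np2_length = np2,
    v_cdr3_nt = v_contrib,
    d_align_nt = d_align,
    j_cdr3_nt = j_contrib
  )
}

sample_light_junctions <- function(preset, n, usage, max_tries) {
  sp <- preset$germline_species
  v_tab <- germline_light_v(sp)
  j_tab <- germline_light_j(sp)
  is_kappa <- stats::runif(n) < usage$kappa_fraction
  locus <- ifelse(is_kappa, "IGK", "IGL")

  draw_genes <- function(tab, usage_k, usage_l) {
    out <- character(n)
    for (loc in c("IGK", "IGL")) {
      sel <- locus == loc
      if (!any(sel)) next
      sub <- tab[tab$locus == loc, , drop = FALSE]
      probs <- gene_usage_from_subgroups(
        sub, if (loc == "IGK") usage_k else usage_l
      )
      out[sel] <- sample(names(probs), sum(sel), replace = TRUE, prob = probs)
    }
    out
  }
  vg <- draw_genes(v_tab, usage$kv_usage, usage$lv_usage)
  jg <- draw_genes(j_tab, usage$kj_usage, usage$lj_usage)

  np <- rzinsert(n, preset$light_insertion)
  ji <- match(jg, j_tab$gene)
  j_contrib <- j_tab$contrib[ji]
  rest <- np + j_contrib
  v_contrib <- draw_frame_completing(rest, preset$light_v_contrib_support)

  vi <- match(vg, v_tab$gene)
  v_nt <- substr(v_tab$cdr3_nt[vi], 22L - v_contrib, 21L)
  j_nt <- j_tab$cdr3_nt[ji]
  n1 <- random_nt(np)

  assemble <- function(i) paste0("TGT", v_nt[i], n1[i], j_nt[i], "TTT")
  junction <- assemble(seq_len(n))
  aa <- translate_nt(junction)
  bad <- which(grepl("*", aa, fixed = TRUE))
  tries <- 0L
  while (length(bad) > 0 && tries < max_tries) {
    redraw <- bad[np[bad] > 0L]
    if (length(redraw) == 0) break
    n1[redraw] <- random_nt(np[redraw])
    junction[bad] <- assemble(bad)
    aa[bad] <- translate_nt(junction[bad])
    keep_bad <- grepl("*", aa[bad], fixed = TRUE)
    if (tries > 20L && all(keep_bad)) break
    bad <- bad[keep_bad]
    tries <- tries + 1L
  }
  if (length(bad) > 0) {
    junction[bad] <- fix_stop_codons(junction[bad])
    aa[bad] <- translate_nt(junction[bad])
  }
  tibble::tibble(
    locus = locus,
    v_call = paste0(vg, "*01"),
    d_call = NA_character_,
    j_call = paste0(jg, "*01"),
    junction = junction,
    junction_aa = aa,
    cdr3_aa_length = nchar(aa) - 2L,
    np1_length = np,
    np2_length = NA_integer_,
    v_cdr3_nt = v_contrib,
    d_align_nt = NA_integer_,
    j_cdr3_nt = j_contrib
  )
}

#' Simulation configuration
#'
#' @param preset preset name (`"human"`, `"mouse"`, `"kymouse"`) or a
#'   [species_preset] object.
#' @param n_subjects number of simulated subjects.
#' @param n_sequences reads emitted per subject and chain (before collapsing
#'   to unique sequences; the preset's clonal redundancy factor governs how
#'   many are duplicates).
#' @param seed integer fixing all randomness of the run.
#' @param concentration Dirichlet concentration for inter-subject usage
#'   jitter; larger means subjects resemble the preset more closely.
#' @param chains chains to simulate, a subset of `c("heavy", "light")`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(preset, n_subjects = 1L, n_sequences = 1000L,
                              seed = 1L, concentration = 500,
                              chains = c("heavy", "light")) {
  if (is.character(preset)) preset <- species_preset(preset)
  stopifnot(inherits(preset, "species_preset"),
            n_subjects >= 1, n_sequences >= 1, concentration > 0)
  chains <- match.arg(chains, several.ok = TRUE)
  structure(
    list(preset = preset, n_subjects = as.integer(n_subjects),
         n_sequences = as.integer(n_sequences), seed = as.integer(seed),
         concentration = concentration, chains = chains),
    class = "simulation_config"
  )
}

jitter_probs <- function(p, concentration) {
  g <- stats::rgamma(length(p), shape = concentration * p)
  if (sum(g) == 0) return(p)
  setNames(g / sum(g), names(p))
}

jitter_usage_heavy <- function(heavy, concentration) {
  list(
    v_usage = jitter_probs(heavy$v_usage, concentration),
    d_usage = jitter_probs(heavy$d_usage, concentration),
    j_usage = jitter_probs(heavy$j_usage, concentration)
  )
}

jitter_usage_light <- function(light, concentration) {
  kf <- light$kappa_fraction
  list(
    kappa_fraction = stats::rbeta(1, concentration * kf,
                                  concentration * (1 - kf)),
    kv_usage = jitter_probs(light$kv_usage, concentration),
    lv_usage = jitter_probs(light$lv_usage, concentration),
    kj_usage = jitter_probs(light$kj_usage, concentration),
    lj_usage = jitter_probs(light$lj_usage, concentration)
  )
}

# emit `n` reads over ~n/redundancy unique junction draws; extra copies are
# spread multinomially so some sequences are clonally expanded
expand_reads <- function(draws_fn, n, redundancy) {
  u <- max(1L, round(n / redundancy))
  unique_draws <- draws_fn(u)
  extra <- n - u
  copies <- rep(1L, u)
  if (extra > 0) {
    copies <- copies + as.integer(stats::rmultinom(1, extra, rep(1 / u, u)))
  }
  unique_draws[rep.int(seq_len(u), copies), , drop = FALSE]
}

#' Simulate a set of naive repertoires
#'
#' Produces `n_subjects` repertoires from a species preset. Per-subject gene
#' usage is drawn by Dirichlet jitter around the preset usage; reads carry
#' clonal redundancy (duplicate nucleotide sequences) per the preset's
#' redundancy factor. Fully deterministic given `config$seed`.
#'
#' @param config a [simulation_config].
#' @param out_dir optional directory; when given, one AIRR TSV per subject
#'   plus a `manifest.yaml` of the generating parameters is written.
#' @return named list of [repertoire] objects.
#' @export
simulate_repertoire <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  preset <- config$preset
  subject_seeds <- derive_seeds(config$seed, config$n_subjects)
  reps <- vector("list", config$n_subjects)
  names(reps) <- sprintf("%s_%02d", preset$name, seq_len(config$n_subjects))
  for (s in seq_len(config$n_subjects)) {
    reps[[s]] <- with_seed(subject_seeds[s], {
      parts <- list()
      if ("heavy" %in% config$chains) {
        hu <- jitter_usage_heavy(preset$heavy, config$concentration)
        parts$heavy <- expand_reads(
          function(k) sample_heavy_junctions(preset, k, hu, 1000),
          config$n_sequences, preset$redundancy
        )
      }
      if ("light" %in% config$chains) {
        lu <- jitter_usage_light(preset$light, config$concentration)
        parts$light <- expand_reads(
          function(k) sample_light_junctions(preset, k, lu, 1000),
          config$n_sequences, preset$redundancy
        )
      }
      rec <- dplyr::bind_rows(parts)
      rec$sequence_id <- sprintf("%s_seq%06d", names(reps)[s],
                                 seq_len(nrow(rec)))
      rec$sequence <- rec$junction
      rec$isotype <- "IGM"
      rec$mutation_count <- 0L
      rec$duplicate_count <- 1L
      repertoire(rec, subject_id = names(reps)[s], species = preset$name,
                 provenance = sprintf("simulated (seed %d)",
                                      subject_seeds[s]))
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reps)) {
      write_rearrangements(reps[[nm]], file.path(out_dir,
                                                 paste0(nm, ".tsv")))
    }
    manifest <- list(
      preset = unclass(preset)[c("name", "heavy", "light", "vd_insertion",
                                 "dj_insertion", "light_insertion",
                                 "trim_max", "redundancy")],
      n_subjects = config$n_subjects,
      n_sequences = config$n_sequences,
      seed = config$seed,
      concentration = config$concentration,
      chains = config$chains
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  reps
}
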