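# End-to-end orchestration: simulate -> filter -> analyse -> report.

#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' every paper-ambiguous convention surfaced as a named flag (overlap
#' denominator, clustering linkage, clonotype identity threshold). User
#' configs (lists or YAML files) are merged over these defaults.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 7L,
    out_dir = "pipeline_out",
    simulate = list(
      species = c("human", "kymouse", "mouse"),
      n_subjects = 3L,
      n_sequences = 2000L,
      chains = c("heavy", "light"),
      concentration = 500
    ),
    analyses = c("usage", "separability", "clones", "overlap", "diversity",
                 "decompose", "structural"),
    usage = list(segment = "V", level = "subgroup"),
    separability = list(subsample_n = 105L, n_repeats = 100L,
                        segment = "V", level = "gene", linkage = "average"),
    clonotype = list(identity = 0.90, linkage = "single"),
    overlap = list(unit = "cdrh3", convention = "mean"),
    decompose = list(group_a = "human", group_b = "kymouse",
                     n_reps = 1000L),
    structural = list(n_per_subject = 300L, bias = 4)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full comparison pipeline
#'
#' Simulates repertoires per species, applies the naive filter and unique
#' collapse, and executes the selected analysis stages in dependency order,
#' writing tidy TSV/JSON outputs plus a run log of seeds and record counts
#' to `out_dir`. Identical configurations produce identical outputs.
#'
#' @param config configuration list (merged over [default_run_config()]) or
#'   path to a YAML file holding one.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  log("bcrcompare pipeline, package version %s",
      as.character(utils::packageVersion("bcrcompare")))
  log("master seed: %d", cfg$seed)
  results <- list(config = cfg)
  stage_seeds <- derive_seeds(cfg$seed, 8)

  # --- simulate ----------------------------------------------------------
  species <- cfg$simulate$species
  sim_seeds <- derive_seeds(stage_seeds[1], length(species))
  reps_by_species <- list()
  for (i in seq_along(species)) {
    sc <- simulation_config(
      species[i],
      n_subjects = cfg$simulate$n_subjects,
      n_sequences = cfg$simulate$n_sequences,
      seed = sim_seeds[i],
      concentration = cfg$simulate$concentration,
      chains = cfg$simulate$chains
    )
    reps_by_species[[species[i]]] <- simulate_repertoire(sc)
    log("simulated %d %s repertoires of %d reads", cfg$simulate$n_subjects,
        species[i], cfg$simulate$n_sequences)
  }
  # naive filter + collapse to unique sequences
  reps_by_species <- lapply(reps_by_species, function(reps) {
    lapply(reps, function(r) {
      n0 <- nrow(r$records)
      r <- collapse_unique(filter_naive(r))
      log("%s: %d reads -> %d unique naive sequences", r$subject_id, n0,
          nrow(r$records))
      r
    })
  })
  all_reps <- unlist(reps_by_species, recursive = FALSE)
  labels <- rep(species, vapply(reps_by_species, length, 0L))
  results$repertoires <- all_reps

  # --- usage -------------------------------------------------------------
  if ("usage" %in% cfg$analyses) {
    profs <- lapply(all_reps, usage_profile,
                    segment = cfg$usage$segment, level = cfg$usage$level)
    mat <- profile_matrix(profs)
    usage_tab <- tibble::as_tibble(mat, rownames = "subject_id") |>
      tidyr::pivot_longer(-"subject_id", names_to = "category",
                          values_to = "frequency")
    usage_tab$species <- labels[match(usage_tab$subject_id,
                                      vapply(all_reps, `[[`, "", "subject_id"))]
    readr::write_tsv(usage_tab, file.path(cfg$out_dir, "usage.tsv"),
                     progress = FALSE)
    tree <- cluster_profiles(z_normalise(mat),
                             cfg$separability$linkage)$tree
    ape::write.tree(ape::as.phylo(tree),
                    file.path(cfg$out_dir, "usage_dendrogram.nwk"))
    results$usage <- usage_tab
    log("usage: %d subjects x %d categories", nrow(mat), ncol(mat))
  }

  # --- separability ------------------------------------------------------
  if ("separability" %in% cfg$analyses) {
    sep <- separability_test(
      all_reps, labels,
      subsample_n = cfg$separability$subsample_n,
      n_repeats = cfg$separability$n_repeats,
      seed = stage_seeds[2],
      segment = cfg$separability$segment,
      level = cfg$separability$level,
      linkage = cfg$separability$linkage
    )
    jsonlite::write_json(
      sep[c("fraction_perfect", "ari", "n_repeats", "subsample_n",
            "segment", "level")],
      file.path(cfg$out_dir, "separability.json"),
      auto_unbox = TRUE, digits = NA
    )
    results$separability <- sep
    log("separability: fraction_perfect %.2f over %d repeats",
        sep$fraction_perfect, sep$n_repeats)
  }

  # --- clones ------------------------------------------------------------
  if (any(c("clones", "overlap", "diversity") %in% cfg$analyses)) {
    assignments <- lapply(all_reps, assign_clonotypes,
                          identity_threshold = cfg$clonotype$identity,
                          linkage = cfg$clonotype$linkage)
    names(assignments) <- vapply(all_reps, `[[`, "", "subject_id")
    clone_tab <- dplyr::bind_rows(lapply(names(assignments), function(nm) {
      dplyr::mutate(assignments[[nm]]$clones, subject_id = nm)
    }))
    readr::write_tsv(clone_tab, file.path(cfg$out_dir, "clones.tsv"),
                     progress = FALSE)
    results$clones <- assignments
    log("clonotypes: %d clones across %d subjects", nrow(clone_tab),
        length(assignments))
  }

  # --- overlap -----------------------------------------------------------
  if ("overlap" %in% cfg$analyses) {
    om <- pairwise_overlap(all_reps, unit = cfg$overlap$unit,
                           convention = cfg$overlap$convention,
                           identity_threshold = cfg$clonotype$identity)
    readr::write_tsv(tibble::as_tibble(om, rownames = "subject_id"),
                     file.path(cfg$out_dir, "overlap.tsv"),
                     progress = FALSE)
    results$overlap <- om
    log("overlap (%s, %s convention) written", cfg$overlap$unit,
        cfg$overlap$convention)
  }

  # --- diversity ---------------------------------------------------------
  if ("diversity" %in% cfg$analyses) {
    div <- dplyr::bind_rows(lapply(seq_along(all_reps), function(i) {
      r <- all_reps[[i]]
      dplyr::bind_rows(lapply(c("cdrh3", "clonotype"), function(u) {
        per_len <- per_length_diversity(r, u)
        tibble::tibble(
          subject_id = r$subject_id, species = labels[i], unit = u,
          H_total = repertoire_diversity(r, u),
          unique_per_sequence = unique_per_sequence_ratio(r, u),
          peak_length = per_len$cdr3_aa_length[which.max(per_len$H)]
        )
      }))
    }))
    readr::write_tsv(div, file.path(cfg$out_dir, "diversity.tsv"),
                     progress = FALSE)
    results$diversity <- div
    log("diversity table written (%d rows)", nrow(div))
  }

  # --- decomposition -----------------------------------------------------
  if ("decompose" %in% cfg$analyses) {
    ga <- reps_by_species[[cfg$decompose$group_a]]
    gb <- reps_by_species[[cfg$decompose$group_b]]
    dec <- decompose_length_difference(ga, gb,
                                       n_reps = cfg$decompose$n_reps,
                                       seed = stage_seeds[3])
    jsonlite::write_json(
      lapply(split(dec$summary, dec$summary$factor), function(row) {
        list(estimate = row$estimate, ci = c(row$ci_lo, row$ci_hi),
             p = row$p, units = row$units)
      }),
      file.path(cfg$out_dir, "decomp.json"), auto_unbox = TRUE, digits = NA
    )
    results$decompose <- dec
    log("decomposition %s vs %s: VD factor %.2f nt", cfg$decompose$group_a,
        cfg$decompose$group_b, dec$np1$estimate)
  }

  # --- structural usage --------------------------------------------------
  if ("structural" %in% cfg$analyses) {
    bg <- synthetic_background()
    ann <- simulate_annotation_table(
      setNames(rep(cfg$simulate$n_subjects, length(species)), species),
      n_per_subject = cfg$structural$n_per_subject,
      background = bg, bias = cfg$structural$bias, seed = stage_seeds[4]
    )
    murine_vs_rest <- setNames(
      ifelse(ann$species[match(unique(ann$subject_id), ann$subject_id)] ==
               "mouse", "murine", "human_like"),
      unique(ann$subject_id)
    )
    uda <- usage_distance_analysis(ann, true_labels = murine_vs_rest)
    jsonlite::write_json(
      list(ari = uda$ari,
           origin_bias = lapply(
             split(ann$subject_id, ann$species),
             function(sub) as.list(species_origin_bias(ann, unique(sub)))
           )),
      file.path(cfg$out_dir, "structusage.json"),
      auto_unbox = TRUE, digits = NA
    )
    results$structural <- uda
    log("structural usage ARI (murine vs rest): %.2f", uda$ari)
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(results)
}
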