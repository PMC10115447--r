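#!/usr/bin/env Rscript

# Step 3: clonotypes, diversity and sharing.
#
# Assigns clonotypes (shared IGHV/IGHJ, >= 90% CDRH3 amino-acid identity),
# computes Shannon diversity overall and per CDRH3 length, the
# unique-per-sequence ratios, and the pairwise CDRH3/clonotype sharing
# matrices under all three denominator conventions. Outputs under
# results/clonal/.

library(bcrcompare)
suppressMessages(library(dplyr))

out_dir <- "results/clonal"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

reps <- list()
for (sp in c("human", "kymouse", "mouse")) {
  for (f in list.files(file.path("scratch/data", sp), pattern = "\\.tsv$",
                       full.names = TRUE)) {
    r <- read_rearrangements(f, species = sp,
                             subject_id = sub("\\.tsv$", "", basename(f)))
    reps[[r$subject_id]] <- collapse_unique(filter_naive(r))
  }
}
labels <- vapply(reps, `[[`, "", "species")

# clone summaries ------------------------------------------------------------
clone_tab <- bind_rows(lapply(reps, function(r) {
  ca <- assign_clonotypes(r)
  tibble::tibble(
    subject_id = r$subject_id, species = r$species,
    n_sequences = nrow(ca$assignment), n_clones = nrow(ca$clones),
    pct_singletons = 100 * mean(ca$clones$size == 1),
    max_clone_size = max(ca$clones$size)
  )
}))
readr::write_tsv(clone_tab, file.path(out_dir, "clone_summary.tsv"))
print(as.data.frame(clone_tab), digits = 3)

# diversity -----------------------------------------------------------------
div <- bind_rows(lapply(reps, function(r) {
  bind_rows(lapply(c("cdrh3", "clonotype"), function(u) {
    pl <- per_length_diversity(r, u)
    tibble::tibble(
      subject_id = r$subject_id, species = r$species, unit = u,
      H = repertoire_diversity(r, u),
      unique_per_sequence = unique_per_sequence_ratio(r, u),
      peak_diversity_length = pl$cdr3_aa_length[which.max(pl$H)]
    )
  }))
}))
readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))
cat("\nmean diversity peak length by species (CDRH3 unit):\n")
d1 <- div[div$unit == "cdrh3", ]
print(tapply(d1$peak_diversity_length, d1$species, mean))

# sharing -------------------------------------------------------------------
summ <- list()
for (conv in c("mean", "min", "jaccard")) {
  for (unit in c("cdrh3", "clonotype")) {
    om <- pairwise_overlap(reps, unit = unit, convention = conv)
    readr::write_tsv(
      tibble::as_tibble(om, rownames = "subject_id"),
      file.path(out_dir, sprintf("overlap_%s_%s.tsv", unit, conv))
    )
    for (sp in unique(labels)) {
      m <- om[labels == sp, labels == sp]
      summ[[paste(unit, conv, sp)]] <- tibble::tibble(
        unit = unit, convention = conv, species = sp,
        mean_pairwise_pct = mean(m[upper.tri(m)])
      )
    }
  }
}
summ <- bind_rows(summ)
readr::write_tsv(summ, file.path(out_dir, "sharing_summary.tsv"))
cat("\nwithin-species mean sharing (%, mean convention):\n")
print(summ[summ$convention == "mean", ])
cat("\nwrote clonal outputs under", out_dir, "\n")
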