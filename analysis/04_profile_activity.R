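#!/usr/bin/env Rscript
# Aggregate the per-pair calls into effector-level summaries: mean indel
# frequencies by concrete PAM (heatmap-style table), effector ranking,
# repair-pathway composition, replicate reproducibility, and nonparametric
# comparisons across effectors.

suppressPackageStartupMessages(library(crisprpair))

call_dir <- "results/calls"
lib <- read_tsv_table("results/design/library_libA.tsv")
lib <- lib[seq_len(min(120, nrow(lib))), ]
out_dir <- "results/profiles"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

effectors <- c("strongA", "strongB", "weak", "variant3R")
freqs <- lapply(effectors, function(e) {
  read_tsv_table(file.path(call_dir, paste0(e, "_frequencies.tsv")))
})
names(freqs) <- effectors

## PAM-preference table (effector x concrete PAM, mean frequency)
pam_groups <- expand_pattern("TTTV")
pam_tab <- dplyr::bind_rows(lapply(effectors, function(e) {
  summarize_by_pam(freqs[[e]], lib, pam_groups, effector = e)
}))
write_tsv_table(pam_tab, file.path(out_dir, "pam_summary.tsv"))
cat("Mean indel frequency by PAM (percent):\n")
wide <- tidyr::pivot_wider(pam_tab[, c("effector", "pam_group",
                                       "mean_frequency")],
                           names_from = "pam_group",
                           values_from = "mean_frequency")
print(as.data.frame(dplyr::mutate(wide, dplyr::across(-1, ~ round(100 * .x, 1)))))

## ranking with the 20% high/low convention
means <- vapply(effectors, function(e) {
  f <- freqs[[e]]
  mean(f$indel_frequency[!f$excluded], na.rm = TRUE)
}, numeric(1))
rk <- rank_effectors(means)
write_tsv_table(rk, file.path(out_dir, "effector_ranking.tsv"))
cat("\nEffector ranking (high/low split at 20%):\n")
print(as.data.frame(rk))

## repair-pathway composition per effector
pathway <- dplyr::bind_rows(lapply(effectors, function(e) {
  cat_tab <- read_tsv_table(file.path(call_dir, paste0(e, "_catalogue.tsv")))
  if (nrow(cat_tab) == 0) return(NULL)
  cls <- vapply(seq_len(nrow(cat_tab)), function(i) {
    ev <- parse_repair_type(paste0(cat_tab$repair_type[i], ":1"))$events
    classify_pathway(ev, lib$target[lib$pair_id == cat_tab$pair_id[i]])
  }, character(1))
  tibble::tibble(effector = e,
                 mmej_pct = 100 * sum(cat_tab$count[cls == "MMEJ"]) /
                   sum(cat_tab$count),
                 n_types = nrow(cat_tab))
}))
write_tsv_table(pathway, file.path(out_dir, "pathway_composition.tsv"))
cat("\nMMEJ share of edited reads (%):\n")
print(as.data.frame(pathway))

## replicate reproducibility of strongA
rep2 <- read_tsv_table(file.path(call_dir, "strongA_rep2_frequencies.tsv"))
rc <- replicate_correlation(freqs$strongA, rep2)
cat(sprintf("\nstrongA replicate correlation: Pearson r = %.3f (n = %d)\n",
            rc$statistic, rc$n))
write_tsv_table(rc, file.path(out_dir, "replicate_correlation.tsv"))

## nonparametric comparisons across effectors
vals <- lapply(freqs, function(f) f$indel_frequency[!f$excluded])
km <- compare_many(vals)
write_tsv_table(km, file.path(out_dir, "effector_comparisons.tsv"))
cat(sprintf("\nKruskal-Wallis H = %.1f, p = %.3g\n",
            km$statistic[km$test == "kruskal_wallis"],
            km$p_value[km$test == "kruskal_wallis"]))
mw <- compare_two(vals$strongA, vals$weak)
cat(sprintf("strongA vs weak: Mann-Whitney U = %.0f, p = %.3g\n",
            mw$statistic, mw$p_value))
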