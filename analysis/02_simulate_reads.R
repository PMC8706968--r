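#!/usr/bin/env Rscript
# Simulate amplicon sequencing for four effector models on the canonical
# library, with matched no-effector controls and ground-truth tables.
#
# The four models sketch the qualitative behaviours seen across wild-type
# and arginine-substituted Cas12a effectors: two strong canonical editors,
# one weak orthologue, and one engineered variant. Each guide additionally
# gets an intrinsic activity multiplier (log-normal, drawn once per
# effector and shared between replicates, as guide-dependent activity is a
# property of the guide-target pair, not of the sequencing run). Activities
# are generator inputs (ground truth), so downstream scripts can score
# recovery.

suppressPackageStartupMessages(library(crisprpair))

lib_file <- "results/design/library_libA.tsv"
if (!file.exists(lib_file)) stop("run analysis/01_design_library.R first")
lib <- read_tsv_table(lib_file)
lib <- lib[seq_len(min(120, nrow(lib))), ]
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 4316

canon <- expand_pattern("TTTV")
act <- function(pams, level) stats::setNames(rep(level, length(pams)), pams)

effectors <- list(
  effector_model("strongA", act(canon, 0.39)),
  effector_model("strongB", act(canon, 0.34), mmej_weight = 0.6),
  effector_model("weak",    act(canon, 0.08)),
  effector_model("variant3R", act(canon, 0.43))
)

depth <- 600
guide_rates <- function(eff, i) {
  # guide-intrinsic multiplier around the effector's per-PAM base activity
  set.seed(seed + 1000 + i)
  base <- unname(eff$pam_activity[lib$pam])
  stats::setNames(pmin(base * stats::rlnorm(nrow(lib), 0, 0.45), 0.9),
                  lib$pair_id)
}

truths <- list()
for (i in seq_along(effectors)) {
  eff <- effectors[[i]]
  rates <- guide_rates(eff, i)
  ds <- generate_dataset(lib, eff, depth_per_pair = depth, seed = seed + i,
                         edit_rates = rates)
  write_fastq(ds$experimental,
              file.path(out_dir, paste0(eff$name, "_exp.fastq.gz")))
  write_fastq(ds$control,
              file.path(out_dir, paste0(eff$name, "_ctl.fastq.gz")))
  ds$truth$effector <- eff$name
  truths[[i]] <- ds$truth
  cat(sprintf("%-10s %d exp + %d ctl reads at depth %d\n", eff$name,
              nrow(ds$experimental), nrow(ds$control), depth))
}
write_tsv_table(dplyr::bind_rows(truths), file.path(out_dir, "truth.tsv"))

# a second biological replicate of strongA: same per-guide truth (activity
# is a property of the pair), independent sampling and noise
ds_rep <- generate_dataset(lib, effectors[[1]], depth_per_pair = depth,
                           seed = seed + 99,
                           edit_rates = guide_rates(effectors[[1]], 1))
write_fastq(ds_rep$experimental,
            file.path(out_dir, "strongA_rep2_exp.fastq.gz"))
write_fastq(ds_rep$control, file.path(out_dir, "strongA_rep2_ctl.fastq.gz"))
cat("replicate 2 of strongA written\n")
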