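#!/usr/bin/env Rscript
# Design the paired guide-target libraries.
#
# Builds a synthetic 25-gene reference set (stand-in for the cancer-gene
# transcripts a real screen would use; labelled synthetic throughout),
# designs a canonical-PAM library (TTTV, Lib-A-style) plus smaller
# altered-PAM libraries (Lib-B/C-style presets), and writes the library
# tables and 142-nt oligo pools under results/design/.

suppressPackageStartupMessages(library(crisprpair))

out_dir <- "results/design"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20211210

set.seed(seed)
genes <- stats::setNames(
  replicate(25, paste(sample(c("A", "C", "G", "T"), 600, TRUE,
                             prob = c(.3, .2, .2, .3)), collapse = "")),
  sprintf("synthgene%02d", 1:25))
write_fasta(genes, file.path(out_dir, "synthetic_genes.fasta"))

libs <- list(
  libA = design_library(genes, pam_patterns = pam_preset("lib-a"),
                        seed = seed),
  libB = design_library(genes, pam_patterns = pam_preset("lib-b"),
                        top_k = 4, seed = seed + 1),
  libC = design_library(genes, pam_patterns = pam_preset("lib-c"),
                        top_k = 4, seed = seed + 2)
)

for (nm in names(libs)) {
  lib <- libs[[nm]]
  write_tsv_table(lib, file.path(out_dir, paste0("library_", nm, ".tsv")))
  write_fasta(reference_amplicons(lib),
              file.path(out_dir, paste0("oligos_", nm, ".fasta")))
  cat(sprintf("%s: %d pairs over %d genes; GC %.0f-%.0f%%; all oligos %d nt\n",
              nm, nrow(lib), length(unique(lib$gene_id)),
              min(100 * vapply(strsplit(lib$spacer, ""), function(b)
                mean(b %in% c("G", "C")), numeric(1))),
              max(100 * vapply(strsplit(lib$spacer, ""), function(b)
                mean(b %in% c("G", "C")), numeric(1))),
              unique(nchar(reference_amplicons(lib)))))
}

cat("\nPAM composition of the altered-PAM libraries:\n")
print(table(substr(libs$libB$pam, 1, 4)))
print(table(substr(libs$libC$pam, 1, 4)))
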