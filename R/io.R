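#' Read a FASTA file
#'
#' @param path FASTA file (gzip transparently supported).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences as FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(toupper(unlist(records)))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip transparently supported).
#' @return Tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble::tibble(read_id = names(x),
                 seq = unname(as.character(x)),
                 qual = unname(as.character(Biostrings::quality(x))))
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `seq` and optionally `qual` (constant
#'   quality `I` is written if absent).
#' @param path Output file (`.gz` suffix compresses).
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  qual <- if ("qual" %in% names(reads)) reads$qual
          else vapply(nchar(reads$seq),
                      function(n) paste(rep("I", n), collapse = ""),
                      character(1))
  q <- Biostrings::BStringSet(qual)
  x <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(q))
  # Biostrings warns about dropping (empty) metadata columns on write
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = grepl("\\.gz$", path)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' TSV with a header row is the pipeline interchange format.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' @rdname read_tsv_table
#' @param x Data frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Chains design -> simulate -> call -> profile with file handoffs in
#' `out_dir`: library and oligo tables, experimental/control FASTQ, truth
#' table, per-pair profile and repair-type catalogue TSVs, and a PAM summary.
#' Identical seeds yield identical outputs.
#'
#' @param sequences Named character vector of reference sequences for design.
#' @param effector [effector_model()].
#' @param out_dir Output directory (created if missing).
#' @param pam_patterns PAM patterns for design.
#' @param noise [noise_model()].
#' @param depth_per_pair Reads per pair and group.
#' @param config [calling_config()].
#' @param pam_groups PAM groups for the summary table (defaults to
#'   `pam_patterns`).
#' @param seed Integer seed for every random step.
#' @return Invisibly, a list with the in-memory results (`library`, `truth`,
#'   `calls`, `pam_summary`) and the written file paths.
#' @export
run_pipeline <- function(sequences, effector, out_dir,
                         pam_patterns = pam_preset("lib-a"),
                         noise = noise_model(), depth_per_pair = 500,
                         config = calling_config(),
                         pam_groups = pam_patterns, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  lib <- design_library(sequences, pam_patterns = pam_patterns,
                        seed = child_seed(seed, "design"))
  write_tsv_table(lib, pth("library.tsv"))
  oligos <- reference_amplicons(lib)
  write_fasta(oligos, pth("oligos.fasta"))

  ds <- generate_dataset(lib, effector, noise = noise,
                         depth_per_pair = depth_per_pair,
                         seed = child_seed(seed, "simulate"))
  write_fastq(ds$experimental, pth("experimental.fastq"))
  write_fastq(ds$control, pth("control.fastq"))
  write_tsv_table(ds$truth, pth("truth.tsv"))

  calls <- call_indels(ds$experimental, ds$control, lib, config = config)
  write_tsv_table(calls$frequencies, pth("frequencies.tsv"))
  write_tsv_table(calls$catalogue, pth("catalogue.tsv"))

  pam_summary <- summarize_by_pam(calls$frequencies, lib, pam_groups,
                                  effector = effector$name)
  write_tsv_table(pam_summary, pth("pam_summary.tsv"))

  invisible(list(library = lib, truth = ds$truth, calls = calls,
                 pam_summary = pam_summary,
                 files = vapply(c("library.tsv", "oligos.fasta",
                                  "experimental.fastq", "control.fastq",
                                  "truth.tsv", "frequencies.tsv",
                                  "catalogue.tsv", "pam_summary.tsv"),
                                pth, character(1))))
}
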