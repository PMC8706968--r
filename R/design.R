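revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_percent <- function(spacer) {
  n <- nchar(spacer)
  gc <- vapply(strsplit(toupper(spacer), "", fixed = TRUE),
               function(b) sum(b %in% c("G", "C")), integer(1))
  100 * gc / n
}

scan_one_strand <- function(sequence, pattern, spacer_len, context_len) {
  plen <- nchar(pattern)
  L <- nchar(sequence)
  need <- plen + spacer_len
  if (L < need) return(integer(0))
  starts <- seq_len(L - need + 1L) # 1-based window starts with room for spacer
  windows <- substring(sequence, starts, starts + plen - 1L)
  starts[matches_pam(windows, pattern)]
}

#' Scan a sequence for PAM-adjacent protospacers on both strands
#'
#' Slides a window over the sequence (and its reverse complement) and reports
#' every position where the PAM-length window matches the degenerate pattern
#' and at least `spacer_len` bases follow 3' of the PAM. Minus-strand sites
#' are reported in the orientation read 5'->3' off the reverse complement;
#' `pam_start` is always the 0-based plus-strand offset of the leftmost base
#' of the PAM site.
#'
#' @param sequence Single nucleotide string (plus strand).
#' @param pattern IUPAC PAM pattern (e.g. `"TTTV"`).
#' @param spacer_len Protospacer length, default 23.
#' @param gene_id Identifier attached to each candidate.
#' @return Tibble with columns `gene_id`, `spacer`, `pam`, `strand`,
#'   `pam_start`, `gc_percent`; sorted by (strand, pam_start).
#' @export
scan_protospacers <- function(sequence, pattern, spacer_len = 23,
                              gene_id = "seq") {
  pattern <- validate_pam_pattern(pattern)
  sequence <- toupper(sequence)
  plen <- nchar(pattern)
  L <- nchar(sequence)

  cand_from <- function(seqstr, strand) {
    starts <- scan_one_strand(seqstr, pattern, spacer_len, 0L)
    if (length(starts) == 0) return(NULL)
    pam <- substring(seqstr, starts, starts + plen - 1L)
    spacer <- substring(seqstr, starts + plen, starts + plen + spacer_len - 1L)
    # 0-based plus-strand offset of leftmost PAM base
    pam_start <- if (strand == "+") starts - 1L else L - (starts - 1L) - plen
    tibble::tibble(
      gene_id = gene_id, spacer = spacer, pam = pam,
      strand = strand, pam_start = as.integer(pam_start),
      gc_percent = gc_percent(spacer)
    )
  }

  out <- dplyr::bind_rows(
    cand_from(sequence, "+"),
    if (L >= plen + spacer_len) cand_from(revcomp(sequence), "-")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(), spacer = character(),
                          pam = character(), strand = character(),
                          pam_start = integer(), gc_percent = double()))
  }
  dplyr::arrange(out, .data$strand, .data$pam_start)
}

#' Filter guide candidates on GC content and thymidine runs
#'
#' Retains candidates whose spacer GC content lies in `[gc_min, gc_max]`
#' (percent) and which contain no run of four repeated thymidines (or a
#' custom forbidden substring). Idempotent; input order preserved.
#'
#' @param candidates Tibble from [scan_protospacers()].
#' @param gc_min,gc_max GC bounds in percent (defaults 20 and 80).
#' @param forbidden_run Substring excluded from spacers, default `"TTTT"`.
#' @return Filtered tibble.
#' @export
filter_guides <- function(candidates, gc_min = 20, gc_max = 80,
                          forbidden_run = "TTTT") {
  if (gc_min > gc_max) stop("gc_min must not exceed gc_max", call. = FALSE)
  gc <- if ("gc_percent" %in% names(candidates)) candidates$gc_percent
        else gc_percent(candidates$spacer)
  keep <- gc >= gc_min & gc <= gc_max &
    !grepl(forbidden_run, candidates$spacer, fixed = TRUE)
  candidates[keep, , drop = FALSE]
}

#' Keep the top-k candidates per gene
#'
#' Candidates are ranked per gene by distance of the spacer GC content from
#' 50% (ascending, favouring mid-GC guides), with ties broken by `pam_start`
#' ascending and then strand (`+` before `-`). This rank is a deterministic
#' stand-in for web-tool guide scores.
#'
#' @param candidates Tibble with `gene_id`, `gc_percent`, `pam_start`, `strand`.
#' @param k Maximum candidates per gene, default 10.
#' @return Tibble with at most `k` rows per gene, in rank order.
#' @export
take_top_k_per_gene <- function(candidates, k = 10) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  candidates |>
    dplyr::mutate(.gc_dist = abs(.data$gc_percent - 50)) |>
    dplyr::arrange(.data$gene_id, .data$.gc_dist, .data$pam_start,
                   .data$strand) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup() |>
    dplyr::select(-".gc_dist")
}

has_homopolymer <- function(x, len = 4) {
  grepl(paste0("A{", len, "}|C{", len, "}|G{", len, "}|T{", len, "}"), x)
}

hamming_lt <- function(bc, accepted_mat, min_distance) {
  # TRUE if bc is within (min_distance - 1) of any accepted barcode
  if (nrow(accepted_mat) == 0) return(FALSE)
  b <- strsplit(bc, "", fixed = TRUE)[[1]]
  d <- rowSums(accepted_mat != matrix(b, nrow = nrow(accepted_mat),
                                      ncol = length(b), byrow = TRUE))
  any(d < min_distance)
}

#' Assign unique barcodes to guide-target pairs
#'
#' Draws random barcodes (seeded, hence reproducible) subject to: all pairwise
#' Hamming distances at least `min_distance`, and no homopolymer run of four
#' or more bases. Distance-3 codes keep demultiplexing unambiguous even if a
#' read carries one barcode error.
#'
#' @param n Number of barcodes required.
#' @param length Barcode length, default 12.
#' @param min_distance Minimum pairwise Hamming distance, default 3.
#' @param seed Integer seed; the same seed yields the same assignment.
#' @param max_attempts Proposals tried before giving up.
#' @return Character vector of `n` distinct barcodes.
#' @export
assign_barcodes <- function(n, length = 12, min_distance = 3, seed = 1,
                            max_attempts = 200 * n + 5000) {
  stopifnot(n >= 1, length >= 1)
  if (4^length < n) {
    stop("barcode space 4^", length, " too small for ", n, " pairs",
         call. = FALSE)
  }
  out <- character(0)
  acc_mat <- matrix(character(0), nrow = 0, ncol = length)
  with_seed(seed, {
    attempts <- 0L
    while (base::length(out) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      bc <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
      if (has_homopolymer(bc)) next
      if (hamming_lt(bc, acc_mat, min_distance)) next
      out <- c(out, bc)
      acc_mat <- rbind(acc_mat, strsplit(bc, "", fixed = TRUE)[[1]])
    }
  })
  if (base::length(out) < n) {
    stop("barcode constraints unsatisfiable: found ", base::length(out),
         " of ", n, " barcodes after ", max_attempts, " attempts",
         call. = FALSE)
  }
  out
}

#' Design a paired guide-target library from reference sequences
#'
#' Full design path: scan each input sequence for PAM-adjacent protospacers,
#' filter on GC content and T-runs, keep the top-k candidates per gene,
#' require 15 nt of downstream genomic context (so the 42-nt target window =
#' 4-nt PAM + 23-nt protospacer + 15-nt context fits), and assign barcodes.
#'
#' @param sequences Named character vector (or list) of reference sequences;
#'   names are gene ids.
#' @param pam_patterns Character vector of IUPAC PAM patterns (see
#'   [pam_preset()]).
#' @param spacer_len Spacer length, default 23.
#' @param context_len Downstream context length, default 15.
#' @param gc_min,gc_max,forbidden_run Guide filters, see [filter_guides()].
#' @param top_k Candidates kept per gene, default 10.
#' @param barcode_len,min_distance Barcode parameters, see [assign_barcodes()].
#' @param seed Seed for barcode assignment.
#' @return Tibble (one row per pair): `pair_id`, `gene_id`, `spacer`,
#'   `barcode`, `pam`, `target`, `strand`, `pam_start`.
#' @export
design_library <- function(sequences, pam_patterns = pam_preset("lib-a"),
                           spacer_len = 23, context_len = 15,
                           gc_min = 20, gc_max = 80, forbidden_run = "TTTT",
                           top_k = 10, barcode_len = 12, min_distance = 3,
                           seed = 1) {
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("gene", seq_along(sequences))
  }
  plen <- nchar(pam_patterns[1])
  target_len <- plen + spacer_len + context_len

  per_gene <- purrr::imap(sequences, function(s, g) {
    purrr::map(pam_patterns, function(p) {
      cand <- scan_protospacers(s, p, spacer_len = spacer_len, gene_id = g)
      if (nrow(cand) == 0) return(cand)
      # keep only sites with full downstream context on their own strand
      L <- nchar(s)
      site_start <- ifelse(cand$strand == "+", cand$pam_start,
                           L - cand$pam_start - plen)
      keep <- site_start + target_len <= L
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0) return(cand)
      src <- ifelse(cand$strand == "+", s, revcomp(s))
      ss <- ifelse(cand$strand == "+", cand$pam_start,
                   L - cand$pam_start - plen)
      cand$target <- substring(src, ss + 1L, ss + target_len)
      cand$pam_pattern <- p
      cand
    }) |> dplyr::bind_rows()
  })
  cand <- dplyr::bind_rows(per_gene)
  if (nrow(cand) == 0) {
    stop("no protospacers found for the given PAM pattern(s)", call. = FALSE)
  }
  cand <- filter_guides(cand, gc_min, gc_max, forbidden_run)
  cand <- take_top_k_per_gene(cand, k = top_k)
  cand <- dplyr::distinct(cand, .data$spacer, .data$target, .keep_all = TRUE)
  if (nrow(cand) == 0) stop("no candidates left after filtering", call. = FALSE)

  cand$pair_id <- sprintf("pair%04d", seq_len(nrow(cand)))
  cand$barcode <- assign_barcodes(nrow(cand), length = barcode_len,
                                  min_distance = min_distance, seed = seed)
  dplyr::select(cand, "pair_id", "gene_id", "spacer", "barcode", "pam",
                "target", "strand", "pam_start")
}
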