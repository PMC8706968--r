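#' Alignment scoring configuration
#'
#' Global (end-to-end) affine scores used when aligning the read-side target
#' region against the 42-nt reference window.
#'
#' @param match,mismatch,gap_open,gap_extend Scores; a gap of length L costs
#'   `gap_open + L * gap_extend` (penalties given as negative numbers).
#' @return Named list of scores.
#' @export
align_scores <- function(match = 2, mismatch = -4, gap_open = -6,
                         gap_extend = -1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

empty_subs <- function() {
  tibble::tibble(pos = integer(), ref_base = character(),
                 read_base = character())
}

# Convert a forward op string (M/D/I) into events + substitutions in
# 0-based reference coordinates.
ops_to_result <- function(ops, read, ref) {
  op <- strsplit(ops, "", fixed = TRUE)[[1]]
  P <- strsplit(read, "", fixed = TRUE)[[1]]
  S <- strsplit(ref, "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L
  ev <- list(); subs <- list()
  k <- 1L
  nop <- length(op)
  while (k <= nop) {
    if (op[k] == "M") {
      i <- i + 1L; j <- j + 1L
      if (P[i] != S[j]) {
        subs[[length(subs) + 1L]] <- list(pos = j - 1L, ref_base = S[j],
                                          read_base = P[i])
      }
      k <- k + 1L
    } else if (op[k] == "D") {
      start <- j
      while (k <= nop && op[k] == "D") { j <- j + 1L; k <- k + 1L }
      ev[[length(ev) + 1L]] <- list(kind = "del", start = start,
                                    length = j - start, seq = "")
    } else {
      i0 <- i; start <- j
      while (k <= nop && op[k] == "I") { i <- i + 1L; k <- k + 1L }
      ev[[length(ev) + 1L]] <- list(kind = "ins", start = start,
                                    length = i - i0,
                                    seq = paste(P[(i0 + 1L):i], collapse = ""))
    }
  }
  list(
    events = if (length(ev) > 0) dplyr::bind_rows(lapply(ev, tibble::as_tibble))
             else event_tbl(),
    substitutions = if (length(subs) > 0)
      dplyr::bind_rows(lapply(subs, tibble::as_tibble)) else empty_subs()
  )
}

#' Align read-side target regions against the reference window
#'
#' Global end-to-end alignment under affine scores. Among score-equivalent
#' alignments the canonical one is reported: fewest indel events, then
#' fewest substitutions, then every gap shifted to its lowest
#' score-equivalent reference coordinate (left alignment). Event coordinates
#' are 0-based with the 5' end of the PAM as position 0.
#'
#' @param reads Character vector of read-side target region sequences.
#' @param reference Reference window (42 nt in the standard layout).
#' @param scores [align_scores()].
#' @return List (one element per read) of lists with `events` (tibble of
#'   del/ins events), `substitutions` (tibble `pos`, `ref_base`,
#'   `read_base`) and `score`.
#' @export
align_target <- function(reads, reference, scores = align_scores()) {
  stopifnot(length(reference) == 1L, nchar(reference) > 0)
  if (length(reads) == 0) return(list())
  if (any(!nzchar(reads))) stop("empty read sequence", call. = FALSE)

  out <- vector("list", length(reads))
  ident <- reads == reference
  id_res <- list(events = event_tbl(), substitutions = empty_subs(),
                 score = scores$match * nchar(reference))
  for (i in which(ident)) out[[i]] <- id_res

  todo <- which(!ident)
  if (length(todo) == 0) return(out)
  uniq <- unique(reads[todo])
  res <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    ops <- .canonical_align_ops(uniq[k], reference, scores$match,
                                scores$mismatch, scores$gap_open,
                                scores$gap_extend)
    r <- ops_to_result(ops, uniq[k], reference)
    r$score <- .canonical_align_score(uniq[k], reference, scores$match,
                                      scores$mismatch, scores$gap_open,
                                      scores$gap_extend)
    res[[k]] <- r
  }
  names(res) <- uniq
  for (i in todo) out[[i]] <- res[[reads[i]]]
  out
}
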