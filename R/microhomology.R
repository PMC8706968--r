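#' Find microhomology-deletion candidates in a target window
#'
#' Scans the target for pairs of identical flanking k-mers (k >=
#' `min_len`) whose collapse produces a deletion, i.e. deleting the interval
#' between the left copy's start and the right copy's start yields the same
#' sequence as removing one repeat unit. These are the deletions that
#' microhomology-mediated end joining (MMEJ) can generate around the cleavage
#' site. Results are left-normalized (reported at the lowest equivalent start
#' coordinate) and deduplicated keeping, for each distinct (start, length),
#' the longest supporting microhomology.
#'
#' @param target Target window string (typically 42 nt).
#' @param min_len Minimum microhomology length, default 2.
#' @param max_span Maximum deletion length reported; defaults to the target
#'   length.
#' @param max_mh Longest k-mer considered, default 8.
#' @return Tibble with `deletion_start` (0-based), `deletion_len`, `mh_len`,
#'   sorted by (deletion_start, deletion_len).
#' @export
find_microhomologies <- function(target, min_len = 2, max_span = nchar(target),
                                 max_mh = 8) {
  stopifnot(min_len >= 1)
  chars <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  L <- length(chars)
  hits <- list()
  for (k in seq(min_len, min(max_mh, L - 1))) {
    if (L < k + 1) break
    starts <- seq_len(L - k + 1L) # 1-based k-mer starts
    kmers <- substring(target, starts, starts + k - 1L)
    groups <- split(starts, kmers)
    for (g in groups) {
      if (length(g) < 2) next
      cmb <- utils::combn(g, 2)
      for (ci in seq_len(ncol(cmb))) {
        i <- cmb[1, ci]; j <- cmb[2, ci]
        len <- j - i
        if (len < 1 || len > max_span) next
        # deleting [i-1, i-1+len) (0-based) collapses the two copies
        hits[[length(hits) + 1L]] <- c(start = i - 1L, len = len, mh = k)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(deletion_start = integer(), deletion_len = integer(),
                          mh_len = integer()))
  }
  hmat <- do.call(rbind, hits)
  out <- tibble::tibble(deletion_start = as.integer(hmat[, "start"]),
                        deletion_len = as.integer(hmat[, "len"]),
                        mh_len = as.integer(hmat[, "mh"]))
  # left-normalize each deletion within the target
  for (r in seq_len(nrow(out))) {
    s <- out$deletion_start[r]; len <- out$deletion_len[r]
    while (s > 0 && chars[s] == chars[s + len]) s <- s - 1L
    out$deletion_start[r] <- s
  }
  out |>
    dplyr::group_by(.data$deletion_start, .data$deletion_len) |>
    dplyr::summarise(mh_len = max(.data$mh_len), .groups = "drop") |>
    dplyr::arrange(.data$deletion_start, .data$deletion_len)
}
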