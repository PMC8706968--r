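#' IUPAC degeneracy sets
#'
#' Mapping from IUPAC nucleotide symbols to the set of concrete bases each
#' symbol stands for (e.g. `V` = A/C/G, `K` = G/T, `N` = A/C/G/T).
#'
#' @format Named list of character vectors.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

validate_pam_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  pattern <- toupper(pattern)
  syms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(syms, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC symbol(s) in PAM pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  pattern
}

#' Expand a degenerate PAM pattern into concrete sequences
#'
#' Every IUPAC symbol is replaced by its degeneracy set and the Cartesian
#' product is returned. The number of sequences equals the product of the
#' per-position degeneracies; e.g. `TTTV` (V = A/C/G) expands to the three
#' canonical Cas12a PAMs TTTA, TTTC and TTTG.
#'
#' @param pattern A string over the IUPAC nucleotide alphabet, typically 4 nt.
#' @return Character vector of concrete sequences, lexicographically sorted.
#' @examples
#' expand_pattern("TTTV")
#' length(expand_pattern("NYYV"))
#' @export
expand_pattern <- function(pattern) {
  pattern <- validate_pam_pattern(pattern)
  syms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- lapply(syms, function(s) IUPAC_SETS[[s]])
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Test concrete sequences against a degenerate PAM pattern
#'
#' @param sequence Character vector of concrete sequences, each the same
#'   length as `pattern`.
#' @param pattern IUPAC pattern string.
#' @return Logical vector: `TRUE` where every base falls in the degeneracy
#'   set of its position.
#' @examples
#' matches_pam(c("TTTA", "TTTT"), "TTTV")
#' @export
matches_pam <- function(sequence, pattern) {
  pattern <- validate_pam_pattern(pattern)
  sequence <- toupper(sequence)
  plen <- nchar(pattern)
  if (any(nchar(sequence) != plen)) {
    stop("sequence length must equal pattern length (", plen, ")", call. = FALSE)
  }
  if (length(sequence) == 0) return(logical(0))
  psyms <- strsplit(pattern, "", fixed = TRUE)[[1]]
  seq_mat <- matrix(unlist(strsplit(sequence, "", fixed = TRUE)),
                    ncol = plen, byrow = TRUE)
  ok <- rep(TRUE, length(sequence))
  for (j in seq_len(plen)) {
    ok <- ok & seq_mat[, j] %in% IUPAC_SETS[[psyms[j]]]
  }
  ok
}

#' PAM pattern presets for the three library designs
#'
#' `lib-a` holds the canonical TTTV PAM; `lib-b` the mostly C-rich altered
#' PAMs (TTCV, VTCV, VCTV, VCCV, VTTV); `lib-c` the TRTN and NTTT groups.
#'
#' @param name One of `"lib-a"`, `"lib-b"`, `"lib-c"`.
#' @return Character vector of IUPAC PAM patterns.
#' @export
pam_preset <- function(name = c("lib-a", "lib-b", "lib-c")) {
  name <- match.arg(tolower(name), c("lib-a", "lib-b", "lib-c"))
  switch(name,
    "lib-a" = "TTTV",
    "lib-b" = c("TTCV", "VTCV", "VCTV", "VCCV", "VTTV"),
    "lib-c" = c("TRTN", "NTTT")
  )
}
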