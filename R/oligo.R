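#' Amplicon element layout
#'
#' Element lengths of the synthesized 142-nt oligonucleotide and hence of the
#' sequenced amplicon: a 20-nt forward constant (primer binding), the 19-nt
#' crRNA scaffold handle, the 23-nt spacer, a 6-nt poly-T terminating crRNA
#' transcription, a 12-nt pair-identifying barcode, the 42-nt target window
#' (PAM + protospacer + downstream context), and a 20-nt reverse constant.
#'
#' @return Named integer vector of element widths (sums to 142).
#' @export
oligo_layout <- function() {
  c(fwd_const = 20L, handle = 19L, spacer = 23L, polyT = 6L,
    barcode = 12L, target = 42L, rev_const = 20L)
}

#' Default constant and handle sequences
#'
#' The forward/reverse constants are arbitrary fixed 20-mers standing in for
#' vendor amplification primers; the handle is a canonical 19-nt direct-repeat
#' scaffold whose stem pairs offsets 4-8 (TCTAC) with 13-17 (GTAGA) and whose
#' non-conserved loop occupies 0-based offsets 9-12. All are configurable in
#' the functions that consume them.
#'
#' @return Named character vector with `fwd_const`, `handle`, `rev_const`.
#' @export
default_elements <- function() {
  c(fwd_const = "AGGCACTTGCTCGTACGACG",
    handle    = "AATTTCTACTCTTGTAGAT",
    rev_const = "ATGTGGAAAGGACGACTCGT")
}

#' Default 0-based loop offsets of the 19-nt handle
#' @return Integer vector of loop positions.
#' @export
default_loop_positions <- function() 9:12

check_len <- function(x, field, len) {
  if (length(x) != 1L || is.na(x) || nchar(x) != len) {
    stop("field '", field, "' must be a single ", len, "-nt string",
         call. = FALSE)
  }
  invisible(x)
}

#' Apply loop-region substitutions to a crRNA scaffold handle
#'
#' Scaffold variants differ from the wild-type direct repeat only by base
#' substitutions in the non-conserved loop; substitutions at stem positions
#' are rejected.
#'
#' @param base_handle 19-nt handle string.
#' @param substitutions Named character vector mapping 0-based handle offsets
#'   to replacement bases, e.g. `c("10" = "A")`. Empty means wild type.
#' @param loop_positions Integer vector of permitted 0-based offsets.
#' @return Handle string of unchanged length with substitutions applied.
#' @export
apply_scaffold_variant <- function(base_handle = default_elements()[["handle"]],
                                   substitutions = character(0),
                                   loop_positions = default_loop_positions()) {
  check_len(base_handle, "handle", 19L)
  if (length(substitutions) == 0) return(base_handle)
  pos <- as.integer(names(substitutions))
  if (any(is.na(pos))) stop("substitutions must be named by 0-based offset",
                            call. = FALSE)
  outside <- setdiff(pos, loop_positions)
  if (length(outside) > 0) {
    stop("substitution at non-loop (stem) position(s): ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  if (!all(substitutions %in% c("A", "C", "G", "T"))) {
    stop("substitution bases must be A/C/G/T", call. = FALSE)
  }
  chars <- strsplit(base_handle, "", fixed = TRUE)[[1]]
  chars[pos + 1L] <- substitutions
  paste(chars, collapse = "")
}

#' Assemble a 142-nt oligonucleotide
#'
#' Concatenates fwd_const | handle | spacer | polyT | barcode | target |
#' rev_const, validating each element length against [oligo_layout()].
#'
#' @param spacer 23-nt spacer.
#' @param barcode 12-nt barcode.
#' @param target 42-nt target window beginning with the PAM.
#' @param handle 19-nt scaffold handle.
#' @param fwd_const,rev_const 20-nt constant ends.
#' @param polyT 6-nt poly-T terminator.
#' @return Single 142-nt string.
#' @seealso [parse_oligo()] for the inverse.
#' @export
assemble_oligo <- function(spacer, barcode, target,
                           handle = default_elements()[["handle"]],
                           fwd_const = default_elements()[["fwd_const"]],
                           rev_const = default_elements()[["rev_const"]],
                           polyT = "TTTTTT") {
  lay <- oligo_layout()
  check_len(fwd_const, "fwd_const", lay[["fwd_const"]])
  check_len(handle, "handle", lay[["handle"]])
  check_len(spacer, "spacer", lay[["spacer"]])
  check_len(polyT, "polyT", lay[["polyT"]])
  if (gsub("T", "", polyT) != "") {
    stop("field 'polyT' must be six thymidines", call. = FALSE)
  }
  check_len(barcode, "barcode", lay[["barcode"]])
  check_len(target, "target", lay[["target"]])
  check_len(rev_const, "rev_const", lay[["rev_const"]])
  paste0(fwd_const, handle, spacer, polyT, barcode, target, rev_const)
}

#' Split a 142-nt oligonucleotide into its elements
#'
#' Inverse of [assemble_oligo()]: fixed-width parsing by [oligo_layout()].
#'
#' @param oligo 142-nt string.
#' @return Named character vector of the seven elements.
#' @export
parse_oligo <- function(oligo) {
  lay <- oligo_layout()
  if (nchar(oligo) != sum(lay)) {
    stop("oligo must be exactly ", sum(lay), " nt, got ", nchar(oligo),
         call. = FALSE)
  }
  ends <- cumsum(lay)
  starts <- ends - lay + 1L
  out <- substring(oligo, starts, ends)
  names(out) <- names(lay)
  out
}

# 1-based offset of the target region within the full-length amplicon,
# and the fixed prefix length before it.
amplicon_prefix_len <- function() {
  lay <- oligo_layout()
  sum(lay[c("fwd_const", "handle", "spacer", "polyT", "barcode")])
}

#' Build full amplicon reference strings for a library
#'
#' @param library Library tibble from [design_library()].
#' @param handle,fwd_const,rev_const Element sequences.
#' @return Character vector of 142-nt reference amplicons, named by pair_id.
#' @export
reference_amplicons <- function(library,
                                handle = default_elements()[["handle"]],
                                fwd_const = default_elements()[["fwd_const"]],
                                rev_const = default_elements()[["rev_const"]]) {
  out <- mapply(assemble_oligo, library$spacer, library$barcode,
                library$target,
                MoreArgs = list(handle = handle, fwd_const = fwd_const,
                                rev_const = rev_const),
                USE.NAMES = FALSE)
  stats::setNames(out, library$pair_id)
}
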