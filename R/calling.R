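#' Indel-calling configuration
#'
#' @param primary_frame Half-open 0-based interval of the primary analysis
#'   frame; default the whole 42-nt target window `c(0, 42)`.
#' @param secondary_frame Half-open interval of width 8 centred on the middle
#'   of the staggered cleavage site (nicks at 22 and 27, midpoint 24.5);
#'   default `c(21, 29)`. Reads whose indels are all small and outside this
#'   frame are re-classified as background.
#' @param small_indel_max Largest indel length treated as "small" in the
#'   secondary filter, default 3.
#' @param substitution_policy `"count_in_frame"` (single-base substitutions
#'   inside the primary frame count as valid editing; recurring sequencing
#'   error types are removed by control subtraction) or `"ignore"`.
#' @param min_reads Pairs with (edited + unedited) reads not exceeding this
#'   are flagged excluded; default 300.
#' @param filtered_as_unedited If `TRUE` (default) background-filtered reads
#'   enter the frequency denominator as unedited; if `FALSE` they are dropped.
#' @param scores Alignment scores, see [align_scores()].
#' @return Object of class `calling_config`.
#' @export
calling_config <- function(primary_frame = c(0L, 42L),
                           secondary_frame = c(21L, 29L),
                           small_indel_max = 3L,
                           substitution_policy = c("count_in_frame", "ignore"),
                           min_reads = 300L,
                           filtered_as_unedited = TRUE,
                           scores = align_scores()) {
  substitution_policy <- match.arg(substitution_policy)
  stopifnot(length(primary_frame) == 2, length(secondary_frame) == 2,
            small_indel_max >= 1,
            secondary_frame[1] >= primary_frame[1],
            secondary_frame[2] <= primary_frame[2])
  structure(list(primary_frame = as.integer(primary_frame),
                 secondary_frame = as.integer(secondary_frame),
                 small_indel_max = as.integer(small_indel_max),
                 substitution_policy = substitution_policy,
                 min_reads = as.integer(min_reads),
                 filtered_as_unedited = filtered_as_unedited,
                 scores = scores),
            class = "calling_config")
}

# event/interval overlap with a half-open frame [a, b)
event_overlaps <- function(events, frame) {
  a <- frame[1]; b <- frame[2]
  ifelse(events$kind == "ins",
         events$start >= a & events$start <= b, # junction between start-1 and start
         events$start < b & events$start + events$length > a)
}

#' Build a demultiplexing index from a library table
#'
#' Keys reads by the crRNA-encoding sequence (19-nt handle + 23-nt spacer)
#' and the 12-nt barcode, both matched exactly at their fixed amplicon
#' offsets.
#'
#' @param library Library tibble.
#' @param handle Handle sequence shared by the library.
#' @return List used by [demultiplex()].
#' @export
library_index <- function(library, handle = default_elements()[["handle"]]) {
  if (anyDuplicated(library$barcode)) {
    stop("duplicate barcodes in library", call. = FALSE)
  }
  list(
    barcode_to_pair = stats::setNames(library$pair_id, library$barcode),
    pair_crrna = stats::setNames(paste0(handle, library$spacer),
                                 library$pair_id),
    pair_target = stats::setNames(library$target, library$pair_id),
    handle = handle
  )
}

#' Demultiplex amplicon reads by crRNA-encoding sequence and barcode
#'
#' A read is assigned to a pair iff its crRNA-encoding region (handle +
#' spacer) and its barcode both match the library exactly at their fixed
#' offsets. A recognized barcode with a mismatched crRNA region yields
#' `"invalid"` (editing could be impaired by an imperfect guide, so such
#' amplicons are excluded); an unrecognized barcode yields `"unassigned"`.
#' Unassigned reads get one reverse-complement rescue attempt.
#'
#' @param reads Character vector of read sequences.
#' @param index [library_index()].
#' @param rescue_revcomp Try reverse-complementing unassigned reads.
#' @return Tibble `read` (sequence), `pair_id` (NA unless assigned),
#'   `status` in `assigned` / `invalid` / `unassigned`; invalid reads carry
#'   the barcode-identified pair in `pair_id`.
#' @export
demultiplex <- function(reads, index, rescue_revcomp = TRUE) {
  lay <- oligo_layout()
  cr_start <- lay[["fwd_const"]] + 1L
  cr_end <- cr_start + lay[["handle"]] + lay[["spacer"]] - 1L
  bc_start <- cr_end + lay[["polyT"]] + 1L
  bc_end <- bc_start + lay[["barcode"]] - 1L

  classify_once <- function(rs) {
    n <- length(rs)
    pair_id <- rep(NA_character_, n)
    status <- rep("unassigned", n)
    long_enough <- nchar(rs) >= bc_end
    bc <- ifelse(long_enough, substring(rs, bc_start, bc_end),
                 NA_character_)
    pid <- unname(index$barcode_to_pair[bc])
    known <- !is.na(pid)
    cr <- substring(rs[known], cr_start, cr_end)
    ok <- cr == unname(index$pair_crrna[pid[known]])
    pair_id[known] <- pid[known]
    status[known] <- ifelse(ok, "assigned", "invalid")
    tibble::tibble(pair_id = pair_id, status = status)
  }

  res <- classify_once(reads)
  if (rescue_revcomp && any(res$status == "unassigned")) {
    idx <- which(res$status == "unassigned")
    rc <- revcomp(reads[idx])
    res2 <- classify_once(rc)
    hit <- res2$status != "unassigned"
    if (any(hit)) {
      reads[idx[hit]] <- rc[hit]
      res$pair_id[idx[hit]] <- res2$pair_id[hit]
      res$status[idx[hit]] <- res2$status[hit]
    }
  }
  tibble::tibble(read = reads, pair_id = res$pair_id, status = res$status)
}

#' Classify one aligned read
#'
#' Round 1: indels overlapping the primary frame are recognized. Round 2:
#' a read whose recognized indels are all of length `<= small_indel_max` and
#' all disjoint from the secondary frame is re-classified as background
#' (`"background_filtered"`). A read with no events (and no qualifying
#' substitution under the active policy) is `"unedited"`; otherwise
#' `"edited"`.
#'
#' @param events Indel event tibble from [align_target()].
#' @param substitutions Substitution tibble from [align_target()].
#' @param config [calling_config()].
#' @return One of `"edited"`, `"unedited"`, `"background_filtered"`.
#' @export
classify_read <- function(events, substitutions, config = calling_config()) {
  recognized <- events[event_overlaps(events, config$primary_frame), ,
                       drop = FALSE]
  subs_in_frame <- substitutions[
    substitutions$pos >= config$primary_frame[1] &
      substitutions$pos < config$primary_frame[2], , drop = FALSE]
  count_subs <- config$substitution_policy == "count_in_frame"

  if (nrow(recognized) == 0) {
    if (count_subs && nrow(subs_in_frame) > 0) return("edited")
    return("unedited")
  }
  small <- all(recognized$length <= config$small_indel_max)
  outside <- !any(event_overlaps(recognized, config$secondary_frame))
  if (small && outside) return("background_filtered")
  "edited"
}

# events actually catalogued for an edited read: recognized indels plus
# (under the literal substitution policy) in-frame substitutions
catalogued_events <- function(events, substitutions, config) {
  recognized <- events[event_overlaps(events, config$primary_frame), ,
                       drop = FALSE]
  if (config$substitution_policy == "count_in_frame" &&
      nrow(substitutions) > 0) {
    sif <- substitutions[substitutions$pos >= config$primary_frame[1] &
                           substitutions$pos < config$primary_frame[2], ,
                         drop = FALSE]
    if (nrow(sif) > 0) {
      recognized <- dplyr::bind_rows(
        recognized,
        event_tbl("sub", sif$pos, 1L, sif$read_base))
    }
  }
  sort_events(recognized)
}

#' Build per-pair editing profiles from demultiplexed reads
#'
#' Extracts the read-side target region of every assigned read (fixed prefix
#' before it, fixed-width constant after it), aligns non-reference regions
#' against the pair's 42-nt reference window, classifies each read and
#' aggregates identical event lists into repair types.
#'
#' @param demux Tibble from [demultiplex()].
#' @param index [library_index()].
#' @param config [calling_config()].
#' @return List with `profiles` (tibble: `pair_id`, `unedited`, `filtered`,
#'   `invalid`, `edited_total`) and `catalogue` (tibble: `pair_id`,
#'   `repair_type` (event-list key), `count`).
#' @export
build_profiles <- function(demux, index, config = calling_config()) {
  lay <- oligo_layout()
  pre <- amplicon_prefix_len()
  rev_len <- lay[["rev_const"]]

  pair_ids <- names(index$pair_crrna)
  counts <- tibble::tibble(pair_id = pair_ids, unedited = 0L, filtered = 0L,
                           invalid = 0L, edited_total = 0L)
  cat_out <- list()

  inv <- table(demux$pair_id[demux$status == "invalid"])
  counts$invalid <- as.integer(inv[counts$pair_id])
  counts$invalid[is.na(counts$invalid)] <- 0L

  assigned <- demux[demux$status == "assigned", , drop = FALSE]
  if (nrow(assigned) > 0) {
    by_pair <- split(assigned$read, assigned$pair_id)
    for (pid in names(by_pair)) {
      reads <- by_pair[[pid]]
      ref <- unname(index$pair_target[pid])
      region <- substring(reads, pre + 1L, nchar(reads) - rev_len)
      # classify each distinct region once; reads sharing it share the call
      tab <- table(region)
      uniq <- names(tab)
      nread <- as.integer(tab)
      aln <- align_target(uniq, ref, scores = config$scores)
      cls <- character(length(aln))
      keys <- rep(NA_character_, length(aln))
      for (i in seq_along(aln)) {
        cls[i] <- classify_read(aln[[i]]$events, aln[[i]]$substitutions,
                                config)
        if (cls[i] == "edited") {
          keys[i] <- event_list_key(
            catalogued_events(aln[[i]]$events, aln[[i]]$substitutions, config))
        }
      }
      row <- which(counts$pair_id == pid)
      counts$unedited[row] <- sum(nread[cls == "unedited"])
      counts$filtered[row] <- sum(nread[cls == "background_filtered"])
      counts$edited_total[row] <- sum(nread[cls == "edited"])
      if (any(cls == "edited")) {
        ed <- cls == "edited"
        agg <- tapply(nread[ed], keys[ed], sum)
        cat_out[[pid]] <- tibble::tibble(pair_id = pid,
                                         repair_type = names(agg),
                                         count = as.integer(agg))
      }
    }
  }
  catalogue <- if (length(cat_out) > 0) dplyr::bind_rows(cat_out)
               else tibble::tibble(pair_id = character(),
                                   repair_type = character(),
                                   count = integer())
  list(profiles = counts, catalogue = catalogue)
}

#' Subtract control background repair types from experimental profiles
#'
#' Only editing types occurring uniquely in the experimental group are kept
#' as effector-induced; any repair type whose event list also appears in the
#' same pair's control catalogue is removed and its reads re-counted as
#' unedited. Pairs absent from the control are processed against an empty
#' control catalogue (and reported in the `missing_control` attribute).
#'
#' @param experimental,control Lists from [build_profiles()].
#' @return List like `experimental` with background types removed.
#' @export
subtract_background <- function(experimental, control) {
  ctl_keys <- paste(control$catalogue$pair_id, control$catalogue$repair_type,
                    sep = "\r")
  exp_cat <- experimental$catalogue
  keys <- paste(exp_cat$pair_id, exp_cat$repair_type, sep = "\r")
  is_bg <- keys %in% ctl_keys
  removed <- exp_cat[is_bg, , drop = FALSE]
  kept <- exp_cat[!is_bg, , drop = FALSE]

  profiles <- experimental$profiles
  if (nrow(removed) > 0) {
    back <- removed |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop")
    idx <- match(back$pair_id, profiles$pair_id)
    profiles$unedited[idx] <- profiles$unedited[idx] + back$n
    profiles$edited_total[idx] <- profiles$edited_total[idx] - back$n
  }
  missing_control <- setdiff(unique(exp_cat$pair_id),
                             unique(control$profiles$pair_id))
  structure(list(profiles = profiles, catalogue = kept),
            missing_control = missing_control)
}

#' Compute per-pair indel frequencies
#'
#' frequency = edited / (edited + unedited), with background-filtered reads
#' counted as unedited in the denominator by default. Pairs whose
#' (edited + unedited) total does not exceed `min_reads` are flagged
#' `excluded` (as are pairs with a zero denominator).
#'
#' @param profiles Profile tibble (after [subtract_background()]).
#' @param config [calling_config()].
#' @return Tibble: `pair_id`, `edited_total`, `unedited_total`,
#'   `indel_frequency`, `excluded`.
#' @export
indel_frequency <- function(profiles, config = calling_config()) {
  unedited <- profiles$unedited +
    if (config$filtered_as_unedited) profiles$filtered else 0L
  denom <- profiles$edited_total + unedited
  freq <- ifelse(denom > 0, profiles$edited_total / denom, NA_real_)
  tibble::tibble(
    pair_id = profiles$pair_id,
    edited_total = profiles$edited_total,
    unedited_total = unedited,
    indel_frequency = freq,
    excluded = denom <= config$min_reads | denom == 0
  )
}

#' Full indel-calling pass: demultiplex, align, classify, subtract, quantify
#'
#' @param exp_reads,ctrl_reads Character vectors of experimental resp.
#'   control amplicon reads (or tibbles with a `seq` column).
#' @param library Library tibble.
#' @param config [calling_config()].
#' @param handle Scaffold handle used by the library.
#' @return List: `frequencies` (tibble from [indel_frequency()]),
#'   `profiles`, `catalogue` (background-subtracted), `demux_summary`.
#' @export
call_indels <- function(exp_reads, ctrl_reads, library,
                        config = calling_config(),
                        handle = default_elements()[["handle"]]) {
  get_seq <- function(x) if (is.data.frame(x)) x$seq else x
  index <- library_index(library, handle = handle)
  dx_e <- demultiplex(get_seq(exp_reads), index)
  dx_c <- demultiplex(get_seq(ctrl_reads), index)
  prof_e <- build_profiles(dx_e, index, config)
  prof_c <- build_profiles(dx_c, index, config)
  sub <- subtract_background(prof_e, prof_c)
  freq <- indel_frequency(sub$profiles, config)
  list(
    frequencies = freq,
    profiles = sub$profiles,
    catalogue = sub$catalogue,
    control_profiles = prof_c$profiles,
    demux_summary = tibble::tibble(
      group = c("experimental", "control"),
      assigned = c(sum(dx_e$status == "assigned"),
                   sum(dx_c$status == "assigned")),
      invalid = c(sum(dx_e$status == "invalid"),
                  sum(dx_c$status == "invalid")),
      unassigned = c(sum(dx_e$status == "unassigned"),
                     sum(dx_c$status == "unassigned"))
    )
  )
}
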