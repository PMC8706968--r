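#' Effector activity model for read simulation
#'
#' Describes one Cas12a effector for the generator: a per-PAM editing
#' probability, the fraction of edited molecules repaired by MMEJ, and the
#' positions of the two staggered nicks in target coordinates. The default
#' nicks (22, 27) place the cut 18/23 nt distal of the 4-nt PAM, the
#' canonical Cas12a staggered geometry.
#'
#' @param name Effector identifier.
#' @param pam_activity Named numeric vector mapping concrete 4-nt PAMs to
#'   editing probabilities in `[0, 1]`. PAMs absent from the map are an error
#'   at simulation time (no silent default).
#' @param mmej_weight Fraction of edited reads routed through MMEJ, default 0.5.
#' @param cut_positions Integer pair (non-target-strand nick, target-strand
#'   nick) as 0-based offsets from the target start.
#' @param nhej_del_prob Probability that an NHEJ outcome is a deletion rather
#'   than a 1-3-nt insertion, default 0.75 (Cas12a outcomes are
#'   deletion-dominated).
#' @param nhej_del_geom_p Geometric parameter for NHEJ deletion lengths,
#'   default 0.3, truncated at `nhej_del_max`.
#' @param nhej_del_max Maximum NHEJ deletion length, default 20.
#' @param ins_max Maximum NHEJ insertion length, default 3.
#' @return Object of class `effector_model`.
#' @export
effector_model <- function(name, pam_activity, mmej_weight = 0.5,
                           cut_positions = c(22L, 27L),
                           nhej_del_prob = 0.75, nhej_del_geom_p = 0.3,
                           nhej_del_max = 20L, ins_max = 3L) {
  stopifnot(all(pam_activity >= 0), all(pam_activity <= 1),
            mmej_weight >= 0, mmej_weight <= 1,
            length(cut_positions) == 2,
            all(cut_positions >= 0), all(cut_positions < 42))
  structure(list(name = name, pam_activity = pam_activity,
                 mmej_weight = mmej_weight,
                 cut_positions = as.integer(cut_positions),
                 nhej_del_prob = nhej_del_prob,
                 nhej_del_geom_p = nhej_del_geom_p,
                 nhej_del_max = as.integer(nhej_del_max),
                 ins_max = as.integer(ins_max)),
            class = "effector_model")
}

#' @export
print.effector_model <- function(x, ...) {
  cat("<effector_model>", x$name, "\n",
      " PAMs:", length(x$pam_activity),
      " mmej_weight:", x$mmej_weight,
      " nicks:", paste(x$cut_positions, collapse = "/"), "\n")
  invisible(x)
}

#' Background noise model for read simulation
#'
#' Background in this assay has three components, reflecting where errors
#' arise in a paired guide-target screen:
#' \itemize{
#'   \item Clonal library variants: oligo-synthesis indels live in the
#'     integrated construct pool. The control group is the same established
#'     cell library without effector delivery, so variant haplotypes (and
#'     their frequencies) are shared between experimental and control reads.
#'   \item Systematic substitution errors: sequencing substitution errors
#'     concentrate at run-specific error-prone positions shared across the
#'     samples of a run; the expected per-base rate `substitution_rate` is
#'     carried by `systematic_sites` pair-specific sites.
#'   \item Stochastic artifacts: a small per-read probability
#'     `background_indel_rate` of an i.i.d. indel miscall of length up to
#'     `artifact_len_max` anywhere in the read.
#' }
#' Control-differential subtraction removes the first two components by
#' construction; the small-indel frame filter removes most of the third.
#'
#' @param substitution_rate Expected per-base substitution error rate,
#'   default 1e-3.
#' @param background_indel_rate Per-read probability of an i.i.d. artifact
#'   indel, default 1e-4.
#' @param artifact_len_max Maximum artifact indel length, default 3.
#' @param systematic_sites Number of pair-specific substitution-error sites
#'   per amplicon, default 3.
#' @param variant_rate Poisson mean number of clonal library variants per
#'   pair, default 0.3.
#' @param variant_abundance Length-2 range of per-variant haplotype
#'   frequencies, default `c(0.005, 0.02)`.
#' @param variant_len_max Maximum variant indel length, default 3.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(substitution_rate = 1e-3,
                        background_indel_rate = 1e-4,
                        artifact_len_max = 3L,
                        systematic_sites = 3L,
                        variant_rate = 0.3,
                        variant_abundance = c(0.005, 0.02),
                        variant_len_max = 3L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            background_indel_rate >= 0, background_indel_rate <= 1,
            artifact_len_max >= 1)
  structure(list(substitution_rate = substitution_rate,
                 background_indel_rate = background_indel_rate,
                 artifact_len_max = as.integer(artifact_len_max),
                 systematic_sites = as.integer(systematic_sites),
                 variant_rate = variant_rate,
                 variant_abundance = variant_abundance,
                 variant_len_max = as.integer(variant_len_max)),
            class = "noise_model")
}

#' Zero-noise model (reads are exact apart from editing)
#' @return A `noise_model` with all rates zero.
#' @export
noise_off <- function() {
  noise_model(substitution_rate = 0, background_indel_rate = 0,
              systematic_sites = 0L, variant_rate = 0)
}

BASES <- c("A", "C", "G", "T")

# Draw one repair outcome event list for a target; internal core shared by
# simulate_repair() and generate_dataset(). Assumes RNG state is set.
draw_repair_events <- function(target, effector, mh = NULL) {
  cuts <- effector$cut_positions
  if (is.null(mh)) {
    mh <- find_microhomologies(target, min_len = 2)
  }
  # MMEJ candidates must span the staggered-cut interval
  el <- mh[mh$deletion_start < cuts[2] &
             mh$deletion_start + mh$deletion_len > cuts[1], , drop = FALSE]
  use_mmej <- nrow(el) > 0 && stats::runif(1) < effector$mmej_weight
  if (use_mmej) {
    i <- sample.int(nrow(el), 1, prob = el$mh_len)
    return(event_tbl("del", el$deletion_start[i], el$deletion_len[i], ""))
  }
  # NHEJ: deletion covering one nick, or a short insertion at a nick
  L <- nchar(target)
  if (stats::runif(1) < effector$nhej_del_prob) {
    len <- min(1L + stats::rgeom(1, effector$nhej_del_geom_p),
               effector$nhej_del_max)
    nick <- sample(cuts, 1)
    lo <- max(0L, nick - len); hi <- min(nick, L - len)
    if (hi < lo) { len <- 1L; lo <- max(0L, nick - 1L); hi <- min(nick, L - 1L) }
    start <- sample(seq(lo, hi), 1)
    event_tbl("del", start, len, "")
  } else {
    len <- sample.int(effector$ins_max, 1)
    nick <- sample(cuts, 1)
    pos <- min(max(nick + sample(-1:1, 1), 1L), L - 1L)
    event_tbl("ins", pos, len,
              paste(sample(BASES, len, replace = TRUE), collapse = ""))
  }
}

#' Simulate one repair outcome for a guide-target pair
#'
#' With probability `pam_activity[pam]` the molecule is edited: the MMEJ
#' branch collapses a microhomology deletion spanning the staggered-cut
#' interval (chosen with probability proportional to microhomology length);
#' the NHEJ branch emits a deletion covering one nick or a 1-3-nt insertion
#' at a nick. Otherwise the molecule is unedited.
#'
#' @param pair One-row tibble (or list) with `pam` and `target`.
#' @param effector [effector_model()].
#' @param seed Integer seed; fixed seed gives identical outcomes.
#' @return Event tibble; zero rows means unedited.
#' @export
simulate_repair <- function(pair, effector, seed = 1) {
  pam <- pair$pam
  if (!pam %in% names(effector$pam_activity)) {
    stop("PAM '", pam, "' absent from effector pam_activity map", call. = FALSE)
  }
  p <- effector$pam_activity[[pam]]
  with_seed(seed, {
    if (stats::runif(1) >= p) event_tbl()
    else draw_repair_events(pair$target, effector)
  })
}

# per-pair shared noise profile (identical for experimental and control)
pair_noise_profile <- function(amp, noise) {
  amp_len <- nchar(amp)
  n_var <- stats::rpois(1, noise$variant_rate)
  variants <- NULL
  if (n_var > 0) {
    variants <- lapply(seq_len(n_var), function(i) {
      kind <- if (stats::runif(1) < 0.8) "del" else "ins"
      len <- sample.int(noise$variant_len_max, 1,
                        prob = c(0.8, 0.15, 0.05)[seq_len(noise$variant_len_max)])
      pos <- sample.int(amp_len - len, 1) - 1L
      seqs <- if (kind == "ins")
        paste(sample(BASES, len, replace = TRUE), collapse = "") else ""
      list(events = event_tbl(kind, pos, len, seqs),
           abundance = stats::runif(1, noise$variant_abundance[1],
                                    noise$variant_abundance[2]))
    })
  }
  sites <- NULL
  if (noise$systematic_sites > 0 && noise$substitution_rate > 0) {
    pos <- sample.int(amp_len, noise$systematic_sites)
    alt <- vapply(pos, function(p) {
      sample(setdiff(BASES, substr(amp, p, p)), 1)
    }, character(1))
    rate <- noise$substitution_rate * amp_len / noise$systematic_sites
    sites <- list(pos = pos, alt = alt, rate = min(rate, 1))
  }
  list(variants = variants, sites = sites)
}

substitute_at <- function(seqs, pos, alt) {
  # vectorized single-base substitution at 1-based pos (skip if beyond length)
  ok <- pos <= nchar(seqs)
  if (any(ok)) {
    substr(seqs[ok], pos[ok], pos[ok]) <- alt[ok]
  }
  seqs
}

apply_read_noise <- function(seqs, profile, noise) {
  # Each read carries at most one background lesion: a systematic
  # substitution OR an i.i.d. artifact indel (and variant-haplotype reads
  # receive neither — the caller excludes them). Per-read error
  # probabilities are small, so co-occurrence (~0.2% of reads) is neglected;
  # every substitution error type is then a single-site type that recurs in
  # the control and is removed by subtraction.
  n <- length(seqs)
  p_sub <- if (is.null(profile$sites)) 0
           else min(profile$sites$rate * length(profile$sites$pos), 1)
  u <- stats::runif(n)
  if (p_sub > 0) {
    hit <- which(u < p_sub)
    if (length(hit) > 0) {
      k <- sample.int(length(profile$sites$pos), length(hit), replace = TRUE)
      seqs[hit] <- substitute_at(seqs[hit], profile$sites$pos[k],
                                 profile$sites$alt[k])
    }
  }
  if (noise$background_indel_rate > 0) {
    hit <- which(u >= p_sub & u < p_sub + noise$background_indel_rate)
    for (i in hit) {
      L <- nchar(seqs[i])
      len <- sample.int(noise$artifact_len_max, 1)
      if (stats::runif(1) < 0.5 && L > len) { # deletion
        pos <- sample.int(L - len, 1)
        seqs[i] <- paste0(substr(seqs[i], 1, pos - 1),
                          substr(seqs[i], pos + len, L))
      } else { # insertion
        pos <- sample.int(L, 1)
        seqs[i] <- paste0(substr(seqs[i], 1, pos),
                          paste(sample(BASES, len, replace = TRUE),
                                collapse = ""),
                          substr(seqs[i], pos + 1, L))
      }
    }
  }
  seqs
}

#' Generate experimental and control amplicon datasets with known truth
#'
#' For every library pair, emits `depth_per_pair` experimental reads (editing
#' probability taken from the effector's PAM activity map) and
#' `depth_per_pair` control reads (editing forced off), both passed through
#' the same noise model: clonal library variants and systematic substitution
#' sites are drawn once per pair and shared between the two groups, while
#' read-level noise is independent.
#'
#' @param library Library tibble from [design_library()] (unique barcodes
#'   required).
#' @param effector [effector_model()]; every PAM present in the library must
#'   be in its activity map.
#' @param noise [noise_model()].
#' @param depth_per_pair Reads per pair and group, default 1000.
#' @param seed Integer seed; everything is reproducible from it.
#' @param elements Named vector with `fwd_const`, `handle`, `rev_const`.
#' @param edit_rates Optional named numeric vector (pair_id -> editing
#'   probability) overriding the effector's per-PAM activities, e.g. to give
#'   each guide its own intrinsic activity. Must cover every library pair.
#' @return List with tibbles `experimental` and `control` (`read_id`, `seq`)
#'   and `truth` (`pair_id`, `true_edit_rate`, `repair_type`, `count`;
#'   unedited molecules appear as `repair_type == "[]"`).
#' @export
generate_dataset <- function(library, effector, noise = noise_model(),
                             depth_per_pair = 1000, seed = 1,
                             elements = default_elements(),
                             edit_rates = NULL) {
  stopifnot(depth_per_pair >= 1)
  if (anyDuplicated(library$barcode)) {
    stop("duplicate barcodes in library", call. = FALSE)
  }
  if (is.null(edit_rates)) {
    missing_pam <- setdiff(unique(library$pam), names(effector$pam_activity))
    if (length(missing_pam) > 0) {
      stop("PAM(s) absent from effector pam_activity map: ",
           paste(missing_pam, collapse = ", "), call. = FALSE)
    }
  } else {
    missing_pair <- setdiff(library$pair_id, names(edit_rates))
    if (length(missing_pair) > 0) {
      stop("edit_rates missing pair(s): ",
           paste(utils::head(missing_pair, 5), collapse = ", "),
           call. = FALSE)
    }
    stopifnot(all(edit_rates >= 0), all(edit_rates <= 1))
  }
  refs <- reference_amplicons(library, handle = elements[["handle"]],
                              fwd_const = elements[["fwd_const"]],
                              rev_const = elements[["rev_const"]])
  pre <- amplicon_prefix_len()
  lay <- oligo_layout()

  exp_out <- vector("list", nrow(library))
  ctl_out <- vector("list", nrow(library))
  truth <- vector("list", nrow(library))

  with_seed(seed, {
    for (i in seq_len(nrow(library))) {
      pair <- library[i, ]
      p_edit <- if (!is.null(edit_rates)) edit_rates[[pair$pair_id]]
                else effector$pam_activity[[pair$pam]]
      amp <- refs[[i]]
      amp_len <- nchar(amp)
      profile <- pair_noise_profile(amp, noise)
      mh <- find_microhomologies(pair$target, min_len = 2)
      prefix <- substr(amp, 1, pre)
      suffix <- substr(amp, pre + lay[["target"]] + 1, amp_len)

      emit_group <- function(p, tag) {
        n <- depth_per_pair
        # haplotype choice: clonal variants are not editable molecules
        var_ab <- vapply(profile$variants, function(v) v$abundance,
                         numeric(1)) %||% numeric(0)
        u <- stats::runif(n)
        hap <- findInterval(u, cumsum(var_ab)) + 1L # k+1 = reference
        is_ref <- hap > length(var_ab)
        edited <- is_ref & (stats::runif(n) < p)
        keys <- character(n)
        seqs <- character(n)
        # unedited reference molecules
        seqs[is_ref & !edited] <- amp
        keys[is_ref & !edited] <- "[]"
        # variant molecules
        if (length(var_ab) > 0) {
          for (k in seq_along(var_ab)) {
            idx <- which(hap == k)
            if (length(idx) == 0) next
            seqs[idx] <- apply_events(amp, profile$variants[[k]]$events)
            keys[idx] <- "[]" # truth tracks effector edits only
          }
        }
        # edited molecules: draw outcomes, group identical ones
        idx_e <- which(edited)
        if (length(idx_e) > 0) {
          evs <- lapply(idx_e, function(.)
            draw_repair_events(pair$target, effector, mh = mh))
          ks <- vapply(evs, event_list_key, character(1))
          uk <- !duplicated(ks)
          built <- vapply(which(uk), function(j) {
            paste0(prefix, apply_events(pair$target, evs[[j]]), suffix)
          }, character(1))
          names(built) <- ks[uk]
          seqs[idx_e] <- built[ks]
          keys[idx_e] <- ks
        }
        noisy <- is_ref # variant-haplotype reads carry their lesion only
        seqs[noisy] <- apply_read_noise(seqs[noisy], profile, noise)
        list(seqs = tibble::tibble(
               read_id = sprintf("%s_%s_%04d", pair$pair_id, tag, seq_len(n)),
               seq = seqs),
             keys = keys)
      }

      eg <- emit_group(p_edit, "exp")
      cg <- emit_group(0, "ctl")
      exp_out[[i]] <- eg$seqs
      ctl_out[[i]] <- cg$seqs
      tt <- table(eg$keys)
      truth[[i]] <- tibble::tibble(pair_id = pair$pair_id,
                                   true_edit_rate = p_edit,
                                   repair_type = names(tt),
                                   count = as.integer(tt))
    }
  })

  list(experimental = dplyr::bind_rows(exp_out),
       control = dplyr::bind_rows(ctl_out),
       truth = dplyr::bind_rows(truth))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
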