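#' Mean indel frequency by PAM group
#'
#' Averages per-pair indel frequencies over the pairs whose concrete PAM
#' falls in each degenerate group's expansion. Excluded (low-read) pairs are
#' dropped, never imputed. Groups may overlap; empty groups are reported
#' with `n_targets = 0` and `NA` mean.
#'
#' @param frequencies Tibble from [indel_frequency()].
#' @param library Library tibble (supplies each pair's PAM).
#' @param groups Character vector of IUPAC PAM patterns (or concrete PAMs).
#' @param effector Optional effector label carried into the output.
#' @return Tibble: `effector`, `pam_group`, `mean_frequency`,
#'   `median_frequency`, `n_targets`.
#' @export
summarize_by_pam <- function(frequencies, library, groups,
                             effector = NA_character_) {
  dat <- dplyr::inner_join(frequencies, library[, c("pair_id", "pam")],
                           by = "pair_id")
  dat <- dat[!dat$excluded & !is.na(dat$indel_frequency), , drop = FALSE]
  purrr::map_dfr(groups, function(g) {
    members <- expand_pattern(g)
    sel <- dat[dat$pam %in% members, , drop = FALSE]
    tibble::tibble(
      effector = effector, pam_group = g,
      mean_frequency = if (nrow(sel) > 0) mean(sel$indel_frequency) else NA_real_,
      median_frequency = if (nrow(sel) > 0) stats::median(sel$indel_frequency)
                         else NA_real_,
      n_targets = nrow(sel)
    )
  })
}

#' Classify a repair type as MMEJ or NHEJ
#'
#' A repair type is called MMEJ iff it is a single deletion whose junction
#' collapses two identical flanking sequences of length at least `mh_min` in
#' the reference (i.e. it is producible by microhomology-mediated end
#' joining, consistent with [find_microhomologies()]). Everything else —
#' insertions, multi-event types, deletions in repeat-free context — is NHEJ.
#'
#' @param events Event tibble (at least one event).
#' @param reference Reference target window.
#' @param mh_min Minimum microhomology length, default 2.
#' @return `"MMEJ"` or `"NHEJ"`.
#' @export
classify_pathway <- function(events, reference, mh_min = 2) {
  stopifnot(nrow(events) >= 1)
  if (nrow(events) != 1 || events$kind != "del") return("NHEJ")
  mh <- find_microhomologies(reference, min_len = mh_min)
  hit <- mh$deletion_start == events$start & mh$deletion_len == events$length
  if (any(hit)) "MMEJ" else "NHEJ"
}

#' Repair-type spectrum of an edited catalogue
#'
#' @param catalogue Tibble with `repair_type` and `count` for one pair.
#' @return Tibble `repair_type`, `count`, `proportion` (of edited reads),
#'   sorted by descending proportion; zero rows if nothing is edited.
#' @export
repair_type_spectrum <- function(catalogue) {
  if (nrow(catalogue) == 0 || sum(catalogue$count) == 0) {
    return(tibble::tibble(repair_type = character(), count = integer(),
                          proportion = double()))
  }
  catalogue |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$repair_type) |>
    dplyr::select("repair_type", "count", "proportion")
}

#' Pearson correlation of indel frequencies between two replicates
#'
#' @param freq_a,freq_b Tibbles from [indel_frequency()]; only pairs present
#'   and non-excluded in both enter the correlation.
#' @return Tibble: `test`, `statistic` (r), `p_value`, `n`.
#' @export
replicate_correlation <- function(freq_a, freq_b) {
  shared <- dplyr::inner_join(
    freq_a[!freq_a$excluded, c("pair_id", "indel_frequency")],
    freq_b[!freq_b$excluded, c("pair_id", "indel_frequency")],
    by = "pair_id", suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stop("need at least 3 shared non-excluded pairs, got ", nrow(shared),
         call. = FALSE)
  }
  ct <- stats::cor.test(shared$indel_frequency_a, shared$indel_frequency_b,
                        method = "pearson")
  tibble::tibble(test = "pearson", statistic = unname(ct$estimate),
                 p_value = ct$p.value, n = nrow(shared))
}

# Mann-Whitney U from the two samples (ties share average ranks):
# U = sum over pairs of [x > y] + 0.5 [x == y]
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  ra <- sum(r[seq_along(a)])
  ra - length(a) * (length(a) + 1) / 2
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact permutation p-value (correct under ties) when the pooled sample is
#' small (`n_a + n_b <= exact_max`); otherwise the tie-corrected normal
#' approximation with continuity correction. Two-tailed p is the probability
#' of a U at least as far from its null mean as observed.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param exact_max Largest pooled size for exact enumeration, default 10.
#' @return Tibble: `test`, `statistic` (U of `group_a`), `p_value`, `n_a`,
#'   `n_b`, `method` (exact/normal).
#' @export
compare_two <- function(group_a, group_b, exact_max = 10) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b)
  u_obs <- u_statistic(group_a, group_b)
  mu <- na * nb / 2
  if (na + nb <= exact_max) {
    pooled <- c(group_a, group_b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    r <- rank(c(group_a, group_b))
    n <- na + nb
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * (n + 1 - tie_term)
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "normal"
  }
  tibble::tibble(test = "mann_whitney_u", statistic = u_obs, p_value = p,
                 n_a = na, n_b = nb, method = method)
}

# tie-corrected Dunn z for groups i, j given pooled ranks
dunn_posthoc <- function(values, labels, adjust = "bonferroni") {
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- split(r, labels)
  means <- vapply(groups, mean, numeric(1))
  sizes <- vapply(groups, length, numeric(1))
  cmb <- utils::combn(names(groups), 2)
  out <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1, k]; g2 <- cmb[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (means[[g1]] - means[[g2]]) / se
    tibble::tibble(test = "dunn_posthoc",
                   groups = paste(g1, g2, sep = " vs "),
                   statistic = z,
                   p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus H test (tie-corrected) across three or more groups, followed
#' by Dunn's pairwise z tests on the pooled ranks with multiplicity
#' adjustment (Bonferroni by default, any [stats::p.adjust()] method).
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @param adjust Adjustment method for the Dunn p-values.
#' @return Tibble of results: one `kruskal_wallis` row (statistic = H) and
#'   one `dunn_posthoc` row per pair with `p_adjusted`.
#' @export
compare_many <- function(groups, adjust = "bonferroni") {
  if (length(groups) < 3) {
    stop("need at least 3 groups; use compare_two() for two", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  kw <- stats::kruskal.test(values, factor(labels))
  omnibus <- tibble::tibble(test = "kruskal_wallis",
                            groups = paste(names(groups), collapse = ", "),
                            statistic = unname(kw$statistic),
                            p_value = kw$p.value, p_adjusted = NA_real_)
  dplyr::bind_rows(omnibus, dunn_posthoc(values, labels, adjust))
}

#' Rank effectors by mean indel frequency
#'
#' Sorts descending by mean frequency (ties broken by effector name) and
#' splits into high/low categories at `threshold` — a reporting convention
#' mirroring the descriptive 20% split between high- and low-activity
#' orthologues, not an inference.
#'
#' @param means Named numeric vector: effector -> mean indel frequency.
#' @param threshold Category boundary, default 0.20.
#' @return Tibble: `effector`, `mean_frequency`, `category`.
#' @export
rank_effectors <- function(means, threshold = 0.20) {
  stopifnot(length(means) >= 1)
  ord <- order(-means, names(means))
  tibble::tibble(
    effector = names(means)[ord],
    mean_frequency = unname(means)[ord],
    category = ifelse(unname(means)[ord] >= threshold, "high", "low")
  )
}
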