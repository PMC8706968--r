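# Independent brute-force oracles used by the tests. These deliberately take
# the slow, exhaustive route so they share no code path with the package.

# --- exhaustive affine global alignment ------------------------------------
# Enumerates ALL maximum-score global alignments of read vs ref under affine
# scores and returns the canonical (lexicographically smallest) event list:
# events ordered by (start, del<ins, length, seq), lists compared
# elementwise. Substitution positions break remaining ties.
oracle_align <- function(read, ref, scores = align_scores(),
                         max_paths = 50000) {
  P <- strsplit(read, "", fixed = TRUE)[[1]]
  S <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(P); m <- length(S)
  ms <- scores$match; mm <- scores$mismatch
  go <- scores$gap_open; ge <- scores$gap_extend
  NEG <- -1e18

  M <- matrix(NEG, n + 1, m + 1) # P[i] aligned to S[j]
  D <- matrix(NEG, n + 1, m + 1) # gap in read (ref char consumed)
  I <- matrix(NEG, n + 1, m + 1) # gap in ref (read char consumed)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) D[1, j] <- go + ge * (j - 1)
  for (i in 2:(n + 1)) I[i, 1] <- go + ge * (i - 1)
  for (i in 2:(n + 1)) {
    sub_i <- ifelse(P[i - 1] == S, ms, mm)
    for (j in 2:(m + 1)) {
      s <- sub_i[j - 1]
      M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      D[i, j] <- max(M[i, j - 1] + go + ge, D[i, j - 1] + ge,
                     I[i, j - 1] + go + ge)
      I[i, j] <- max(M[i - 1, j] + go + ge, I[i - 1, j] + ge,
                     D[i - 1, j] + go + ge)
    }
  }
  best <- max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])

  paths <- list()
  eps <- 1e-9
  # walk backwards collecting ops: "M" consumes (i,j), "D" consumes j, "I" i
  recurse <- function(i, j, state, ops) {
    if (length(paths) >= max_paths) return()
    if (i == 1 && j == 1) {
      if (state == "M") paths[[length(paths) + 1L]] <<- rev(ops)
      return()
    }
    if (state == "M") {
      if (i == 1 || j == 1) return()
      s <- if (P[i - 1] == S[j - 1]) ms else mm
      target <- M[i, j] - s
      for (prev in c("M", "D", "I")) {
        val <- switch(prev, M = M[i - 1, j - 1], D = D[i - 1, j - 1],
                      I = I[i - 1, j - 1])
        if (abs(val - target) < eps) {
          recurse(i - 1, j - 1, prev, c(ops, "M"))
        }
      }
    } else if (state == "D") {
      if (j == 1) return()
      if (abs(D[1, j] - D[i, j]) < eps && i == 1 && j >= 2) {
        # initial run handled by generic cases below as well
      }
      if (i == 1 && j == 2) { # initial gap reaches origin via open
        if (abs(D[i, j] - (go + ge)) < eps) {
          recurse(1, 1, "M", c(ops, "D"))
        }
        return()
      }
      for (prev in c("M", "D", "I")) {
        val <- switch(prev, M = M[i, j - 1] + go + ge, D = D[i, j - 1] + ge,
                      I = I[i, j - 1] + go + ge)
        if (abs(val - D[i, j]) < eps) {
          recurse(i, j - 1, prev, c(ops, "D"))
        }
      }
    } else {
      if (i == 1) return()
      if (j == 1 && i == 2) {
        if (abs(I[i, j] - (go + ge)) < eps) {
          recurse(1, 1, "M", c(ops, "I"))
        }
        return()
      }
      for (prev in c("M", "D", "I")) {
        val <- switch(prev, M = M[i - 1, j] + go + ge, I = I[i - 1, j] + ge,
                      D = D[i - 1, j] + go + ge)
        if (abs(val - I[i, j]) < eps) {
          recurse(i - 1, j, prev, c(ops, "I"))
        }
      }
    }
  }
  for (st in c("M", "D", "I")) {
    val <- switch(st, M = M[n + 1, m + 1], D = D[n + 1, m + 1],
                  I = I[n + 1, m + 1])
    if (abs(val - best) < eps) recurse(n + 1, m + 1, st, character(0))
  }

  path_to_result <- function(ops) {
    i <- 0L; j <- 0L # consumed so far
    ev <- list(); subs <- integer(0)
    k <- 1L
    while (k <= length(ops)) {
      if (ops[k] == "M") {
        i <- i + 1L; j <- j + 1L
        if (P[i] != S[j]) subs <- c(subs, j - 1L)
        k <- k + 1L
      } else if (ops[k] == "D") {
        start <- j
        while (k <= length(ops) && ops[k] == "D") { j <- j + 1L; k <- k + 1L }
        ev[[length(ev) + 1L]] <- list(kind = "del", start = start,
                                      length = j - start, seq = "")
      } else {
        i0 <- i; start <- j
        while (k <= length(ops) && ops[k] == "I") { i <- i + 1L; k <- k + 1L }
        ev[[length(ev) + 1L]] <- list(kind = "ins", start = start,
                                      length = i - i0,
                                      seq = paste(P[(i0 + 1L):i], collapse = ""))
      }
    }
    events <- if (length(ev) > 0) dplyr::bind_rows(lapply(ev, tibble::as_tibble))
              else tibble::tibble(kind = character(), start = integer(),
                                  length = integer(), seq = character())
    list(events = events, subs = subs)
  }

  # canonical = fewest indel events, then fewest substitutions, then the
  # lexicographically smallest forward op string under D < I < M (which
  # yields leftmost gap placements)
  key_of <- function(ops, res) {
    paste0(sprintf("%04d", nrow(res$events)), "|",
           sprintf("%04d", length(res$subs)), "|",
           chartr("DIM", "012", paste(ops, collapse = "")))
  }

  results <- lapply(paths, path_to_result)
  keys <- mapply(key_of, paths, results)
  canonical <- results[[order(keys)[1]]]
  list(events = canonical$events, n_sub = length(canonical$subs),
       score = best, n_optimal = length(paths))
}

# --- naive protospacer scan ------------------------------------------------
oracle_scan_plus <- function(sequence, pattern, spacer_len) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
               M = c("A", "C"), S = c("C", "G"), W = c("A", "T"),
               B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pl <- nchar(pattern)
  psym <- strsplit(pattern, "", fixed = TRUE)[[1]]
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hits <- integer(0)
  for (s in seq_len(max(0, length(chars) - pl - spacer_len + 1))) {
    ok <- TRUE
    for (q in seq_len(pl)) {
      if (!chars[s + q - 1] %in% sets[[psym[q]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s - 1L) # 0-based
  }
  hits
}

# --- exhaustive permutation Mann-Whitney -----------------------------------
# Computes U directly from pairwise comparisons and the two-tailed p as the
# fraction of all label assignments whose U is at least as extreme.
oracle_mann_whitney <- function(a, b) {
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  pooled <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  sets <- utils::combn(length(pooled), na)
  us <- numeric(ncol(sets))
  for (c in seq_len(ncol(sets))) {
    us[c] <- u_of(pooled[sets[, c]], pooled[-sets[, c]])
  }
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# plant up to two indel events in a reference, returning read + truth
plant_events <- function(ref, n_events) {
  L <- nchar(ref)
  read <- ref
  shift <- 0L
  starts <- sort(sample(seq(3, L - 10), n_events))
  for (s in starts) {
    len <- sample(1:6, 1)
    pos <- s + shift
    if (stats::runif(1) < 0.5 && pos + len <= nchar(read)) {
      read <- paste0(substr(read, 1, pos), substr(read, pos + len + 1,
                                                  nchar(read)))
      shift <- shift - len
    } else {
      ins <- rand_dna(len)
      read <- paste0(substr(read, 1, pos), ins,
                     substr(read, pos + 1, nchar(read)))
      shift <- shift + len
    }
  }
  read
}
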