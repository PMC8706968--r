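# Indel/substitution events are tibbles with columns:
#   kind  : "del", "ins" or "sub"
#   start : 0-based target coordinate (5' end of the PAM = position 0).
#           Deletions remove positions start..start+length-1; insertions sit
#           between start-1 and start; substitutions replace position start.
#   length: event length (1 for substitutions)
#   seq   : inserted bases ("ins"), observed base ("sub"), "" for deletions

event_tbl <- function(kind = character(), start = integer(),
                      length = integer(), seq = character()) {
  tibble::tibble(kind = kind, start = as.integer(start),
                 length = as.integer(length), seq = seq)
}

sort_events <- function(ev) {
  ord <- order(ev$start, match(ev$kind, c("del", "ins", "sub")), ev$length,
               ev$seq)
  ev[ord, , drop = FALSE]
}

#' Apply an event list to a reference sequence
#'
#' Reconstructs the read-side sequence implied by a sorted list of deletion,
#' insertion and substitution events in reference coordinates.
#'
#' @param reference Reference string (e.g. the 42-nt target window).
#' @param events Event tibble (see [parse_repair_type()]).
#' @return The edited sequence.
#' @export
apply_events <- function(reference, events) {
  if (nrow(events) == 0) return(reference)
  events <- sort_events(events)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  out <- character(0)
  cursor <- 0L # next unconsumed 0-based ref position
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]
    if (s < cursor) stop("overlapping events at position ", s, call. = FALSE)
    out <- c(out, chars[seq_len(s - cursor) + cursor])
    if (events$kind[i] == "del") {
      cursor <- s + events$length[i]
    } else if (events$kind[i] == "ins") {
      out <- c(out, strsplit(events$seq[i], "", fixed = TRUE)[[1]])
      cursor <- s
    } else { # sub
      out <- c(out, events$seq[i])
      cursor <- s + 1L
    }
  }
  if (cursor < length(chars)) out <- c(out, chars[(cursor + 1L):length(chars)])
  paste(out, collapse = "")
}

event_key_one <- function(kind, start, length, seq) {
  switch(kind,
    del = sprintf("(%d, %d)", start, length),
    ins = sprintf("(%d, %dI:%s)", start, length, seq),
    sub = sprintf("(%d, 1S:%s)", start, seq)
  )
}

#' Serialize a repair type
#'
#' Renders an event list plus read count in the catalogue format, e.g. a
#' 6-bp deletion at positions 20-25 seen in 111 reads is `"[(20, 6)]:111"`.
#' Insertions carry an `I` suffix on the length followed by the inserted
#' bases (`"[(22, 2I:AG)]:5"`); single-base substitutions an `S` tag with the
#' observed base (`"[(7, 1S:G)]:3"`).
#'
#' @param events Event tibble.
#' @param count Read count (positive integer).
#' @return Single string; parses back with [parse_repair_type()].
#' @export
serialize_repair_type <- function(events, count) {
  stopifnot(count >= 1)
  events <- sort_events(events)
  body <- vapply(seq_len(nrow(events)), function(i) {
    event_key_one(events$kind[i], events$start[i], events$length[i],
                  events$seq[i])
  }, character(1))
  paste0("[", paste(body, collapse = ", "), "]:", count)
}

# key without the count, used to match repair types across groups
event_list_key <- function(events) {
  events <- sort_events(events)
  if (nrow(events) == 0) return("[]")
  body <- vapply(seq_len(nrow(events)), function(i) {
    event_key_one(events$kind[i], events$start[i], events$length[i],
                  events$seq[i])
  }, character(1))
  paste0("[", paste(body, collapse = ", "), "]")
}

#' Parse a serialized repair type
#'
#' @param s String in the format written by [serialize_repair_type()].
#' @return List with `events` (tibble) and `count` (integer).
#' @export
parse_repair_type <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^\\[(.*)\\]:([0-9]+)$", s))[[1]]
  if (length(m) != 3) {
    stop("malformed repair type string at '", s, "': expected '[...]:count'",
         call. = FALSE)
  }
  count <- as.integer(m[3])
  events <- parse_event_list(m[2], context = s)
  list(events = events, count = count)
}

parse_event_list <- function(body, context = body) {
  if (body == "") return(event_tbl())
  parts <- strsplit(body, "\\), \\(")[[1]]
  parts <- gsub("^\\(|\\)$", "", parts)
  ev <- lapply(parts, function(p) {
    if (grepl("^[0-9]+, [0-9]+$", p)) {
      f <- strsplit(p, ", ", fixed = TRUE)[[1]]
      list(kind = "del", start = as.integer(f[1]),
           length = as.integer(f[2]), seq = "")
    } else if (grepl("^[0-9]+, [0-9]+I:[ACGTN]+$", p)) {
      f <- regmatches(p, regexec("^([0-9]+), ([0-9]+)I:([ACGTN]+)$", p))[[1]]
      list(kind = "ins", start = as.integer(f[2]),
           length = as.integer(f[3]), seq = f[4])
    } else if (grepl("^[0-9]+, 1S:[ACGTN]$", p)) {
      f <- regmatches(p, regexec("^([0-9]+), 1S:([ACGTN])$", p))[[1]]
      list(kind = "sub", start = as.integer(f[2]), length = 1L, seq = f[3])
    } else {
      stop("malformed event '(", p, ")' in repair type '", context, "'",
           call. = FALSE)
    }
  })
  ev <- dplyr::bind_rows(lapply(ev, tibble::as_tibble))
  ok <- ev$kind != "ins" | nchar(ev$seq) == ev$length
  if (!all(ok)) {
    stop("insertion length does not match inserted bases in '", context, "'",
         call. = FALSE)
  }
  sort_events(ev)
}
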