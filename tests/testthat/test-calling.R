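make_amplicon <- function(pair, target = NULL) {
  el <- default_elements()
  paste0(el[["fwd_const"]], el[["handle"]], pair$spacer, "TTTTTT",
         pair$barcode, if (is.null(target)) pair$target else target,
         el[["rev_const"]])
}

test_that("demultiplexing keys on exact crRNA region and barcode", {
  lib <- fixture_library(n_pairs = 4)
  index <- library_index(lib)
  amp <- make_amplicon(lib[1, ])
  # exact read -> assigned to its pair
  dx <- demultiplex(amp, index)
  expect_equal(dx$status, "assigned")
  expect_equal(dx$pair_id, lib$pair_id[1])
  # one substitution inside the spacer with a correct barcode -> invalid
  bad <- amp
  substr(bad, 45, 45) <- setdiff(c("A", "C", "G", "T"),
                                 substr(amp, 45, 45))[1]
  dx <- demultiplex(bad, index)
  expect_equal(dx$status, "invalid")
  expect_equal(dx$pair_id, lib$pair_id[1])
  # unknown barcode -> unassigned
  unk <- amp
  substr(unk, 69, 80) <- "AAAAAAAAAAAA"
  expect_equal(demultiplex(unk, index)$status, "unassigned")
  # truncated read -> unassigned
  expect_equal(demultiplex(substr(amp, 1, 60), index)$status, "unassigned")
  # reverse-complemented read is rescued
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp)))
  dx <- demultiplex(rc, index)
  expect_equal(dx$status, "assigned")
  expect_equal(dx$pair_id, lib$pair_id[1])
})

test_that("two-round classification separates edits from background", {
  cfg <- calling_config()
  no_subs <- tibble::tibble(pos = integer(), ref_base = character(),
                            read_base = character())
  # worked 6-bp deletion at the cut site -> edited
  expect_equal(classify_read(event_tbl("del", 20L, 6L, ""), no_subs, cfg),
               "edited")
  # small indel far outside the 8-bp frame -> background
  expect_equal(classify_read(event_tbl("del", 2L, 1L, ""), no_subs, cfg),
               "background_filtered")
  expect_equal(classify_read(event_tbl("ins", 2L, 3L, "ACG"), no_subs, cfg),
               "background_filtered")
  # small indel inside the frame -> edited
  expect_equal(classify_read(event_tbl("del", 24L, 1L, ""), no_subs, cfg),
               "edited")
  # large indel outside the frame -> edited (round 2 only filters small ones)
  expect_equal(classify_read(event_tbl("del", 2L, 10L, ""), no_subs, cfg),
               "edited")
  # no events -> unedited
  expect_equal(classify_read(event_tbl(), no_subs, cfg), "unedited")
  # substitution-only reads follow the configured policy
  s <- tibble::tibble(pos = 10L, ref_base = "A", read_base = "G")
  expect_equal(classify_read(event_tbl(), s, cfg), "edited")
  cfg_ig <- calling_config(substitution_policy = "ignore")
  expect_equal(classify_read(event_tbl(), s, cfg_ig), "unedited")
})

test_that("profiles conserve read counts across classes", {
  lib <- fixture_library(n_pairs = 8)
  eff <- fixture_effector(activity = 0.4)
  ds <- generate_dataset(lib, eff, depth_per_pair = 150, seed = 13)
  index <- library_index(lib)
  dx <- demultiplex(ds$experimental$seq, index)
  prof <- build_profiles(dx, index)
  # assigned = unedited + filtered + edited, per pair and in total
  assigned <- table(dx$pair_id[dx$status == "assigned"])
  for (pid in lib$pair_id) {
    row <- prof$profiles[prof$profiles$pair_id == pid, ]
    expect_equal(row$unedited + row$filtered + row$edited_total,
                 as.integer(assigned[pid]))
  }
  # catalogue totals equal the edited totals
  cat_sum <- tapply(prof$catalogue$count, prof$catalogue$pair_id, sum)
  for (pid in names(cat_sum)) {
    expect_equal(as.integer(cat_sum[pid]),
                 prof$profiles$edited_total[prof$profiles$pair_id == pid])
  }
  # demultiplexed totals partition the input
  expect_equal(sum(dx$status == "assigned") + sum(dx$status == "invalid") +
                 sum(dx$status == "unassigned"), nrow(ds$experimental))
})

test_that("control subtraction removes exactly the shared repair types", {
  prof <- function(pair_id, types, counts, unedited = 100L) {
    list(profiles = tibble::tibble(pair_id = pair_id, unedited = unedited,
                                   filtered = 0L, invalid = 0L,
                                   edited_total = sum(counts)),
         catalogue = tibble::tibble(pair_id = pair_id, repair_type = types,
                                    count = counts))
  }
  e <- prof("p1", c("[(20, 6)]", "[(3, 1)]"), c(50L, 5L))
  c1 <- prof("p1", "[(3, 1)]", 7L)
  sub <- subtract_background(e, c1)
  expect_equal(sub$catalogue$repair_type, "[(20, 6)]")
  expect_equal(sub$profiles$unedited, 105L)
  expect_equal(sub$profiles$edited_total, 50L)
  # type only in experimental is retained untouched
  expect_equal(sub$catalogue$count, 50L)
  # empty control leaves the experimental profile unchanged
  c0 <- list(profiles = tibble::tibble(pair_id = character(),
                                       unedited = integer(),
                                       filtered = integer(),
                                       invalid = integer(),
                                       edited_total = integer()),
             catalogue = tibble::tibble(pair_id = character(),
                                        repair_type = character(),
                                        count = integer()))
  sub0 <- subtract_background(e, c0)
  expect_equal(sub0$profiles$edited_total, 55L)
  expect_equal(attr(sub0, "missing_control"), "p1")
  # matching is per pair: the same type under another pair is not removed
  c2 <- prof("p2", "[(3, 1)]", 7L)
  sub2 <- subtract_background(e, c2)
  expect_equal(sub2$profiles$edited_total, 55L)
})

test_that("indel frequency follows the edited/(edited+unedited) formula", {
  prof <- tibble::tibble(pair_id = c("a", "b", "c", "d"),
                         unedited = c(189L, 400L, 250L, 0L),
                         filtered = c(0L, 10L, 49L, 0L),
                         invalid = c(0L, 0L, 0L, 0L),
                         edited_total = c(111L, 0L, 0L, 0L))
  f <- indel_frequency(prof)
  expect_equal(f$indel_frequency[1], 0.37)
  expect_true(f$excluded[1]) # exactly 300 reads does not exceed min_reads
  expect_equal(f$indel_frequency[2], 0)
  expect_false(f$excluded[2])
  # 299 total reads with the read-count-over-300 rule -> excluded
  expect_true(f$excluded[3])
  expect_true(f$excluded[4]) # zero denominator
  # filtered reads count as unedited in the denominator by default
  expect_equal(f$unedited_total[2], 410L)
  cfg_drop <- calling_config(filtered_as_unedited = FALSE)
  expect_equal(indel_frequency(prof, cfg_drop)$unedited_total[2], 400L)
})
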