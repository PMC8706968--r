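freq_tbl <- function(pair_id, freq, excluded = FALSE) {
  tibble::tibble(pair_id = pair_id, edited_total = 0L, unedited_total = 0L,
                 indel_frequency = freq,
                 excluded = rep_len(excluded, length(pair_id)))
}

test_that("PAM-group summaries average the member pairs", {
  lib <- tibble::tibble(pair_id = paste0("p", 1:4),
                        pam = c("TTTA", "TTTC", "TATA", "TTTA"))
  fr <- freq_tbl(lib$pair_id, c(0.2, 0.4, 0.9, 0.3),
                 excluded = c(FALSE, FALSE, FALSE, TRUE))
  s <- summarize_by_pam(fr, lib, c("TTTV", "TATN", "TTCV"), effector = "e1")
  expect_equal(s$mean_frequency[s$pam_group == "TTTV"], 0.3) # (0.2+0.4)/2
  expect_equal(s$n_targets[s$pam_group == "TTTV"], 2) # excluded pair dropped
  expect_equal(s$mean_frequency[s$pam_group == "TATN"], 0.9)
  expect_true(is.na(s$mean_frequency[s$pam_group == "TTCV"]))
  expect_equal(s$n_targets[s$pam_group == "TTCV"], 0)
  # order invariance and subgroup-mean recombination
  s2 <- summarize_by_pam(fr[c(3, 1, 4, 2), ], lib, "TTTV")
  expect_equal(s2$mean_frequency, 0.3)
  sub <- summarize_by_pam(fr, lib, c("TTTA", "TTTC"))
  w <- sum(sub$mean_frequency * sub$n_targets) / sum(sub$n_targets)
  expect_equal(w, 0.3)
})

test_that("pathway classification matches the microhomology scan", {
  # deletion collapsing two 4-nt repeats -> MMEJ
  t <- paste0("TTTA", "ACGT", "GTCC", "ACGT",
              paste(rep(c("A", "C"), 13), collapse = ""))
  mh <- find_microhomologies(t, min_len = 2)
  hit <- mh[mh$mh_len >= 4, ][1, ]
  expect_equal(classify_pathway(
    event_tbl("del", hit$deletion_start, hit$deletion_len, ""), t), "MMEJ")
  # insertions are NHEJ by definition
  expect_equal(classify_pathway(event_tbl("ins", 22L, 2L, "AG"), t), "NHEJ")
  # deletion in repeat-free context -> NHEJ
  t2 <- "TTTACGATCGGATCGATTAGCGGCGATAACGATCAGGCTAGC"
  del <- event_tbl("del", 22L, 5L, "")
  mh2 <- find_microhomologies(t2, min_len = 2)
  expect_false(any(mh2$deletion_start == 22 & mh2$deletion_len == 5))
  expect_equal(classify_pathway(del, t2), "NHEJ")
  # multi-event types are NHEJ
  expect_equal(classify_pathway(
    event_tbl(c("del", "ins"), c(20L, 27L), c(2L, 1L), c("", "A")), t), "NHEJ")
})

test_that("repair-type spectra are normalized and sorted", {
  cat1 <- tibble::tibble(pair_id = "p", repair_type = c("[(20, 6)]",
                                                        "[(22, 2)]"),
                         count = c(70L, 30L))
  sp <- repair_type_spectrum(cat1)
  expect_equal(sp$proportion, c(0.7, 0.3))
  expect_equal(sum(sp$proportion), 1)
  one <- repair_type_spectrum(cat1[1, ])
  expect_equal(one$proportion, 1)
  expect_equal(nrow(repair_type_spectrum(cat1[0, ])), 0)
  set.seed(8)
  rnd <- tibble::tibble(pair_id = "p",
                        repair_type = paste0("[(", 1:12, ", 1)]"),
                        count = sample.int(50, 12))
  expect_equal(sum(repair_type_spectrum(rnd)$proportion), 1)
})

test_that("replicate correlation uses shared non-excluded pairs", {
  a <- freq_tbl(paste0("p", 1:4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(replicate_correlation(a, a)$statistic, 1)
  b <- a
  b$indel_frequency <- 0.5 - a$indel_frequency # exact negation around mean
  expect_equal(replicate_correlation(a, b)$statistic, -1)
  # frozen toy value: r of (1,2,3,4) vs (2,4,5,9), hand-computed as
  # cov/(sd_x sd_y) = 3.66667 / (1.29099 * 2.94392) = 0.9647638
  b2 <- freq_tbl(paste0("p", 1:4), c(2, 4, 5, 9))
  a2 <- freq_tbl(paste0("p", 1:4), 1:4)
  expect_equal(replicate_correlation(a2, b2)$statistic, 0.9647638,
               tolerance = 1e-6)
  expect_error(replicate_correlation(a[1:2, ], a[1:2, ]), "3")
})

test_that("Mann-Whitney U is exact for small samples including ties", {
  # complete separation: U = 0 for the lower group
  r <- compare_two(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  o <- oracle_mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, o$p)
  # identical multisets: p = 1
  r2 <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r2$p_value, 0.99)
  # tie-free case agrees with the standard exact test
  set.seed(12)
  x <- round(runif(5), 3); y <- round(runif(5) + 0.3, 3)
  r3 <- compare_two(x, y)
  w <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(unname(r3$statistic), unname(w$statistic))
  expect_equal(r3$p_value, w$p.value, tolerance = 1e-9)
  expect_error(compare_two(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney permutation property holds for pooled n <= 10", {
  set.seed(33)
  for (rep in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    # draw with ties likely
    a <- sample(1:4, na, replace = TRUE)
    b <- sample(2:6, nb, replace = TRUE)
    r <- compare_two(a, b)
    o <- oracle_mann_whitney(a, b)
    expect_equal(r$statistic, o$u)
    expect_equal(r$p_value, o$p)
  }
})

test_that("Kruskal-Wallis and Dunn behave across group structures", {
  set.seed(44)
  same <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  r <- compare_many(same)
  h <- r[r$test == "kruskal_wallis", ]
  expect_lt(h$statistic, 8)
  dunn_same <- r[r$test == "dunn_posthoc", ]
  expect_false(any(dunn_same$p_adjusted < 0.05, na.rm = TRUE))
  shifted <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12) + 10)
  r2 <- compare_many(shifted)
  dunn <- r2[r2$test == "dunn_posthoc", ]
  expect_true(all(dunn$p_adjusted[grepl("c", dunn$groups)] < 0.05))
  expect_error(compare_many(same[1:2]), "compare_two")
})

test_that("effector ranking splits at the activity threshold", {
  means <- c(As = 0.39, Pr = 0.343, Mb3 = 0.227, Hk = 0.072, Pi = 0.10)
  rk <- rank_effectors(means, threshold = 0.20)
  expect_equal(rk$effector[1], "As")
  expect_equal(rk$category, c("high", "high", "high", "low", "low"))
  all_low <- rank_effectors(c(x = 0.1, y = 0.05))
  expect_true(all(all_low$category == "low"))
  tied <- rank_effectors(c(b = 0.3, a = 0.3))
  expect_equal(tied$effector, c("a", "b"))
})
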