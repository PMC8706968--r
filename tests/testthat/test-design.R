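test_that("protospacer scanning finds plus- and minus-strand sites", {
  plus <- scan_protospacers("CTTTAGGGG", "TTTV", spacer_len = 4)
  expect_equal(nrow(plus), 1)
  expect_equal(plus$strand, "+")
  expect_equal(plus$pam, "TTTA")
  expect_equal(plus$pam_start, 1L)
  expect_equal(plus$spacer, "GGGG")

  minus <- scan_protospacers("CCCCTAAAG", "TTTV", spacer_len = 4)
  expect_equal(nrow(minus), 1)
  expect_equal(minus$strand, "-")
  expect_equal(minus$pam, "TTTA")
  expect_equal(minus$spacer, "GGGG")
  # leftmost plus-strand base of the site: revcomp match at offset 1
  expect_equal(minus$pam_start, 4L)

  expect_equal(nrow(scan_protospacers("AAAAAAAA", "TTTV", spacer_len = 4)), 0)
  expect_equal(nrow(scan_protospacers("", "TTTV", spacer_len = 4)), 0)
})

test_that("scanning agrees with a naive sliding-window oracle on both strands", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(50:400, 1)
    s <- rand_dna(L)
    pat <- sample(c("TTTV", "TRTN", "NTTT", "KKYV"), 1)
    got <- scan_protospacers(s, pat, spacer_len = 23)
    want_plus <- oracle_scan_plus(s, pat, 23)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    want_minus <- L - oracle_scan_plus(rc, pat, 23) - 4L
    expect_setequal(got$pam_start[got$strand == "+"], want_plus)
    expect_setequal(got$pam_start[got$strand == "-"], want_minus)
  }
})

test_that("guide filters drop T-runs and extreme GC and are idempotent", {
  cand <- tibble::tibble(
    gene_id = "g",
    spacer = c("ACGTACGTACGTACGTACGTACG",      # mid GC, keep
               "ACGTTTTACGTACGTACGTACGT",      # contains TTTT
               paste(rep("A", 23), collapse = ""),  # GC 0
               paste(rep("G", 23), collapse = "")), # GC 100
    strand = "+", pam_start = 1:4)
  cand$gc_percent <- vapply(cand$spacer, function(s) {
    100 * sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  }, numeric(1))
  kept <- filter_guides(cand)
  expect_equal(kept$spacer, cand$spacer[1])
  expect_identical(filter_guides(kept), kept)
  expect_error(filter_guides(cand, gc_min = 60, gc_max = 40), "gc_min")
})

test_that("top-k selection is per gene, deterministic, and mid-GC-first", {
  set.seed(4)
  cand <- tibble::tibble(
    gene_id = rep(c("a", "b"), each = 12),
    spacer = replicate(24, rand_dna(23)),
    strand = "+",
    pam_start = rep(1:12, 2),
    gc_percent = runif(24, 20, 80))
  got <- take_top_k_per_gene(cand, k = 10)
  expect_equal(unname(table(got$gene_id)["a"]), 10L)
  expect_equal(nrow(got), 20)
  worst_kept <- max(abs(got$gc_percent[got$gene_id == "a"] - 50))
  dropped <- cand$gc_percent[cand$gene_id == "a"]
  dropped <- dropped[!dropped %in% got$gc_percent[got$gene_id == "a"]]
  expect_true(all(abs(dropped - 50) >= worst_kept))
  expect_equal(nrow(take_top_k_per_gene(cand[1:4, ], k = 10)), 4)
  expect_error(take_top_k_per_gene(cand, k = 0), "positive")
})

test_that("barcode assignment respects distance and homopolymer constraints", {
  bcs <- assign_barcodes(100, length = 12, min_distance = 3, seed = 1)
  expect_length(unique(bcs), 100)
  expect_true(all(nchar(bcs) == 12))
  expect_false(any(grepl("A{4}|C{4}|G{4}|T{4}", bcs)))
  mat <- do.call(rbind, strsplit(bcs, ""))
  for (i in 1:99) {
    d <- rowSums(mat[(i + 1):100, , drop = FALSE] !=
                   matrix(mat[i, ], nrow = 100 - i, ncol = 12, byrow = TRUE))
    expect_true(all(d >= 3))
  }
  expect_identical(assign_barcodes(50, seed = 8), assign_barcodes(50, seed = 8))
  expect_length(assign_barcodes(1), 1)
  expect_error(assign_barcodes(100, length = 3), "too small|unsatisfiable")
})

test_that("library design yields unique, well-formed guide-target pairs", {
  lib <- fixture_library(n_pairs = 1000)
  expect_true(all(nchar(lib$spacer) == 23))
  expect_true(all(nchar(lib$target) == 42))
  expect_true(all(nchar(lib$barcode) == 12))
  expect_true(all(substr(lib$target, 1, 4) == lib$pam))
  expect_true(all(matches_pam(lib$pam, "TTTV")))
  expect_false(anyDuplicated(lib$barcode) > 0)
  expect_false(anyDuplicated(paste(lib$spacer, lib$barcode)) > 0)
  # spacer is the 23 nt immediately 3' of the PAM within the target
  expect_identical(substr(lib$target, 5, 27), lib$spacer)
})
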