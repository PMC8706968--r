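test_that("repair simulation honors activity, branch forcing and seeds", {
  pair <- fixture_pair()
  # zero activity: always unedited
  eff0 <- effector_model("e0", c(TTTA = 0))
  for (s in 1:10) expect_equal(nrow(simulate_repair(pair, eff0, seed = s)), 0)
  # activity 1 with mmej_weight 1 and a single spanning microhomology:
  # every edited read carries that one deletion
  t <- paste0("TTTA", rand_dna(14), "CAGT", "ACGTAC", "CAGT", rand_dna(10))
  expect_equal(nchar(t), 42)
  pair2 <- fixture_pair(target = t)
  effm <- effector_model("em", c(TTTA = 1), mmej_weight = 1)
  mh <- find_microhomologies(t, min_len = 2)
  span <- mh[mh$deletion_start < 27 & mh$deletion_start + mh$deletion_len > 22, ]
  if (nrow(span) == 1) {
    for (s in 1:5) {
      ev <- simulate_repair(pair2, effm, seed = s)
      expect_equal(ev$kind, "del")
      expect_equal(ev$start, span$deletion_start)
      expect_equal(ev$length, span$deletion_len)
    }
  }
  # determinism
  eff <- effector_model("e", c(TTTA = 0.5))
  expect_identical(simulate_repair(pair, eff, seed = 42),
                   simulate_repair(pair, eff, seed = 42))
  # unknown PAM is an error, never a silent default
  expect_error(simulate_repair(fixture_pair(), effector_model("x", c(AAAA = 1))),
               "PAM")
})

test_that("simulated NHEJ outcomes stay near the staggered cut", {
  pair <- fixture_pair()
  eff <- effector_model("e", c(TTTA = 1), mmej_weight = 0)
  for (s in 1:50) {
    ev <- simulate_repair(pair, eff, seed = s)
    expect_equal(nrow(ev), 1)
    if (ev$kind == "del") {
      # deletion covers one of the nicks
      expect_true((ev$start <= 22 && ev$start + ev$length >= 22) ||
                    (ev$start <= 27 && ev$start + ev$length >= 27))
      expect_lte(ev$length, 20)
    } else {
      expect_true(ev$start >= 21 && ev$start <= 28)
      expect_lte(ev$length, 3)
      expect_equal(nchar(ev$seq), ev$length)
    }
  }
})

test_that("generated datasets have exact depth and faithful truth records", {
  lib <- fixture_library(n_pairs = 6)
  eff <- fixture_effector(activity = 0.3)
  ds <- generate_dataset(lib, eff, noise = noise_off(), depth_per_pair = 50,
                         seed = 2)
  expect_equal(nrow(ds$experimental), 6 * 50)
  expect_equal(nrow(ds$control), 6 * 50)
  # truth counts sum to the emitted depth per pair
  sums <- tapply(ds$truth$count, ds$truth$pair_id, sum)
  expect_true(all(sums == 50))
  # with noise off, every edited read equals the reference amplicon with
  # exactly the recorded events applied, and control reads are verbatim
  refs <- reference_amplicons(lib)
  pre <- 80L
  for (pid in lib$pair_id) {
    ref <- refs[[pid]]
    ctl <- ds$control$seq[startsWith(ds$control$read_id, paste0(pid, "_ctl"))]
    expect_true(all(ctl == ref))
    tr <- ds$truth[ds$truth$pair_id == pid, ]
    exp_reads <- ds$experimental$seq[
      startsWith(ds$experimental$read_id, paste0(pid, "_exp"))]
    built <- vapply(tr$repair_type, function(k) {
      ev <- parse_repair_type(paste0(k, ":1"))$events
      target <- lib$target[lib$pair_id == pid]
      paste0(substr(ref, 1, pre), apply_events(target, ev),
             substr(ref, pre + 43, nchar(ref)))
    }, character(1))
    expect_setequal(unique(exp_reads), unique(built))
    got <- table(exp_reads)
    want <- tapply(tr$count, built[tr$repair_type], sum)
    expect_equal(as.integer(got[names(want)]), as.integer(want))
  }
})

test_that("noise-free edited fractions match the binomial model", {
  lib <- fixture_library(n_pairs = 4)
  p <- 0.35
  eff <- fixture_effector(activity = p)
  ds <- generate_dataset(lib, eff, noise = noise_off(),
                         depth_per_pair = 1000, seed = 31)
  refs <- reference_amplicons(lib)
  ci <- stats::qbinom(c(0.005, 0.995), 1000, p)
  for (pid in lib$pair_id) {
    n_ed <- sum(ds$experimental$seq[
      startsWith(ds$experimental$read_id, paste0(pid, "_exp"))] != refs[[pid]])
    expect_gte(n_ed, ci[1])
    expect_lte(n_ed, ci[2])
  }
})

test_that("dataset generation is deterministic and validates inputs", {
  lib <- fixture_library(n_pairs = 3)
  eff <- fixture_effector()
  d1 <- generate_dataset(lib, eff, depth_per_pair = 20, seed = 9)
  d2 <- generate_dataset(lib, eff, depth_per_pair = 20, seed = 9)
  expect_identical(d1$experimental, d2$experimental)
  expect_identical(d1$truth, d2$truth)
  bad <- lib; bad$barcode[2] <- bad$barcode[1]
  expect_error(generate_dataset(bad, eff, depth_per_pair = 5, seed = 1),
               "barcode")
  lib2 <- lib; lib2$pam[1] <- "AAAA"
  expect_error(generate_dataset(lib2, eff, depth_per_pair = 5, seed = 1),
               "PAM")
})

test_that("per-pair edit-rate overrides drive the emitted truth", {
  lib <- fixture_library(n_pairs = 3)
  eff <- fixture_effector(activity = 0.9)
  rates <- stats::setNames(c(0, 0.5, 1), lib$pair_id)
  ds <- generate_dataset(lib, eff, noise = noise_off(), depth_per_pair = 80,
                         seed = 4, edit_rates = rates)
  expect_equal(unique(ds$truth[, c("pair_id", "true_edit_rate")])$true_edit_rate,
               unname(rates))
  refs <- reference_amplicons(lib)
  # rate 0: all reads are the reference; rate 1: none are
  r1 <- ds$experimental$seq[startsWith(ds$experimental$read_id,
                                       paste0(lib$pair_id[1], "_"))]
  r3 <- ds$experimental$seq[startsWith(ds$experimental$read_id,
                                       paste0(lib$pair_id[3], "_"))]
  expect_true(all(r1 == refs[[1]]))
  expect_true(all(r3 != refs[[3]]))
  expect_error(generate_dataset(lib, eff, depth_per_pair = 5, seed = 1,
                                edit_rates = rates[1:2]),
               "missing pair")
})
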