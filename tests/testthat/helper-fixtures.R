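# Shared fixture builders. Everything is generated in code at test time.

fixture_genes <- function(n = 4, len = 400, seed = 99) {
  set.seed(seed)
  stats::setNames(
    replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE,
                              prob = c(.3, .2, .2, .3)), collapse = "")),
    paste0("g", seq_len(n)))
}

fixture_library <- function(n_pairs = 20, seed = 7, genes = fixture_genes()) {
  lib <- design_library(genes, seed = seed)
  lib[seq_len(min(n_pairs, nrow(lib))), ]
}

fixture_effector <- function(pams = expand_pattern("TTTV"),
                             activity = 0.4, ...) {
  effector_model("fx", stats::setNames(rep(activity, length(pams)), pams), ...)
}

# one-row pair for unit tests; target = PAM + protospacer + context (42 nt)
fixture_pair <- function(target = NULL, seed = 3) {
  set.seed(seed)
  if (is.null(target)) {
    target <- paste0("TTTA",
                     paste(sample(c("A", "C", "G", "T"), 38, TRUE),
                           collapse = ""))
  }
  tibble::tibble(pair_id = "p1", gene_id = "g1",
                 spacer = substr(target, 5, 27),
                 barcode = "ACGTACGTACGT", pam = substr(target, 1, 4),
                 target = target, strand = "+", pam_start = 0L)
}
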