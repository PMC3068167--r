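test_that("a canonical a-module yields exactly one zero-tolerance candidate", {
  g <- cremp_grammar(gap_tolerance = 0L)
  hits <- find_candidate_modules(CANONICAL_A, g)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 0L)
  expect_identical(hits$end, 27L)
  expect_identical(hits$observed_gaps[[1]], c(4L, 5L, 8L))
  expect_identical(hits$observed_tail, 6L)
  expect_identical(hits$deviations[[1]], character(0))
})

test_that("cysteine-free sequences yield no candidates", {
  expect_identical(nrow(find_candidate_modules(strrep("A", 80),
                                               default_grammar)), 0L)
})

test_that("a single-residue gap deletion is tolerated and flagged", {
  # delete one residue between C2 and C3 (gaps become 4,4,8); mirrors the
  # single-amino-acid deletion seen in lizard module 7
  chars <- strsplit(CANONICAL_A, "")[[1]]
  shrunk <- paste(chars[-11], collapse = "") # position 11 is filler
  hits <- find_candidate_modules(shrunk, default_grammar)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$observed_gaps[[1]], c(4L, 4L, 8L))
  expect_identical(hits$deviations[[1]], "gap_shrunk")
  expect_identical(hits$label, "variant")
  expect_identical(hits$end - hits$start, 26L)
})

test_that("chaining one a+b repeat gives a single region covering 59 residues", {
  ab <- paste0(CANONICAL_A, CANONICAL_B)
  cand <- find_candidate_modules(ab, default_grammar)
  regions <- chain_modules(cand)
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$n_modules, 2L)
  expect_identical(regions$start, 0L)
  expect_identical(regions$end, 59L)
  h <- regions$hits[[1]]
  expect_identical(sum(h$end - h$start), 59L)
})

test_that("chaining prefers the larger of two overlapping candidates", {
  mk <- function(start, end, dev = 0L) {
    tibble::tibble(seq_id = "s", start = start, end = end, label = "a",
                   spec_label = "a", observed_gaps = list(c(4L, 5L, 8L)),
                   observed_tail = end - start - 21L, insert_length = 0L,
                   deviations = list(character(0)), n_deviations = dev,
                   diag_score = 0L)
  }
  cand <- dplyr::bind_rows(mk(0L, 32L), mk(3L, 30L))
  reg <- chain_modules(cand)
  expect_identical(reg$hits[[1]]$start, 0L)
  expect_identical(reg$hits[[1]]$end, 32L)
  expect_identical(nrow(chain_modules(cand[0, ])), 0L)
})

test_that("scanner matches the brute-force quadruple oracle on random input", {
  set.seed(101)
  g <- default_grammar
  n_checked <- 0L
  for (i in 1:60) {
    len <- sample(40:200, 1)
    seq <- if (i %% 3 == 0) {
      # embed a (possibly mutated) canonical module in random context
      paste0(random_protein(sample(0:40, 1)),
             if (i %% 2) CANONICAL_A else CANONICAL_B,
             random_protein(sample(0:40, 1)))
    } else {
      random_protein(len, c_prob = 0.15)
    }
    got <- find_candidate_modules(seq, g)
    want <- brute_force_candidates(seq, g)
    got_df <- as.data.frame(got[c("start", "end", "spec_label",
                                  "observed_tail")])
    rownames(got_df) <- rownames(want) <- NULL
    expect_identical(got_df, want)
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 20) # the comparison must actually see candidates
})

test_that("chained coverage equals exhaustive chain search", {
  set.seed(202)
  for (i in 1:25) {
    seq <- random_protein(sample(60:160, 1), c_prob = 0.18)
    cand <- find_candidate_modules(seq, default_grammar)
    if (nrow(cand) == 0 || nrow(cand) > 10) next
    reg <- chain_modules(cand)
    got_cov <- if (nrow(reg)) sum(vapply(reg$hits, function(h) {
      sum(h$end - h$start)
    }, numeric(1))) else 0
    got_n <- sum(reg$n_modules)
    best <- best_chain_exhaustive(cand)
    expect_identical(as.integer(got_cov), as.integer(best$coverage))
    expect_identical(as.integer(got_n), as.integer(best$n))
    # selected hits never overlap
    if (nrow(reg)) {
      all_h <- dplyr::bind_rows(reg$hits)
      all_h <- all_h[order(all_h$start), ]
      if (nrow(all_h) > 1) {
        expect_true(all(all_h$start[-1] >= all_h$end[-nrow(all_h)]))
      }
    }
  }
})

test_that("rescanning a reported insert-free hit reproduces it at offset 0", {
  g <- default_grammar
  sim <- simulate_protein(strrep("ab", 3), g, substitution_rate = 0.05,
                          seed = 7)
  sc <- scan_proteins(sim$seq, g)
  hits <- sc$hits[sc$hits$insert_length == 0L, ]
  for (i in seq_len(nrow(hits))) {
    sub <- substr(sim$seq$residues, hits$start[i] + 1L, hits$end[i])
    re <- find_candidate_modules(sub, g)
    re <- re[re$spec_label == hits$spec_label[i] & re$start == 0L, ]
    expect_identical(nrow(re), 1L)
    expect_identical(re$end, hits$end[i] - hits$start[i])
    expect_identical(re$observed_gaps[[1]], hits$observed_gaps[[i]])
  }
})

test_that("architecture strings render classified labels by base letter", {
  expect_identical(architecture_string(c("a", "b", "a", "b")), "abab")
  expect_identical(architecture_string(c("a", "a_variant", "b_variant")),
                   "aab")
  expect_identical(architecture_string(rep("a", 21)), strrep("a", 21))
  expect_identical(architecture_string(c("variant", "unknown")), "vv")
  expect_identical(architecture_string(character(0)), "")
})

test_that("compress_pattern finds the smallest dividing period", {
  expect_identical(compress_pattern("abab"), "(ab)2")
  expect_identical(compress_pattern("abbabb"), "(abb)2")
  expect_identical(compress_pattern("a"), "(a)1")
  expect_identical(compress_pattern("abba"), "(abba)1")
  set.seed(33)
  for (i in 1:40) {
    s <- paste(sample(c("a", "b"), sample(1:12, 1), replace = TRUE),
               collapse = "")
    p <- smallest_period(s)
    expect_identical(compress_pattern(s),
                     sprintf("(%s)%d", substr(s, 1, p), nchar(s) %/% p))
  }
})
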