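test_that("a zero-noise four-repeat protein has the expected geometry", {
  sim <- simulate_protein(strrep("ab", 4), default_grammar, seed = 1)
  expect_identical(nchar(sim$seq$residues), 236L)
  expect_identical(sum(strsplit(sim$seq$residues, "")[[1]] == "C"), 32L)
  expect_identical(nrow(sim$truth), 8L)
  sc <- scan_proteins(sim$seq, default_grammar)
  expect_identical(nrow(sc$hits), 8L)
  expect_identical(sc$regions$architecture, "abababab")
  expect_identical(sc$regions$pattern, "(ab)4")
  rep_ <- recovery_report(sim$truth, sc$hits)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$exact_boundary_rate, 1)
  expect_equal(rep_$type_accuracy, 1)
})

test_that("an all-a plan produces 21 tiled truth records", {
  sim <- simulate_protein(strrep("a", 21), default_grammar, seed = 4)
  expect_identical(nchar(sim$seq$residues), 21L * 27L)
  expect_identical(nrow(sim$truth), 21L)
  expect_identical(sim$truth$start[1], 0L)
  expect_identical(sim$truth$end[21], 567L)
  expect_identical(sim$truth$start[-1], sim$truth$end[-21])
})

test_that("seeded simulations are reproducible and leave the RNG alone", {
  s1 <- simulate_protein(strrep("ab", 3), substitution_rate = 0.2, seed = 99)
  s2 <- simulate_protein(strrep("ab", 3), substitution_rate = 0.2, seed = 99)
  expect_identical(s1$seq$residues, s2$seq$residues)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- simulate_protein(strrep("ab", 3), substitution_rate = 0.2, seed = 100)
  expect_false(identical(s1$seq$residues, s3$seq$residues))

  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_protein("ab", substitution_rate = 0.5, seed = 7))
  expect_identical(stats::runif(1), before)
})

test_that("schedules plant gap deviations and A/P-rich tail inserts", {
  dev <- data.frame(module_index = 1, gap_index = 3, delta = -1)
  ins <- data.frame(module_index = 2, insert_length = 100)
  sim <- simulate_protein("aa", default_grammar, deviation_schedule = dev,
                          insert_schedule = ins, seed = 12)
  expect_identical(sim$truth$gap_deviation, c(-1L, 0L))
  expect_identical(sim$truth$insert_length, c(0L, 100L))
  expect_identical(nchar(sim$seq$residues), 26L + 27L + 100L)
  insert_chars <- strsplit(substr(sim$seq$residues, 26L + 27L + 1L,
                                  26L + 27L + 100L), "")[[1]]
  expect_gt(mean(insert_chars %in% c("A", "P")), 0.6)
  expect_false(any(insert_chars == "C"))

  # a gap that cannot shrink without destroying an anchor errors
  g1 <- grammar(list(module_spec("z", c(0L, 5L, 8L), 6L)),
                conserved_catalogue()[0, ])
  expect_error(
    simulate_protein("z", g1,
                     deviation_schedule = data.frame(module_index = 1,
                                                     gap_index = 1,
                                                     delta = -1)),
    "cannot shrink")
  expect_error(
    simulate_protein("ab", deviation_schedule = data.frame(
      module_index = 5, gap_index = 1, delta = -1)),
    "outside the plan")
})

test_that("protected substitutions never touch anchors or diagnostics", {
  g <- default_grammar
  sim <- simulate_protein(strrep("ab", 5), g, substitution_rate = 0.5,
                          seed = 8)
  chars <- strsplit(sim$seq$residues, "")[[1]]
  for (i in seq_len(nrow(sim$truth))) {
    sp <- g$specs[[sim$truth$type[i]]]
    mod <- chars[(sim$truth$start[i] + 1):sim$truth$end[i]]
    expect_identical(which(mod == "C"), cys_positions(sp))
    rel <- g$catalogue[g$catalogue$scope %in% c("shared", sp$label), ]
    expect_identical(mod[rel$position], rel$residue)
  }
})

test_that("zero-noise scans recover every planted module exactly", {
  plans <- list(strrep("a", 100), strrep("ab", 20), strrep("abb", 7))
  for (p in plans) {
    sim <- simulate_protein(p, default_grammar, seed = nchar(p))
    sc <- scan_proteins(sim$seq, default_grammar)
    rep_ <- recovery_report(sim$truth, sc$hits)
    expect_equal(rep_$recall, 1)
    expect_equal(rep_$precision, 1)
    expect_equal(rep_$exact_boundary_rate, 1)
    expect_equal(rep_$type_accuracy, 1)
  }
})

test_that("recovery arithmetic handles misses and boundary slack", {
  truth <- tibble::tibble(module_index = 1:8,
                          start = seq(0L, by = 27L, length.out = 8),
                          end = seq(27L, by = 27L, length.out = 8),
                          type = rep("a", 8), gap_deviation = 0L,
                          insert_length = 0L)
  pred <- tibble::tibble(seq_id = "s", start = truth$start,
                         end = truth$end, label = "a")
  r <- recovery_report(truth, pred)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  r7 <- recovery_report(truth, pred[-3, ])
  expect_equal(r7$recall, 0.875)
  expect_equal(r7$precision, 1)

  off <- pred
  off$start[1] <- off$start[1] + 1L
  expect_equal(recovery_report(truth, off, slack = 0)$recall, 0.875)
  expect_equal(recovery_report(truth, off, slack = 1)$recall, 1)
})

test_that("a lizard-style schedule is recovered with its inserts and types", {
  # 38 a-modules: one-residue deletion in module 7, extra residue after
  # module 12, progressively longer A/P-rich inserts on even modules 22-28
  # (10, 25, 40, then 59 residues), embedded in cysteine-free flanks
  g <- default_grammar
  dev <- data.frame(module_index = 7, gap_index = 3, delta = -1)
  ins <- data.frame(module_index = c(12, 22, 24, 26, 28),
                    insert_length = c(1, 10, 25, 40, 59))
  sim <- simulate_protein(strrep("a", 38), g, deviation_schedule = dev,
                          insert_schedule = ins, flank_lengths = c(15, 15),
                          seed = 42)
  sc <- scan_proteins(sim$seq, g)
  expect_identical(nrow(sc$hits), 38L)
  expect_true(all(sc$hits$base_type == "a"))
  expect_identical(sum(sc$hits$label[1:21] == "a"), 19L) # modules 7, 12 deviate
  expect_identical(sc$hits$insert_length[28], 59L)
  expect_identical(sc$hits$insert_length[c(22, 24, 26)], c(10L, 25L, 40L))
  expect_identical(sc$regions$pattern, "(a)38")
})
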