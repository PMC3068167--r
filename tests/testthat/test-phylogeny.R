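test_that("p-distances count mismatches, with X mismatching everything", {
  d0 <- pdistance_matrix(c("CAD", "CAD"))
  expect_equal(d0[1, 2], 0)
  d1 <- pdistance_matrix(c("CAD", "CED"))
  expect_equal(d1[1, 2], 1 / 3, tolerance = 1e-12)
  dx <- pdistance_matrix(c("XAD", "XAD"))
  expect_equal(dx[1, 2], 1 / 3, tolerance = 1e-12)
  expect_error(pdistance_matrix(c("CAD", "CADA")), "equal length")
})

test_that("canonical a and trimmed b differ at exactly 3 of 27 positions", {
  d <- pdistance_matrix(c(CANONICAL_A, substr(CANONICAL_B, 1, 27)))
  expect_equal(d[1, 2], 3 / 27, tolerance = 1e-12)
})

test_that("UPGMA reproduces hand-computed merges and is ultrametric", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2), tolerance = 1e-9)

  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(d3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["A", "B"], 0.2, tolerance = 1e-9)
  expect_equal(cp["A", "C"], 0.6, tolerance = 1e-9)
  expect_equal(cp["B", "C"], 0.6, tolerance = 1e-9)
  # ultrametric: equal root-to-tip depths
  depths <- ape::node.depth.edgelength(t3)[seq_len(3)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)

  expect_error(upgma_tree(d2[1, 1, drop = FALSE]), "2 leaves")
})

test_that("tied merges pick the lexicographically smallest pair", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(0.8, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.2
  t1 <- ape::write.tree(upgma_tree(d))
  t2 <- ape::write.tree(upgma_tree(d))
  expect_identical(t1, t2)
  # (A,B) merged before (C,D): it appears first in the newick string
  expect_lt(regexpr("A", t1), regexpr("C", t1))
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(stats::runif(n * 3), n)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
    mine <- ape::cophenetic.phylo(upgma_tree(d))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ref <- as.matrix(stats::cophenetic(hc))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
  }
})

test_that("segregation purity counts majority types at the root split", {
  perfect <- ape::read.tree(text = "((a1,a2,a3,a4,a5),(b1,b2,b3,b4,b5));")
  types <- stats::setNames(substr(perfect$tip.label, 1, 1),
                           perfect$tip.label)
  expect_equal(segregation_purity(perfect, types), 1)

  one_off <- ape::read.tree(text = "((a1,a2,a3,a4,a5),(b1,b2,b3,b4,a6));")
  types2 <- stats::setNames(substr(one_off$tip.label, 1, 1),
                            one_off$tip.label)
  expect_equal(segregation_purity(one_off, types2), 0.9)

  mixed <- ape::read.tree(text = paste0(
    "((a1,b1,a2,b2,a3,b3,a4,b4,a5,b5),",
    "(a6,b6,a7,b7,a8,b8,a9,b9,a10,b10));"))
  types3 <- stats::setNames(substr(mixed$tip.label, 1, 1), mixed$tip.label)
  expect_equal(segregation_purity(mixed, types3), 0.5)

  solo <- ape::read.tree(text = "(a1,a2);")
  expect_warning(p <- segregation_purity(solo, c(a1 = "a", a2 = "a")),
                 "single-type")
  expect_equal(p, 1)
})

test_that("zero-noise a/b stacks segregate perfectly", {
  sim <- simulate_protein(strrep("ab", 4), default_grammar, seed = 2)
  sc <- scan_proteins(sim$seq, default_grammar)
  seg <- segregate_modules(sc)
  expect_equal(seg$purity, 1)
  gl <- glance(seg)
  expect_identical(gl$n_modules, 8L)
  expect_equal(gl$mean_within, 0)
  expect_equal(gl$mean_between, 3 / 27, tolerance = 1e-12)
})

test_that("global alignment identity matches hand-computed cases", {
  s59 <- paste0(CANONICAL_A, CANONICAL_B, collapse = "")
  expect_equal(nw_identity(s59, s59), 100)
  expect_equal(nw_identity("ACD", "AED"), 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(nw_identity("AC", "A"), 50, tolerance = 1e-9)
  expect_error(nw_identity("", "A"))
})

test_that("alignment identity is symmetric and exact when gap-free", {
  set.seed(66)
  for (i in 1:10) {
    a <- random_protein(40)
    # few mismatches: the optimal global alignment stays gap-free
    bc <- strsplit(a, "")[[1]]
    pos <- sample(40, 3)
    bc[pos] <- sample(setdiff(LETTERS[1:20], bc[pos]), 3)
    bc[!bc %in% c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y")] <- "S"
    b <- paste(bc, collapse = "")
    expect_equal(nw_identity(a, b), nw_identity(b, a), tolerance = 1e-9)
    direct <- 100 * mean(strsplit(a, "")[[1]] == bc)
    expect_gte(nw_identity(a, b) + 1e-9, direct)
    expect_equal(nw_identity(a, b), direct, tolerance = 1e-9)
  }
})

test_that("alignment scores match an independent aligner", {
  nw_score <- function(s1, s2, match = 1, mismatch = 0, gap = -1) {
    a <- strsplit(s1, "")[[1]]
    b <- strsplit(s2, "")[[1]]
    aa <- unique(c(a, b))
    mat <- matrix(mismatch, length(aa), length(aa),
                  dimnames = list(aa, aa))
    diag(mat) <- match
    Biostrings::pairwiseAlignment(
      s1, s2, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
  }
  set.seed(77)
  for (i in 1:8) {
    s1 <- random_protein(sample(5:25, 1))
    s2 <- random_protein(sample(5:25, 1))
    expect_equal(crempr:::nw_align(s1, s2)$score, nw_score(s1, s2),
                 tolerance = 1e-9)
  }
})
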