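# Shared fixtures and independent oracles for the test suite.
# Expected strings below were derived once by direct construction from the
# conserved-position catalogue and frozen.

CANONICAL_A <- "CADAACPKGAACAAAAGAPACAAAAPA"           # 27 residues
CANONICAL_B <- "CADAACAKGAACAAAAGAPACAAAKAAAAAAA"      # 32 residues

default_grammar <- cremp_grammar()

random_protein <- function(len, c_prob = 0.12) {
  other <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), "C")
  p <- c(c_prob, rep((1 - c_prob) / length(other), length(other)))
  paste(sample(c("C", other), len, replace = TRUE, prob = p), collapse = "")
}

# Brute-force scanner: enumerate EVERY quadruple of cysteine positions and
# test every template, checking the no-cysteine constraint on each X region
# explicitly. Independent of the consecutive-anchor shortcut used by the
# package scanner.
brute_force_candidates <- function(residues, grammar) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")
  n <- length(chars)
  out <- list()
  if (length(cys) >= 4) {
    quads <- utils::combn(cys, 4)
    for (q in seq_len(ncol(quads))) {
      anchors <- quads[, q]
      # X regions between anchors must be cysteine-free
      clean <- TRUE
      for (i in 1:3) {
        span <- if (anchors[i] + 1 <= anchors[i + 1] - 1) {
          (anchors[i] + 1):(anchors[i + 1] - 1)
        } else integer(0)
        if (any(chars[span] == "C")) { clean <- FALSE; break }
      }
      if (!clean) next
      obs_gaps <- diff(anchors) - 1L
      for (sp in grammar$specs) {
        if (any(abs(obs_gaps - sp$internal_gaps) > sp$gap_tolerance)) next
        last_c <- anchors[4]
        later <- cys[cys > last_c]
        if (length(later)) {
          d <- later[1] - last_c - 1L
          if (d < sp$tail) next
          obs_tail <- if (d <= sp$tail + sp$max_tail_insert) d else sp$tail
        } else {
          if (n - last_c < sp$tail) next
          obs_tail <- sp$tail
        }
        if (any(chars[seq_len(obs_tail) + last_c] == "C")) next
        out[[length(out) + 1L]] <- data.frame(
          start = anchors[1] - 1L, end = last_c + obs_tail,
          spec_label = sp$label, observed_tail = obs_tail)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      spec_label = character(0),
                      observed_tail = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$spec_label), , drop = FALSE]
}

# Exhaustive chain search over all subsets of candidates (<= ~12):
# returns the best (coverage, n modules) achievable by a non-overlapping
# subset.
best_chain_exhaustive <- function(cand) {
  n <- nrow(cand)
  best_cov <- 0L
  best_n <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) > 1L) {
      o <- idx[order(cand$start[idx])]
      if (any(cand$start[o][-1L] < cand$end[o][-length(o)])) next
    }
    cov <- sum(cand$end[idx] - cand$start[idx])
    if (cov > best_cov || (cov == best_cov && length(idx) > best_n)) {
      best_cov <- cov
      best_n <- length(idx)
    }
  }
  list(coverage = best_cov, n = best_n)
}

# Direct Shannon entropy in bits of a vector of column symbols.
entropy_bits <- function(symbols) {
  p <- table(symbols) / length(symbols)
  -sum(p * log2(p))
}

# Smallest-period oracle: brute force over every prefix length.
smallest_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p == 0 && strrep(substr(s, 1, p), n / p) == s) return(p)
  }
  n
}

random_composition <- function() {
  v <- stats::runif(length(composition_keys()))
  stats::setNames(100 * v / sum(v), composition_keys())
}
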