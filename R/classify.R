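#' Classify a module hit into type a, b, or a variant thereof
#'
#' The rule cascade (applied in order):
#'
#' 1. **Canonical match** — observed gaps and tail equal a template exactly
#'    and no opposing-type diagnostic residue is present: the template's
#'    label (`a` or `b`), with evidence `tail_match` plus any diagnostics.
#' 2. **Diagnostic majority** — P at module positions 7 and/or 26 vote `a`;
#'    K at 25 votes `b`; a strict majority yields `a_variant`/`b_variant`
#'    (evidence lists the fired residues; `conflict` is recorded when both
#'    sides fire).
#' 3. **Tail proximity** — with no or tied votes, the effective tail
#'    (observed tail minus any tail insert) is compared to the canonical
#'    tails; the closer template wins as `*_variant`, equidistance gives
#'    `unknown`.
#'
#' Diagnostic positions are 1-based from the module's first cysteine and
#' anchored to the cysteine preceding them, so a shrunk/grown gap shifts
#' downstream positions by the cumulative offset. Residue `X` never matches
#' a diagnostic.
#'
#' @param hit One-row module-hit tibble (see [find_candidate_modules()]).
#' @param seq The residue string of the hit's sequence, or a
#'   protein-sequence tibble containing it.
#' @param grammar A [cremp_grammar()].
#' @return A list with elements `label` (one of `a`, `b`, `a_variant`,
#'   `b_variant`, `unknown`) and `evidence` (character vector of fired
#'   rules).
#' @examples
#' g <- cremp_grammar()
#' seqs <- protein_sequences("m", build_canonical_sequence(g$specs$a))
#' hit <- find_candidate_modules(seqs, g)[1, ]
#' classify_module(hit, seqs, g)
#' @export
classify_module <- function(hit, seq, grammar = cremp_grammar()) {
  hit <- as_tibble(hit)
  stopifnot(nrow(hit) == 1L)
  residues <- if (is.character(seq)) seq else {
    seq <- as_tibble(seq)
    seq$residues[match(hit$seq_id, seq$id)]
  }
  if (is.na(residues)) abort("hit's sequence not found in `seq`.")
  if (hit$start < 0L || hit$end > nchar(residues)) {
    abort("hit coordinates out of sequence bounds.")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  obs_gaps <- hit$observed_gaps[[1]]
  obs_tail <- hit$observed_tail
  eff_tail <- obs_tail - hit$insert_length

  # Fired type-specific diagnostics per template label.
  votes <- lapply(grammar$specs, function(sp) {
    rel <- grammar$catalogue[grammar$catalogue$scope == sp$label, ]
    if (!nrow(rel)) return(character(0))
    fired <- vapply(seq_len(nrow(rel)), function(i) {
      adj <- adjust_position(rel$position[i], sp, obs_gaps, obs_tail)
      !is.na(adj) && hit$start + adj <= length(chars) &&
        chars[hit$start + adj] == rel$residue[i]
    }, logical(1))
    paste0(rel$residue[fired], rel$position[fired])
  })
  n_votes <- vapply(votes, length, integer(1))

  # Rule 1: exact canonical template, unopposed.
  for (sp in grammar$specs) {
    if (length(obs_gaps) == length(sp$internal_gaps) &&
        all(obs_gaps == sp$internal_gaps) && obs_tail == sp$tail &&
        sum(n_votes[setdiff(names(n_votes), sp$label)]) == 0L) {
      return(list(label = sp$label,
                  evidence = c("tail_match", votes[[sp$label]])))
    }
  }

  evidence <- unlist(votes, use.names = FALSE)
  if (sum(n_votes > 0L) > 1L) evidence <- c(evidence, "conflict")

  # Rule 2: strict diagnostic majority.
  top <- which(n_votes == max(n_votes))
  if (max(n_votes) > 0L && length(top) == 1L) {
    return(list(label = paste0(names(n_votes)[top], "_variant"),
                evidence = evidence))
  }

  # Rule 3: tail proximity on the insert-corrected tail.
  dist <- vapply(grammar$specs, function(sp) abs(eff_tail - sp$tail),
                 numeric(1))
  nearest <- which(dist == min(dist))
  if (length(nearest) == 1L) {
    return(list(label = paste0(names(dist)[nearest], "_variant"),
                evidence = c(evidence, "tail_proximity")))
  }
  list(label = "unknown", evidence = evidence)
}

#' Classify every hit in a module-hit table
#'
#' Adds/overwrites the `label` column with the final classification and adds
#' `evidence` (list-column) and `base_type` (label with any `_variant`
#' suffix removed).
#'
#' @param hits Module-hit tibble.
#' @param seqs Protein-sequence tibble containing the hits' sequences.
#' @param grammar A [cremp_grammar()].
#' @return The classified hit tibble.
#' @export
classify_hits <- function(hits, seqs, grammar = cremp_grammar()) {
  hits <- as_tibble(hits)
  seqs <- coerce_seqs(seqs)
  if (!nrow(hits)) {
    hits$evidence <- list()
    hits$base_type <- character(0)
    return(hits)
  }
  res <- purrr::map(seq_len(nrow(hits)), function(i) {
    classify_module(hits[i, ], seqs, grammar)
  })
  hits$label <- vapply(res, `[[`, character(1), "label")
  hits$evidence <- purrr::map(res, "evidence")
  hits$base_type <- sub("_variant$", "", hits$label)
  hits
}
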