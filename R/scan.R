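#' Find all candidate module occurrences in protein sequences
#'
#' Every cysteine is treated as a potential module start. Because the
#' inter-cysteine spacers (`X` regions) may not contain cysteine, the three
#' following anchors of a candidate are necessarily the next three cysteines
#' in the sequence; a candidate is kept when each observed gap is within
#' `gap_tolerance` of a template's canonical gap. The tail after the last
#' anchor is the canonical tail, extended up to `max_tail_insert` extra
#' residues when the next module's anchoring cysteine lies farther away
#' (tail insertions are only observable when bounded by the next module); a
#' terminal module's tail is capped at the canonical tail, and a template
#' whose canonical tail does not fit before the sequence end yields no
#' candidate there.
#'
#' Coordinates are 0-based half-open (`start`, `end`); the provisional
#' `label` is the template whose canonical gaps match exactly, else
#' `"variant"`. Use [classify_hits()] or [scan_proteins()] for final type
#' assignment.
#'
#' @param seqs Protein-sequence tibble ([read_fasta()],
#'   [protein_sequences()]) or a single residue string.
#' @param grammar A [cremp_grammar()].
#' @return A tibble of candidate hits with columns `seq_id`, `start`, `end`,
#'   `label`, `spec_label`, `observed_gaps` (list), `observed_tail`,
#'   `insert_length`, `deviations` (list), `n_deviations`, `diag_score`.
#' @examples
#' g <- cremp_grammar()
#' seqs <- protein_sequences("m1", build_canonical_sequence(g$specs$a))
#' find_candidate_modules(seqs, g)
#' @export
find_candidate_modules <- function(seqs, grammar = cremp_grammar()) {
  stopifnot(inherits(grammar, "cremp_grammar"))
  seqs <- coerce_seqs(seqs)
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    scan_one(seqs$id[i], seqs$residues[i], grammar)
  })
}

coerce_seqs <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- protein_sequences(paste0("seq", seq_along(seqs)), seqs)
  }
  as_tibble(seqs)
}

empty_hits <- function() {
  tibble(seq_id = character(), start = integer(), end = integer(),
         label = character(), spec_label = character(),
         observed_gaps = list(), observed_tail = integer(),
         insert_length = integer(), deviations = list(),
         n_deviations = integer(), diag_score = integer())
}

scan_one <- function(seq_id, residues, grammar) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")
  n <- length(chars)
  out <- list()
  for (sp in grammar$specs) {
    ngap <- length(sp$internal_gaps)
    need <- ngap + 1L
    if (length(cys) < need) next
    for (k in seq_len(length(cys) - ngap)) {
      anchors <- cys[k:(k + ngap)]
      obs_gaps <- diff(anchors) - 1L
      if (any(abs(obs_gaps - sp$internal_gaps) > sp$gap_tolerance)) next
      last_c <- anchors[need]
      next_c <- if (k + need <= length(cys)) cys[k + need] else NA_integer_
      if (!is.na(next_c)) {
        d <- next_c - last_c - 1L
        if (d < sp$tail) next
        obs_tail <- if (d <= sp$tail + sp$max_tail_insert) d else sp$tail
      } else {
        # terminal module: tail capped at canonical; if the sequence ends
        # before a full canonical tail the template cannot complete here
        if (n - last_c < sp$tail) next
        obs_tail <- sp$tail
      }
      insert <- max(0L, obs_tail - sp$tail)
      start <- anchors[1] - 1L          # 0-based
      end <- last_c + obs_tail          # half-open
      devs <- character(0)
      if (any(obs_gaps < sp$internal_gaps)) devs <- c(devs, "gap_shrunk")
      if (any(obs_gaps > sp$internal_gaps)) devs <- c(devs, "gap_grown")
      if (insert > 0L) devs <- c(devs, "tail_insert")
      n_dev <- sum(obs_gaps != sp$internal_gaps) + (insert > 0L)
      label <- if (all(obs_gaps == sp$internal_gaps)) sp$label else "variant"
      diag <- diag_agreement(chars, start, obs_gaps, obs_tail, sp,
                             grammar$catalogue)
      out[[length(out) + 1L]] <- tibble(
        seq_id = seq_id, start = start, end = end, label = label,
        spec_label = sp$label, observed_gaps = list(obs_gaps),
        observed_tail = obs_tail, insert_length = insert,
        deviations = list(devs), n_deviations = n_dev, diag_score = diag)
    }
  }
  if (!length(out)) return(empty_hits())
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end,
                 .data$spec_label)
}

# Map a catalogue position (1-based, canonical frame of `spec`) to the
# observed frame of a hit with gap deviations: positions are anchored to the
# preceding cysteine, so downstream positions shift by the cumulative gap
# offset. Returns NA when the position falls outside its segment or the hit.
adjust_position <- function(p, spec, obs_gaps, obs_tail) {
  cc <- cys_positions(spec)
  oc <- cumsum(c(1L, obs_gaps + 1L))
  hit_len <- length(oc) + sum(obs_gaps) + obs_tail
  if (p %in% cc) return(oc[match(p, cc)])
  seg <- findInterval(p, cc)           # cysteine preceding p
  if (seg == 0L) return(NA_integer_)
  adj <- p + (oc[seg] - cc[seg])
  upper <- if (seg < length(oc)) oc[seg + 1L] - 1L else hit_len
  if (adj <= oc[seg] || adj > upper) return(NA_integer_)
  adj
}

# Number of catalogued residues (shared + the spec's own scope) present at
# their adjusted positions within a candidate.
diag_agreement <- function(chars, start, obs_gaps, obs_tail, spec,
                           catalogue) {
  rel <- catalogue[catalogue$scope %in% c("shared", spec$label), ]
  if (!nrow(rel)) return(0L)
  hits <- vapply(seq_len(nrow(rel)), function(i) {
    adj <- adjust_position(rel$position[i], spec, obs_gaps, obs_tail)
    if (is.na(adj)) return(FALSE)
    pos <- start + adj
    pos <= length(chars) && chars[pos] == rel$residue[i]
  }, logical(1))
  sum(hits)
}

#' Chain candidate modules into non-overlapping repeat regions
#'
#' Selects a non-overlapping subset of candidates maximising (primarily)
#' total residues covered and (secondarily) number of modules, by dynamic
#' programming over candidates sorted by end (weighted interval scheduling).
#' Ties are broken toward chains with fewer deviations, then higher
#' diagnostic-residue agreement, deterministically. Maximal runs of selected
#' modules separated by at most `max_gap_between_modules` non-module residues
#' become one region.
#'
#' @param candidates Candidate tibble from [find_candidate_modules()].
#' @param max_gap_between_modules Non-module residues tolerated between
#'   consecutive modules of one region (default 0: contiguous repeats).
#' @return A region tibble: `seq_id`, `region`, `start`, `end`, `n_modules`,
#'   and a list-column `hits` holding each region's selected module hits.
#' @export
chain_modules <- function(candidates, max_gap_between_modules = 0L) {
  candidates <- as_tibble(candidates)
  if (!nrow(candidates)) {
    return(tibble(seq_id = character(), region = integer(),
                  start = integer(), end = integer(),
                  n_modules = integer(), hits = list()))
  }
  candidates |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(chain_one, max_gap = max_gap_between_modules)
}

# Lexicographic comparison of additive chain scores:
# (coverage, n modules, -deviations, diagnostic agreement).
chain_score <- function(h) {
  c(h$end - h$start, 1, -h$n_deviations, h$diag_score)
}

chain_one <- function(cand, max_gap = 0L) {
  cand <- dplyr::arrange(cand, .data$end, .data$start, .data$spec_label)
  n <- nrow(cand)
  scores <- vapply(seq_len(n), function(j) chain_score(cand[j, ]),
                   numeric(4))
  # F[, k+1]: best score over the first k candidates; take[k]/pred[k] for
  # reconstruction of the chain ending at k.
  F <- matrix(0, nrow = 4, ncol = n + 1L)
  take <- logical(n)
  ends <- cand$end
  for (k in seq_len(n)) {
    p <- findInterval(cand$start[k], ends) # last i with end_i <= start_k
    with_k <- scores[, k] + F[, p + 1L]
    if (lex_gt(with_k, F[, k])) {
      F[, k + 1L] <- with_k
      take[k] <- TRUE
    } else {
      F[, k + 1L] <- F[, k]
    }
  }
  sel <- integer(0)
  k <- n
  while (k > 0L) {
    if (take[k] && all(F[, k + 1L] == scores[, k] +
                         F[, findInterval(cand$start[k], ends) + 1L])) {
      sel <- c(k, sel)
      k <- findInterval(cand$start[k], ends)
    } else {
      k <- k - 1L
    }
  }
  chosen <- cand[sel, , drop = FALSE]
  chosen <- dplyr::arrange(chosen, .data$start)
  if (!nrow(chosen)) {
    return(tibble(seq_id = character(), region = integer(),
                  start = integer(), end = integer(),
                  n_modules = integer(), hits = list()))
  }
  breaks <- c(0L, which(chosen$start[-1L] - chosen$end[-nrow(chosen)] >
                          max_gap), nrow(chosen))
  purrr::map_dfr(seq_len(length(breaks) - 1L), function(r) {
    rows <- (breaks[r] + 1L):breaks[r + 1L]
    h <- chosen[rows, , drop = FALSE]
    tibble(seq_id = h$seq_id[1], region = r, start = h$start[1],
           end = h$end[nrow(h)], n_modules = nrow(h), hits = list(h))
  })
}

lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Architecture string of a repeat region
#'
#' One letter per module in order: classified `a`/`a_variant` render as
#' `"a"`, `b`/`b_variant` as `"b"`, and unclassified or unknown modules as
#' `"v"`.
#'
#' @param region A one-row region tibble (from [chain_modules()]), a hit
#'   tibble, or a character vector of labels.
#' @return A single string.
#' @export
architecture_string <- function(region) {
  labels <- if (is.character(region)) {
    region
  } else if (is.data.frame(region) && "hits" %in% names(region)) {
    if (nrow(region) == 0L) character(0) else region$hits[[1]]$label
  } else if (is.data.frame(region)) {
    region$label
  } else {
    abort("cannot extract module labels from `region`.")
  }
  if (!length(labels)) return("")
  letters1 <- dplyr::case_when(
    labels %in% c("variant", "unknown") ~ "v",
    TRUE ~ substr(sub("_variant$", "", labels), 1L, 1L)
  )
  paste(letters1, collapse = "")
}

#' Compress an architecture string into its smallest periodic pattern
#'
#' Finds the smallest period `p` dividing the string length such that the
#' string is the `p`-prefix repeated; returns `"(unit)k"`. A string with no
#' shorter period is returned as `"(string)1"`.
#'
#' @param arch Architecture string over the module-label alphabet.
#' @return A string like `"(ab)2"`.
#' @examples
#' compress_pattern("abab")   # "(ab)2"
#' compress_pattern("abbabb") # "(abb)2"
#' @export
compress_pattern <- function(arch) {
  stopifnot(is.character(arch), length(arch) == 1L)
  n <- nchar(arch)
  if (n == 0L) return("")
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    unit <- substr(arch, 1L, p)
    if (strrep(unit, n %/% p) == arch) {
      return(sprintf("(%s)%d", unit, n %/% p))
    }
  }
  sprintf("(%s)1", arch)
}

#' Scan proteins for module repeats: detect, chain and classify
#'
#' End-to-end driver: [find_candidate_modules()], [chain_modules()],
#' [classify_hits()], plus per-region architecture strings and compressed
#' periodic patterns.
#'
#' @inheritParams find_candidate_modules
#' @inheritParams chain_modules
#' @return An object of class `cremp_scan`: list with `seqs`, `grammar`,
#'   `hits` (classified selected modules) and `regions` (with `architecture`
#'   and `pattern` columns). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' g <- cremp_grammar()
#' ab <- paste0(build_canonical_sequence(g$specs$a),
#'              build_canonical_sequence(g$specs$b))
#' scan <- scan_proteins(protein_sequences("rep1", ab), g)
#' glance(scan)
#' @export
scan_proteins <- function(seqs, grammar = cremp_grammar(),
                          max_gap_between_modules = 0L) {
  seqs <- coerce_seqs(seqs)
  cand <- find_candidate_modules(seqs, grammar)
  regions <- chain_modules(cand, max_gap_between_modules)
  regions$hits <- purrr::map(regions$hits, classify_hits, seqs = seqs,
                             grammar = grammar)
  regions$architecture <- vapply(regions$hits, architecture_string,
                                 character(1))
  regions$pattern <- vapply(regions$architecture, compress_pattern,
                            character(1), USE.NAMES = FALSE)
  hits <- if (nrow(regions)) dplyr::bind_rows(regions$hits) else
    classify_hits(empty_hits(), seqs, grammar)
  structure(list(seqs = seqs, grammar = grammar, hits = hits,
                 regions = regions),
            class = "cremp_scan")
}

#' @export
print.cremp_scan <- function(x, ...) {
  cat(sprintf("<cremp_scan> %d sequence(s): %d module(s) in %d region(s)\n",
              nrow(x$seqs), nrow(x$hits), nrow(x$regions)))
  if (nrow(x$regions)) {
    print(dplyr::select(x$regions, -"hits"))
  }
  invisible(x)
}

#' @rdname scan_proteins
#' @param x A `cremp_scan` object.
#' @param ... Unused.
#' @method tidy cremp_scan
#' @export
tidy.cremp_scan <- function(x, ...) x$hits

#' @rdname scan_proteins
#' @method glance cremp_scan
#' @export
glance.cremp_scan <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$seqs),
    n_modules = nrow(x$hits),
    n_regions = nrow(x$regions),
    residues_covered = sum(x$hits$end - x$hits$start),
    total_residues = sum(nchar(x$seqs$residues))
  )
}

#' @rdname scan_proteins
#' @param object A `cremp_scan` object.
#' @method autoplot cremp_scan
#' @export
autoplot.cremp_scan <- function(object, ...) {
  seq_len_tbl <- tibble(seq_id = object$seqs$id,
                        len = nchar(object$seqs$residues))
  hits <- dplyr::mutate(object$hits,
                        type = substr(sub("_variant$", "", .data$label), 1, 1))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seq_len_tbl,
      ggplot2::aes(x = 0, xend = .data$len, y = .data$seq_id,
                   yend = .data$seq_id),
      linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_tile(
      data = hits,
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$seq_id,
                   width = .data$end - .data$start, fill = .data$type),
      height = 0.6, colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = "residue (0-based)", y = NULL, fill = "module type") +
    ggplot2::theme_minimal()
}
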