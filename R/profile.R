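#' Stack same-type modules into an alignment-free matrix of rows
#'
#' Same-type stacking keeps each module's full canonical length (27 for a,
#' 32 for b), excluding gap-deviant modules (shrunk/grown internal gaps);
#' modules with tail inserts contribute only their canonical-length prefix,
#' since inserts are C-terminal extensions. Cross-type stacking trims
#' exactly 5 residues from the C-terminus of every b module so all rows are
#' the a-module length, reproducing the equal-length device used to compare
#' the two types.
#'
#' @param x A `cremp_scan` object, or a classified module-hit tibble (then
#'   `seqs` is required).
#' @param type `"a"`, `"b"`, or `"cross"` (both types, b rows trimmed).
#' @param seqs Protein-sequence tibble (when `x` is a hit tibble).
#' @param grammar A [cremp_grammar()].
#' @return An object of class `cremp_stack`: list with `type`, `rows`
#'   (character vector of equal-length residue strings) and `source`
#'   (tibble `seq_id`, `start`, `label`, `base_type`).
#' @export
stack_modules <- function(x, type = c("a", "b", "cross"), seqs = NULL,
                          grammar = cremp_grammar()) {
  type <- match.arg(type)
  if (inherits(x, "cremp_scan")) {
    seqs <- x$seqs
    grammar <- x$grammar
    hits <- x$hits
  } else {
    hits <- as_tibble(x)
    if (is.null(seqs)) abort("`seqs` is required when `x` is a hit tibble.")
    seqs <- coerce_seqs(seqs)
  }
  if (!"base_type" %in% names(hits)) {
    hits <- classify_hits(hits, seqs, grammar)
  }
  wanted <- if (type == "cross") names(grammar$specs) else type
  keep <- hits$base_type %in% wanted &
    vapply(seq_len(nrow(hits)), function(i) {
      sp <- grammar$specs[[hits$base_type[i]]]
      !is.null(sp) &&
        length(hits$observed_gaps[[i]]) == length(sp$internal_gaps) &&
        all(hits$observed_gaps[[i]] == sp$internal_gaps) &&
        (hits$observed_tail[i] - hits$insert_length[i]) == sp$tail
    }, logical(1))
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) {
    abort("empty module stack after filtering (no canonical-geometry modules of the requested type).")
  }
  row_len <- if (type == "cross") {
    min(vapply(grammar$specs[unique(hits$base_type)], module_length,
               integer(1)))
  } else {
    module_length(grammar$specs[[type]])
  }
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    res <- seqs$residues[match(hits$seq_id[i], seqs$id)]
    substr(res, hits$start[i] + 1L, hits$start[i] + row_len)
  }, character(1))
  structure(
    list(type = type, rows = rows,
         source = tibble(seq_id = hits$seq_id, start = hits$start,
                         label = hits$label, base_type = hits$base_type)),
    class = "cremp_stack"
  )
}

#' @export
print.cremp_stack <- function(x, ...) {
  cat(sprintf("<cremp_stack '%s'> %d row(s) x %d position(s)\n",
              x$type, length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Position frequency and information-content profile of a module stack
#'
#' Per-position empirical residue fractions and sequence-logo information
#' content in bits: `log2(20) - H`, where `H` is the Shannon entropy of the
#' position's residue distribution. `X` counts as its own symbol in the
#' frequencies and contributes its fraction to `H` (it is never
#' informative); information is clamped to `[0, log2 20]`.
#'
#' @param stack A `cremp_stack` from [stack_modules()], or a character
#'   vector of equal-length residue strings.
#' @return An object of class `cremp_profile`: list with `length`,
#'   `n_rows`, `frequencies` (residue x position matrix of fractions) and
#'   `information` (bits per position). Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
position_profile <- function(stack) {
  rows <- if (inherits(stack, "cremp_stack")) stack$rows else stack
  stopifnot(is.character(rows), length(rows) >= 1L)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) abort("stack rows must have equal length.")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  symbols <- sort(aa_alphabet())
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = symbols))
    as.numeric(tab) / length(rows)
  }, numeric(length(symbols)))
  rownames(freq) <- symbols
  info <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    min(max(log2(20) - h, 0), log2(20))
  })
  structure(
    list(length = L, n_rows = length(rows), frequencies = freq,
         information = unname(info)),
    class = "cremp_profile"
  )
}

#' @export
print.cremp_profile <- function(x, ...) {
  cat(sprintf(
    "<cremp_profile> %d position(s), %d row(s); mean information %.3f bits\n",
    x$length, x$n_rows, mean(x$information)))
  invisible(x)
}

#' Positions conserved above a fraction threshold
#'
#' Returns every position whose most frequent residue reaches
#' `min_fraction`; ties between residues are broken toward the
#' lexicographically smaller residue.
#'
#' @param profile A `cremp_profile`.
#' @param min_fraction Minimum top-residue fraction (default 1.0: absolute
#'   conservation).
#' @return Tibble with columns `position` (1-based), `residue`, `fraction`.
#' @export
conserved_positions <- function(profile, min_fraction = 1.0) {
  stopifnot(inherits(profile, "cremp_profile"))
  top <- apply(profile$frequencies, 2, which.max) # rows sorted: lexicographic
  frac <- profile$frequencies[cbind(top, seq_len(profile$length))]
  keep <- frac >= min_fraction
  tibble(position = which(keep),
         residue = rownames(profile$frequencies)[top[keep]],
         fraction = frac[keep])
}

#' Consensus sequence of a profile
#'
#' Per-position top residue; ties broken lexicographically.
#'
#' @param profile A `cremp_profile`.
#' @return A residue string of length `profile$length`.
#' @export
consensus <- function(profile) {
  stopifnot(inherits(profile, "cremp_profile"))
  top <- apply(profile$frequencies, 2, which.max)
  paste(rownames(profile$frequencies)[top], collapse = "")
}

#' @rdname position_profile
#' @param x A `cremp_profile`.
#' @param ... Unused.
#' @method tidy cremp_profile
#' @export
tidy.cremp_profile <- function(x, ...) {
  freq <- as_tibble(t(x$frequencies))
  freq$position <- seq_len(x$length)
  long <- tidyr::pivot_longer(freq, -"position", names_to = "residue",
                              values_to = "frequency")
  long <- long[long$frequency > 0, , drop = FALSE]
  long$information <- x$information[long$position]
  long
}

#' @rdname position_profile
#' @method glance cremp_profile
#' @export
glance.cremp_profile <- function(x, ...) {
  tibble(
    positions = x$length,
    n_modules = x$n_rows,
    mean_information = mean(x$information),
    n_conserved = nrow(conserved_positions(x))
  )
}

#' @rdname position_profile
#' @param object A `cremp_profile`.
#' @method autoplot cremp_profile
#' @export
autoplot.cremp_profile <- function(object, ...) {
  cons <- strsplit(consensus(object), "", fixed = TRUE)[[1]]
  df <- tibble(position = seq_len(object$length),
               information = object$information,
               residue = cons)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$information)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$residue == "C"),
                      show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue),
                       vjust = -0.3, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d4a017",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "module position (1 = first cysteine)",
                  y = "information (bits)") +
    ggplot2::ylim(0, log2(20) * 1.08) +
    ggplot2::theme_minimal()
}
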