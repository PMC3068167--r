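#' Construct a validated protein-sequence table
#'
#' Sequences flow through the package as tibbles with one row per protein and
#' columns `id`, `description`, `residues`. Residues are upper-cased and
#' checked against the 20 standard one-letter codes plus `X` (unknown).
#'
#' @param id Character vector of non-empty identifiers.
#' @param residues Character vector of amino-acid strings.
#' @param description Optional free-text descriptions (default empty).
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' protein_sequences("s1", "CADAA")
#' @export
protein_sequences <- function(id, residues, description = "") {
  stopifnot(is.character(id), is.character(residues),
            length(id) == length(residues))
  if (any(!nzchar(id)) || any(grepl("\\s", id))) {
    abort("sequence ids must be non-empty tokens without whitespace.")
  }
  description <- rep_len(as.character(description), length(id))
  id <- unname(id)
  description <- unname(description)
  residues <- unname(toupper(residues))
  purrr::walk2(id, residues, validate_residues)
  tibble(id = id, description = description, residues = residues)
}

# Error if a residue string contains characters outside the alphabet,
# reporting the record and the first offending position.
validate_residues <- function(id, residues) {
  if (nchar(residues) < 1L) {
    abort(sprintf("record '%s' has an empty sequence.", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad)) {
    abort(sprintf(
      "record '%s': illegal residue '%s' at position %d (allowed: 20 standard codes plus X).",
      id, chars[bad[1]], bad[1]))
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Lower-case input is normalised to upper case; the description (text after
#' the first whitespace in the header) is retained but never used in
#' computation. Characters outside the 20 standard codes plus `X` raise an
#' error naming the record and offending position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  protein_sequences(ids, as.character(set), desc)
}

#' Write protein sequences to a FASTA file
#'
#' Sequence lines are wrapped at 60 columns; `read_fasta(write_fasta(x))`
#' reproduces `x` exactly. An empty table writes an empty file.
#'
#' @param seqs Tibble as returned by [read_fasta()] / [protein_sequences()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_tibble(seqs)
  if (nrow(seqs) > 0) {
    seqs <- protein_sequences(seqs$id, seqs$residues,
                              seqs$description %||% "")
  }
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- ifelse(nzchar(seqs$description %||% character(0)),
                       paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## Annotation output ----------------------------------------------------------

annotation_columns <- c("seq_id", "start", "end", "label", "observed_gaps",
                        "observed_tail", "insert_length", "deviations")

# Flatten list-columns for text output: integer vectors -> "4,5,8".
flatten_hits <- function(hits) {
  hits <- as_tibble(hits)
  tibble(
    seq_id = hits$seq_id,
    start = hits$start,
    end = hits$end,
    start1 = hits$start + 1L,
    end1 = hits$end,
    label = hits$label,
    observed_gaps = vapply(hits$observed_gaps, paste, character(1),
                           collapse = ","),
    observed_tail = hits$observed_tail,
    insert_length = hits$insert_length,
    deviations = vapply(hits$deviations, paste, character(1), collapse = ",")
  )
}

#' Write module annotations to TSV, BED or JSON
#'
#' All three formats encode the same information. Internal coordinates are
#' 0-based half-open; the TSV additionally carries 1-based inclusive columns
#' (`start1`, `end1`) matching residue numbering in the literature; BED uses
#' the 0-based half-open convention directly.
#'
#' @param hits Module-hit tibble (from [find_candidate_modules()],
#'   [scan_proteins()], ...).
#' @param path Output path.
#' @param format One of `"tsv"`, `"bed"`, `"json"`.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(hits, path, format = c("tsv", "bed", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(
                       paste0("unknown annotation format: ",
                              format[1], " (use tsv, bed or json).")))
  hits <- as_tibble(hits)
  if (format == "tsv") {
    readr::write_tsv(flatten_hits(hits), path)
  } else if (format == "bed") {
    bed <- tibble(chrom = hits$seq_id, start = hits$start, end = hits$end,
                  name = hits$label, score = 0L, strand = "+")
    readr::write_tsv(bed, path, col_names = FALSE)
  } else {
    recs <- purrr::map(seq_len(nrow(hits)), function(i) {
      list(seq_id = hits$seq_id[i], start = hits$start[i], end = hits$end[i],
           label = hits$label[i],
           observed_gaps = as.integer(hits$observed_gaps[[i]]),
           observed_tail = hits$observed_tail[i],
           insert_length = hits$insert_length[i],
           deviations = as.character(hits$deviations[[i]]))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read module annotations written by [write_annotations()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"` (BED drops the spacing detail and is
#'   write-only).
#' @return A module-hit tibble with list-columns `observed_gaps` and
#'   `deviations`.
#' @export
read_annotations <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           observed_gaps = readr::col_character(),
                           deviations = readr::col_character()))
    gaps <- purrr::map(x$observed_gaps %||% character(0), parse_int_csv)
    devs <- purrr::map(x$deviations %||% character(0), parse_chr_csv)
    tibble(seq_id = x$seq_id, start = as.integer(x$start),
           end = as.integer(x$end), label = x$label,
           observed_gaps = gaps,
           observed_tail = as.integer(x$observed_tail),
           insert_length = as.integer(x$insert_length),
           deviations = devs)
  } else {
    recs <- jsonlite::read_json(path)
    purrr::map_dfr(recs, function(r) {
      tibble(seq_id = r$seq_id, start = as.integer(r$start),
             end = as.integer(r$end), label = r$label,
             observed_gaps = list(as.integer(unlist(r$observed_gaps))),
             observed_tail = as.integer(r$observed_tail),
             insert_length = as.integer(r$insert_length),
             deviations = list(as.character(unlist(r$deviations))))
    })
  }
}

parse_int_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) integer(0)
  else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

parse_chr_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ",", fixed = TRUE)[[1]]
}
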