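#' Aggregated amino-acid composition of a set of sequences
#'
#' Residue counts are pooled across sequences and reported as percentages
#' over 17 components: the 20 standard residues minus tryptophan, with
#' aspartate+asparagine merged into `DN` and glutamate+glutamine into `EQ`.
#' This matches the convention used to compare gene-derived compositions
#' with acid-hydrolysis amino-acid analyses, where Asp/Asn and Glu/Gln are
#' indistinguishable and Trp is destroyed. `W` and `X` are excluded from
#' both numerator and denominator.
#'
#' @param seqs Protein-sequence tibble or character vector of residue
#'   strings.
#' @return An object of class `composition_vector`: list with `percent`
#'   (named numeric over the 17 keys, summing to 100) and `total_residues`
#'   (residues counted after exclusions).
#' @examples
#' composition_vector("DN")$percent[["DN"]] # 100
#' @export
composition_vector <- function(seqs) {
  seqs <- coerce_seqs(seqs)
  chars <- unlist(strsplit(seqs$residues, "", fixed = TRUE))
  chars <- chars[!chars %in% c("W", "X")]
  if (!length(chars)) {
    abort("no residues left after excluding W and X.")
  }
  counts <- table(factor(chars, levels = setdiff(aa_standard(), "W")))
  merged <- c(
    counts[setdiff(names(counts), c("D", "N", "E", "Q"))],
    DN = sum(counts[c("D", "N")]),
    EQ = sum(counts[c("E", "Q")])
  )
  merged <- merged[composition_keys()]
  percent <- setNames(100 * as.numeric(merged) / sum(merged),
                      composition_keys())
  structure(
    list(percent = percent, total_residues = length(chars)),
    class = "composition_vector"
  )
}

#' The 17 composition components
#'
#' @return Character vector of component keys.
#' @export
composition_keys <- function() {
  sort(c(setdiff(aa_standard(), c("W", "D", "N", "E", "Q")), "DN", "EQ"))
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("<composition_vector> %d residue(s)\n", x$total_residues))
  print(round(x$percent, 2))
  invisible(x)
}

#' @method tidy composition_vector
#' @export
tidy.composition_vector <- function(x, ...) {
  tibble(component = names(x$percent), percent = unname(x$percent))
}

as_percent_vector <- function(v) {
  if (inherits(v, "composition_vector")) return(v$percent)
  if (is.numeric(v) && !is.null(names(v))) return(v)
  abort("expected a composition_vector or a named numeric vector.")
}

#' Euclidean distance between two composition vectors
#'
#' Square root of the sum of squared per-component percentage differences.
#'
#' @param v1,v2 `composition_vector` objects (or named percentage vectors
#'   over the same keys).
#' @return A non-negative number.
#' @examples
#' a <- composition_vector("GGGG")
#' euclidean_distance(a, a) # 0
#' @export
euclidean_distance <- function(v1, v2) {
  p1 <- as_percent_vector(v1)
  p2 <- as_percent_vector(v2)
  if (!setequal(names(p1), names(p2))) {
    abort("composition vectors have mismatched component keys.")
  }
  p2 <- p2[names(p1)]
  if (anyNA(p1) || anyNA(p2)) {
    abort("composition vectors contain missing components.")
  }
  sqrt(sum((p1 - p2)^2))
}

#' Rank reference compositions by distance from a query
#'
#' @param query A `composition_vector` (or named percentage vector).
#' @param refs A named list of compositions, or a data frame with a `label`
#'   column plus one column per composition key.
#' @return Tibble `label`, `distance`, ascending by distance (ties broken
#'   by label).
#' @export
rank_references <- function(query, refs) {
  if (is.data.frame(refs)) {
    labs <- refs$label
    refs <- purrr::map(seq_len(nrow(refs)), function(i) {
      v <- unlist(refs[i, setdiff(names(refs), "label")])
      v[!is.na(v)]
    })
    names(refs) <- labs
  }
  if (!length(refs)) abort("`refs` must be non-empty.")
  d <- vapply(refs, euclidean_distance, numeric(1), v1 = query)
  out <- tibble(label = names(refs), distance = unname(d))
  dplyr::arrange(out, .data$distance, .data$label)
}

#' Read reference compositions from a YAML config
#'
#' Each entry maps a label to a named percentage table over the composition
#' keys, optionally with `Hyl`/`Hyp` entries (hydroxylysine/-proline from
#' acid-hydrolysis literature), which are added to `K` and `P` at load.
#' Entries covering only part of the key set are returned as-is and flagged
#' with a warning: they document known components (the shipped eggshell
#' membrane entry pins only Gly and Cys, the two values reported in the
#' source literature) and must be completed by the user before distance
#' ranking.
#'
#' @param path YAML file; defaults to the shipped reference table.
#' @return Named list of percentage vectors.
#' @export
read_composition_refs <- function(path = system.file(
  "extdata", "composition_refs.yaml", package = "crempr")) {
  y <- yaml::read_yaml(path)
  refs <- purrr::map(y, function(e) {
    v <- unlist(e)
    v <- v[!names(v) %in% c("note")]
    v <- vapply(v, as.numeric, numeric(1))
    if ("Hyl" %in% names(v)) {
      v["K"] <- sum(v[c("K", "Hyl")], na.rm = TRUE)
      v <- v[names(v) != "Hyl"]
    }
    if ("Hyp" %in% names(v)) {
      v["P"] <- sum(v[c("P", "Hyp")], na.rm = TRUE)
      v <- v[names(v) != "Hyp"]
    }
    v
  })
  partial <- names(refs)[vapply(refs, function(v) {
    !all(composition_keys() %in% names(v))
  }, logical(1))]
  if (length(partial)) {
    warn(paste0("partial reference composition(s): ",
                paste(partial, collapse = ", "),
                " (distance ranking requires all ",
                length(composition_keys()), " components)."))
  }
  refs
}
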