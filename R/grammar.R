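#' Define a cysteine-spacing module template
#'
#' A module is a run of cysteines with fixed inter-cysteine spacings plus a
#' cysteine-free C-terminal tail. The canonical CREMP types are
#' `a = C-X4-C-X5-C-X8-C-X6` (27 residues) and `b = C-X4-C-X5-C-X8-C-X11`
#' (32 residues).
#'
#' @param label Single-letter (or short token) type label, e.g. `"a"`.
#' @param internal_gaps Integer vector of residues between consecutive
#'   cysteines; the module contains `length(internal_gaps) + 1` cysteines.
#' @param tail Number of residues after the last cysteine.
#' @param gap_tolerance Allowed per-gap deviation (residues) when scanning.
#' @param max_tail_insert Maximum number of extra residues tolerated between
#'   the canonical tail and the next module's anchoring cysteine. The default
#'   (64) accommodates the longest tail insertion observed in lizard CREMP
#'   (59 residues).
#'
#' @return An object of class `module_spec`.
#' @examples
#' a <- module_spec("a", c(4, 5, 8), 6)
#' module_length(a) # 27
#' @export
module_spec <- function(label, internal_gaps, tail,
                        gap_tolerance = 1L, max_tail_insert = 64L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  internal_gaps <- as.integer(internal_gaps)
  if (any(internal_gaps < 0L)) {
    abort("`internal_gaps` must be non-negative integers.")
  }
  tail <- as.integer(tail)
  stopifnot(length(tail) == 1L, tail >= 0L)
  gap_tolerance <- as.integer(gap_tolerance)
  max_tail_insert <- as.integer(max_tail_insert)
  stopifnot(gap_tolerance >= 0L, max_tail_insert >= 0L)
  structure(
    list(
      label = label,
      internal_gaps = internal_gaps,
      tail = tail,
      gap_tolerance = gap_tolerance,
      max_tail_insert = max_tail_insert
    ),
    class = "module_spec"
  )
}

#' @export
print.module_spec <- function(x, ...) {
  pat <- paste0("C", paste0("-X", x$internal_gaps, "-C", collapse = ""),
                "-X", x$tail)
  cat(sprintf("<module_spec '%s'> %s (%d residues, tol %d, max insert %d)\n",
              x$label, pat, module_length(x), x$gap_tolerance,
              x$max_tail_insert))
  invisible(x)
}

#' Total residue length of a module template
#'
#' `(n cysteines) + sum(internal_gaps) + tail`.
#'
#' @param spec A [module_spec()].
#' @return Integer length in residues.
#' @examples
#' module_length(module_spec("a", c(4, 5, 8), 6))  # 27
#' module_length(module_spec("b", c(4, 5, 8), 11)) # 32
#' @export
module_length <- function(spec) {
  stopifnot(inherits(spec, "module_spec"))
  (length(spec$internal_gaps) + 1L) + sum(spec$internal_gaps) + spec$tail
}

#' Total residue length of an ordered run of module templates
#'
#' The canonical CREMP repeat (one a followed by one b module) is 59 residues;
#' the expressed two-repeat fragment (a-b-a-b) is 118.
#'
#' @param specs A non-empty list of [module_spec()] objects.
#' @return Integer length in residues.
#' @examples
#' g <- cremp_grammar()
#' repeat_length(list(g$specs$a, g$specs$b)) # 59
#' @export
repeat_length <- function(specs) {
  if (inherits(specs, "module_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  sum(vapply(specs, module_length, integer(1)))
}

#' Cysteine anchor positions of a module template
#'
#' Positions are 1-based from the module's first cysteine (position 1), the
#' numbering used for all diagnostic residues.
#'
#' @param spec A [module_spec()].
#' @return Integer vector of cysteine positions.
#' @export
cys_positions <- function(spec) {
  stopifnot(inherits(spec, "module_spec"))
  cumsum(c(1L, spec$internal_gaps + 1L))
}

#' The conserved-residue catalogue of CREMP modules
#'
#' Positions are 1-based from the module's first cysteine. Shared positions
#' (D3, K8, G9, G17, P19) are absolutely conserved in both module types;
#' P7 and P26 occur only in type a, K25 only in type b.
#'
#' @return A tibble with columns `position`, `residue`, `scope` (`"shared"`
#'   or a type label).
#' @export
conserved_catalogue <- function() {
  tibble(
    position = c(3L, 8L, 9L, 17L, 19L, 7L, 26L, 25L),
    residue  = c("D", "K", "G", "G", "P", "P", "P", "K"),
    scope    = c(rep("shared", 5L), "a", "a", "b")
  )
}

#' The default CREMP module grammar
#'
#' Bundles the canonical a and b module templates (both `C-X4-C-X5-C-X8-C`
#' with 6- and 11-residue tails respectively) with the conserved-residue
#' catalogue.
#'
#' @inheritParams module_spec
#' @param catalogue Conserved-residue tibble; see [conserved_catalogue()].
#' @return An object of class `cremp_grammar`: a list with elements `specs`
#'   (named list of [module_spec()]) and `catalogue`.
#' @examples
#' cremp_grammar()
#' @export
cremp_grammar <- function(gap_tolerance = 1L, max_tail_insert = 64L,
                          catalogue = conserved_catalogue()) {
  grammar(
    specs = list(
      module_spec("a", c(4L, 5L, 8L), 6L, gap_tolerance, max_tail_insert),
      module_spec("b", c(4L, 5L, 8L), 11L, gap_tolerance, max_tail_insert)
    ),
    catalogue = catalogue
  )
}

#' Build a grammar from module templates and a catalogue
#'
#' @param specs List of [module_spec()] objects with distinct labels.
#' @param catalogue Tibble with columns `position`, `residue`, `scope`; scope
#'   is `"shared"` or one of the spec labels.
#' @return A `cremp_grammar` object.
#' @export
grammar <- function(specs, catalogue = conserved_catalogue()) {
  stopifnot(is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "module_spec")))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("module spec labels must be distinct.")
  names(specs) <- labels
  catalogue <- as_tibble(catalogue)
  stopifnot(all(c("position", "residue", "scope") %in% names(catalogue)))
  bad_scope <- setdiff(unique(catalogue$scope), c("shared", labels))
  if (length(bad_scope)) {
    abort(paste0("catalogue scope(s) not in grammar: ",
                 paste(bad_scope, collapse = ", ")))
  }
  for (sp in specs) {
    rel <- catalogue[catalogue$scope %in% c("shared", sp$label), ]
    if (any(rel$position > module_length(sp))) {
      abort(sprintf("catalogue position outside module '%s' (length %d).",
                    sp$label, module_length(sp)))
    }
    clash <- intersect(rel$position, cys_positions(sp))
    if (length(clash) && any(rel$residue[match(clash, rel$position)] != "C")) {
      abort(sprintf(
        "catalogued residue collides with a cysteine anchor at position %s of module '%s'.",
        paste(clash, collapse = ","), sp$label))
    }
  }
  structure(list(specs = specs, catalogue = catalogue),
            class = "cremp_grammar")
}

#' @export
print.cremp_grammar <- function(x, ...) {
  cat(sprintf("<cremp_grammar> %d module type(s), %d catalogued residue(s)\n",
              length(x$specs), nrow(x$catalogue)))
  for (sp in x$specs) print(sp)
  invisible(x)
}

#' Canonical sequence of a module template
#'
#' Places cysteines at the anchor positions, the catalogued conserved
#' residues (shared plus the type-specific set) at their positions, and a
#' filler residue everywhere else.
#'
#' @param spec A [module_spec()].
#' @param catalogue Conserved-residue tibble (see [conserved_catalogue()]).
#' @param filler Single standard residue other than `C`; default `"A"`.
#' @return A string of `module_length(spec)` residues.
#' @examples
#' g <- cremp_grammar()
#' build_canonical_sequence(g$specs$a) # "CADAACPKGAACAAAAGAPACAAAAPA"
#' @export
build_canonical_sequence <- function(spec, catalogue = conserved_catalogue(),
                                     filler = "A") {
  stopifnot(inherits(spec, "module_spec"))
  if (!filler %in% aa_non_cys()) {
    abort("`filler` must be a standard residue other than C.")
  }
  len <- module_length(spec)
  chars <- rep(filler, len)
  chars[cys_positions(spec)] <- "C"
  rel <- catalogue[catalogue$scope %in% c("shared", spec$label), ]
  rel <- rel[rel$position <= len, , drop = FALSE]
  clash <- rel$position %in% cys_positions(spec) & rel$residue != "C"
  if (any(clash)) {
    abort(sprintf("catalogued position %s collides with a cysteine anchor.",
                  paste(rel$position[clash], collapse = ",")))
  }
  chars[rel$position] <- rel$residue
  paste(chars, collapse = "")
}

## Grammar config I/O ---------------------------------------------------------

#' Read or write a module grammar as YAML
#'
#' The YAML layout mirrors the grammar: a `specs` list of
#' `{label, internal_gaps, tail, gap_tolerance, max_tail_insert}` entries and
#' a `catalogue` list of `{position, residue, scope}` entries. The shipped
#' default config (`system.file("extdata", "cremp_grammar.yaml",
#' package = "crempr")`) encodes the canonical a/b grammar; users can define
#' other four-cysteine grammars (e.g. the looser slime-mold
#' `C-X4-C-X5-C-X6-10-C` spacing via a tolerant third gap).
#'
#' @param path File path.
#' @return `read_grammar()` returns a `cremp_grammar`; `write_grammar()`
#'   invisibly returns `path`.
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) abort(paste0("grammar file not found: ", path))
  y <- yaml::read_yaml(path)
  specs <- lapply(y$specs, function(s) {
    module_spec(s$label, unlist(s$internal_gaps), s$tail,
                s$gap_tolerance %||% 1L, s$max_tail_insert %||% 64L)
  })
  catalogue <- purrr::map_dfr(y$catalogue, function(e) {
    tibble(position = as.integer(e$position), residue = e$residue,
           scope = e$scope)
  })
  if (is.null(y$catalogue)) catalogue <- conserved_catalogue()[0, ]
  grammar(specs, catalogue)
}

#' @rdname read_grammar
#' @param grammar A `cremp_grammar` object.
#' @export
write_grammar <- function(grammar, path) {
  stopifnot(inherits(grammar, "cremp_grammar"))
  y <- list(
    specs = lapply(unname(grammar$specs), function(s) {
      list(label = s$label, internal_gaps = as.list(s$internal_gaps),
           tail = s$tail, gap_tolerance = s$gap_tolerance,
           max_tail_insert = s$max_tail_insert)
    }),
    catalogue = lapply(seq_len(nrow(grammar$catalogue)), function(i) {
      as.list(grammar$catalogue[i, ])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
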