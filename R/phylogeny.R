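#' p-distance matrix over a module stack
#'
#' `d(i, j)` is the fraction of mismatched positions between two equal-length
#' rows; `X` mismatches everything, including another `X` (unknown residues
#' carry no evidence of identity).
#'
#' @param stack A `cremp_stack` (cross-type stacks use the 5-residue
#'   b-trim), or a character vector of equal-length residue strings.
#' @param labels Optional row labels; defaults to `type|seq_id:start` built
#'   from the stack's provenance.
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, and an attribute `types` (base module type per row).
#' @export
pdistance_matrix <- function(stack, labels = NULL) {
  if (inherits(stack, "cremp_stack")) {
    rows <- stack$rows
    types <- stack$source$base_type
    if (is.null(labels)) {
      # no ":" in labels (reserved by newick for branch lengths)
      labels <- sprintf("%s|%s_%d", types, stack$source$seq_id,
                        stack$source$start)
    }
  } else {
    rows <- stack
    types <- rep(NA_character_, length(rows))
    if (is.null(labels)) labels <- paste0("r", seq_along(rows))
  }
  if (length(unique(nchar(rows))) != 1L) {
    abort("rows must have equal length.")
  }
  labels <- make.unique(labels)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        mism <- mat[i, ] != mat[j, ] | mat[i, ] == "X" | mat[j, ] == "X"
        d[i, j] <- d[j, i] <- mean(mism)
      }
    }
  }
  attr(d, "types") <- setNames(types, labels)
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group average linkage: repeatedly merge the
#' closest pair of clusters (ties broken toward the lexicographically
#' smallest pair of cluster representative labels), with size-weighted
#' average distance updates; each merge sits at height `d/2`, so the tree is
#' ultrametric.
#'
#' @param d Symmetric distance matrix with row/column names (e.g. from
#'   [pdistance_matrix()]).
#' @return An [ape::phylo] tree with branch lengths; write with
#'   [ape::write.tree()].
#' @export
upgma_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) abort("UPGMA needs at least 2 leaves.")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # Active clusters: newick fragment, height, size, representative label.
  cl <- lapply(seq_len(n), function(i) {
    list(nwk = labs[i], h = 0, size = 1L, rep = labs[i])
  })
  D <- d
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        dij <- D[i, j]
        pair <- sort(c(cl[[i]]$rep, cl[[j]]$rep))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(i = i, j = j, d = dij, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    new <- list(
      nwk = sprintf("(%s:%s,%s:%s)", cl[[i]]$nwk,
                    format(h - cl[[i]]$h, digits = 10),
                    cl[[j]]$nwk, format(h - cl[[j]]$h, digits = 10)),
      h = h,
      size = cl[[i]]$size + cl[[j]]$size,
      rep = min(cl[[i]]$rep, cl[[j]]$rep)
    )
    # Size-weighted average-linkage update into slot i; retire slot j.
    for (k in setdiff(active, c(i, j))) {
      dk <- (cl[[i]]$size * D[i, k] + cl[[j]]$size * D[j, k]) / new$size
      D[i, k] <- D[k, i] <- dk
    }
    cl[[i]] <- new
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(cl[[active]]$nwk, ";"))
}

#' Two-cluster segregation purity of a typed tree
#'
#' Cuts the tree at its root into the two subtrees of the final merge;
#' purity is the total majority-type leaf count across the two clusters
#' divided by the number of leaves. 1.0 means the two module types
#' segregate perfectly.
#'
#' @param tree A rooted binary [ape::phylo] (e.g. from [upgma_tree()]).
#' @param types Character vector of type tags, either named by tip label or
#'   aligned with `tree$tip.label`. Defaults to the `|`-prefix of each tip
#'   label (the convention of [pdistance_matrix()]).
#' @return A number in `[0, 1]`.
#' @export
segregation_purity <- function(tree, types = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(types)) types <- sub("\\|.*$", "", tips)
  if (!is.null(names(types))) {
    types <- types[tips]
  } else {
    stopifnot(length(types) == length(tips))
    types <- setNames(types, tips)
  }
  if (anyNA(types)) abort("every leaf needs a type tag.")
  if (length(unique(types)) == 1L) {
    warn("single-type input: segregation purity is trivially 1.")
    return(1)
  }
  ntip <- length(tips)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2L) abort("tree root must be a binary split.")
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  maj <- vapply(kids, function(k) {
    max(table(types[tips[tips_under(k)]]))
  }, numeric(1))
  sum(maj) / ntip
}

#' Global-alignment percent identity (Needleman–Wunsch)
#'
#' Full-length global alignment with linear scoring (default match 1,
#' mismatch 0, gap -1) and deterministic traceback preferring diagonal,
#' then up (gap in `s2`), then left. Identity is the number of identical
#' aligned pairs divided by the number of alignment columns, in percent.
#'
#' @param s1,s2 Non-empty residue strings.
#' @param match,mismatch,gap Alignment scores.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' nw_identity("ACD", "AED") # 66.67
#' @export
nw_identity <- function(s1, s2, match = 1, mismatch = 0, gap = -1) {
  nw_align(s1, s2, match, mismatch, gap)$identity
}

# Full global DP; returns score, identity (%) and alignment column count.
nw_align <- function(s1, s2, match = 1, mismatch = 0, gap = -1) {
  stopifnot(is.character(s1), is.character(s2), nzchar(s1), nzchar(s2))
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # Traceback: diagonal, then up, then left.
  i <- n; j <- m
  ident <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
        S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      if (a[i] == b[j]) ident <- ident + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = S[n + 1L, m + 1L], identity = 100 * ident / cols,
       columns = cols)
}

#' Quantify a/b module segregation in one step
#'
#' Builds a cross-type module stack, its p-distance matrix and UPGMA tree,
#' and computes the two-cluster segregation purity.
#'
#' @param x A `cremp_scan` object or a `cremp_stack` (cross-type).
#' @param ... Passed to [stack_modules()] when `x` is a scan.
#' @return An object of class `cremp_segregation`: list with `stack`,
#'   `distances`, `tree`, `purity`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
segregate_modules <- function(x, ...) {
  stack <- if (inherits(x, "cremp_stack")) x else
    stack_modules(x, type = "cross", ...)
  d <- pdistance_matrix(stack)
  tree <- upgma_tree(d)
  purity <- segregation_purity(tree, attr(d, "types"))
  structure(list(stack = stack, distances = d, tree = tree, purity = purity),
            class = "cremp_segregation")
}

#' @export
print.cremp_segregation <- function(x, ...) {
  cat(sprintf("<cremp_segregation> %d module(s); purity %.3f\n",
              length(x$stack$rows), x$purity))
  invisible(x)
}

#' @rdname segregate_modules
#' @param ... Unused.
#' @method glance cremp_segregation
#' @export
glance.cremp_segregation <- function(x, ...) {
  tab <- table(x$stack$source$base_type)
  tibble(
    n_modules = length(x$stack$rows),
    n_types = length(tab),
    purity = x$purity,
    mean_within = mean_group_dist(x$distances, x$stack$source$base_type,
                                  within = TRUE),
    mean_between = mean_group_dist(x$distances, x$stack$source$base_type,
                                   within = FALSE)
  )
}

mean_group_dist <- function(d, types, within) {
  n <- nrow(d)
  if (n < 2L) return(NA_real_)
  same <- outer(types, types, "==")
  sel <- upper.tri(d) & (if (within) same else !same)
  if (!any(sel)) return(NA_real_)
  mean(d[sel])
}

#' @rdname segregate_modules
#' @method tidy cremp_segregation
#' @export
tidy.cremp_segregation <- function(x, ...) {
  d <- x$distances
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(
    item1 = rownames(d)[idx[, 1]],
    item2 = colnames(d)[idx[, 2]],
    distance = d[idx]
  )
}

#' @rdname segregate_modules
#' @param object A `cremp_segregation`.
#' @method autoplot cremp_segregation
#' @export
autoplot.cremp_segregation <- function(object, ...) {
  ord <- object$tree$tip.label[order(match(object$tree$tip.label,
                                           tree_tip_order(object$tree)))]
  df <- tidy.cremp_segregation(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, item1 = "item2",
                                            item2 = "item1"))
  df2$item1 <- factor(df2$item1, levels = ord)
  df2$item2 <- factor(df2$item2, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(.data$item1, .data$item2,
                                    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "p-distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

tree_tip_order <- function(tree) {
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], rec))
  }
  tree$tip.label[rec(ntip + 1L)]
}
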