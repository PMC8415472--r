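# Agglomerative tree construction from number strings.
#
# The tree distance is the sum-difference: the L1 (Manhattan) distance
# between two equal-length number strings, gap positions contributing the
# absolute property value against 0. At each step the closest pair of
# profiles is merged by unweighted position-wise averaging (WPGMA-like), the
# merge distance is recorded verbatim on the new node, and the loop repeats
# until one cluster remains.

#' Sum-difference (L1) distance between two number strings
#'
#' @param a,b Equal-length numeric vectors (e.g. [encode_sequence()] output
#'   for the same property).
#' @return Non-negative scalar: `sum(abs(a - b))`.
#' @export
sum_difference <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  sum(abs(a - b))
}

# Shared agglomerative loop. `dist_fun(i, j)` returns the current distance
# between active clusters i and j; `merge_fun(i, j)` updates cluster state
# after i and j merge (new cluster replaces slot i, slot j is dropped by the
# caller). Tie-breaking: strictly-smaller comparison during a row-major scan
# keeps the lowest (row, column) pair in the current ordering.
.agglomerate <- function(n, labels, dist_fun, merge_fun) {
  ids <- -seq_len(n)           # hclust convention: negatives are leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- length(ids)
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        d <- dist_fun(i, j)
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    merge[m, ] <- c(ids[bi], ids[bj])
    height[m] <- best
    merge_fun(bi, bj)
    ids[bi] <- m
    ids <- ids[-bj]
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "merge_tree")
}

#' Build a sum-difference tree from number strings
#'
#' Iteratively merges the pair of profiles with the smallest sum-difference,
#' replacing the pair by the unweighted position-wise mean of their two
#' current profiles, until one cluster remains. Merge distances are stored
#' verbatim; for display the tree is rendered ultrametrically with each
#' merge node at height d/2 (see [to_newick()]).
#'
#' @param encoded List of at least two equal-length numeric vectors, one per
#'   taxon (same property throughout).
#' @param labels Taxon labels; defaults to the vectors' `taxon` attributes
#'   or list names.
#' @return A `merge_tree`: list with `labels`, `merge` (hclust-style merge
#'   matrix), and `height` (merge distances in merge order).
#' @export
build_sumdiff_tree <- function(encoded, labels = NULL) {
  n <- length(encoded)
  if (n < 2L) stop("need at least 2 sequences to build a tree")
  profiles <- lapply(encoded, as.numeric)
  lens <- vapply(profiles, length, integer(1))
  if (length(unique(lens)) > 1L) stop("number strings differ in length")
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      tx <- attr(encoded[[i]], "taxon")
      if (!is.null(tx) && !is.na(tx)) tx
      else if (!is.null(names(encoded)) && nzchar(names(encoded)[i])) names(encoded)[i]
      else paste0("t", i)
    }, character(1))
  }
  env <- environment()
  .agglomerate(
    n, labels,
    dist_fun = function(i, j) sum_difference(profiles[[i]], profiles[[j]]),
    merge_fun = function(i, j) {
      newp <- (profiles[[i]] + profiles[[j]]) / 2
      profiles[[i]] <- newp
      profiles[[j]] <- NULL
      assign("profiles", profiles, envir = env)
    })
}

#' Build a tree from a precomputed distance matrix
#'
#' Runs the same agglomerative loop as [build_sumdiff_tree()], but since no
#' profiles exist to average, the distance from a merged cluster to any
#' other cluster is the arithmetic mean of its two members' distances
#' (WPGMA).
#'
#' @param m Symmetric non-negative numeric matrix with zero diagonal and
#'   taxon dimnames, or a [stats::dist] object.
#' @return A `merge_tree`.
#' @export
build_tree_from_distances <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance input must be square")
  if (any(!is.finite(m))) stop("distances must be finite")
  if (any(m < 0)) stop("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  d <- m
  env <- environment()
  .agglomerate(
    nrow(m), labels,
    dist_fun = function(i, j) d[i, j],
    merge_fun = function(i, j) {
      newrow <- (d[i, ] + d[j, ]) / 2
      d[i, ] <- newrow; d[, i] <- newrow; d[i, i] <- 0
      d <- d[-j, -j, drop = FALSE]
      assign("d", d, envir = env)
    })
}

#' Convert a similarity in [-1, 1] to a tree distance
#'
#' Bridge from correlation-type relatedness values to distances for
#' [build_tree_from_distances()]: perfect synchrony (r = 1) maps to 0,
#' no correlation to 1, exact mirror images to 2.
#'
#' @param r Numeric vector with entries in \[-1, 1\].
#' @return `1 - r`, elementwise.
#' @export
similarity_to_distance <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("similarities must lie in [-1, 1]")
  }
  1 - pmin(1, pmax(-1, r))
}

# Heights of internal nodes for ultrametric rendering: merge distance / 2.
.node_heights <- function(t) t$height / 2

# Recursive Newick for one node id (negative leaf / positive merge index).
.newick_node <- function(t, id, parent_h, digits) {
  hs <- .node_heights(t)
  if (id < 0) {
    lab <- t$labels[-id]
    sprintf("%s:%s", lab, format(max(0, parent_h), digits = digits))
  } else {
    h <- hs[id]
    kids <- t$merge[id, ]
    inner <- paste(vapply(kids, function(k) .newick_node(t, k, h, digits),
                          character(1)), collapse = ",")
    sprintf("(%s):%s", inner, format(max(0, parent_h - h), digits = digits))
  }
}

#' Serialize a merge tree as Newick
#'
#' Renders the tree ultrametrically: each merge at distance d places the new
#' node at height d/2, and a child's edge length is the height difference
#' (floored at 0 when a later merge is closer than an earlier one). Raw
#' merge distances remain available in `t$height`.
#'
#' @param t A `merge_tree`.
#' @param digits Significant digits for branch lengths.
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "merge_tree"))
  if (length(t$labels) == 1L) return(paste0(t$labels, ";"))
  root <- nrow(t$merge)
  h <- .node_heights(t)[root]
  kids <- t$merge[root, ]
  inner <- paste(vapply(kids, function(k) .newick_node(t, k, h, digits),
                        character(1)), collapse = ",")
  sprintf("(%s);", inner)
}

#' Convert a merge tree to an `ape` phylo object
#' @param x A `merge_tree`.
#' @param ... Unused.
#' @return An [ape::phylo] tree with the ultrametric branch lengths of
#'   [to_newick()].
#' @importFrom ape as.phylo
#' @exportS3Method ape::as.phylo
as.phylo.merge_tree <- function(x, ...) ape::read.tree(text = to_newick(x))

#' @export
print.merge_tree <- function(x, ...) {
  cat("Agglomerative merge tree: ", length(x$labels), " leaves\n", sep = "")
  if (length(x$height)) {
    cat("merge distances: ",
        paste(format(x$height, digits = 6), collapse = ", "), "\n", sep = "")
  }
  cat(to_newick(x, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.merge_tree <- function(x, ...) {
  graphics::plot(as.phylo.merge_tree(x), ...)
  invisible(x)
}

# Cophenetic merge distance between leaves (the raw merge distance at which
# two leaves first join); used for cross-checks against reference
# agglomerative implementations.
#' @export
cophenetic.merge_tree <- function(x) {
  n <- length(x$labels)
  members <- vector("list", nrow(x$merge))
  cm <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  leafset <- function(id) if (id < 0) -id else members[[id]]
  for (m in seq_len(nrow(x$merge))) {
    a <- leafset(x$merge[m, 1]); b <- leafset(x$merge[m, 2])
    cm[a, b] <- x$height[m]; cm[b, a] <- x$height[m]
    members[[m]] <- c(a, b)
  }
  stats::as.dist(cm)
}

#' Read a labeled distance matrix
#'
#' Accepts either a TSV with a header row of labels and a leading label
#' column, or PHYLIP square format (first line: taxon count).
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty distance file: ", path)
  first <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  if (length(first) == 1L && !is.na(suppressWarnings(as.integer(first)))) {
    n <- as.integer(first)                       # PHYLIP square
    rows <- strsplit(trimws(lines[seq.int(2, 1 + n)]), "[\t ]+")
    labs <- vapply(rows, `[`, character(1), 1)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  } else {                                       # labeled TSV
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    labs <- rownames(df)
    m <- as.matrix(df)
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Write a labeled distance matrix as TSV
#' @param m Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
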