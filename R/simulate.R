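# Synthetic protein-family simulator: a root sequence evolved down a given
# binary topology with per-branch substitution counts, optional protected
# (never-mutated) blocks, and per-taxon gap blocks applied after
# substitution. The substitution model is deliberately minimal — positions
# uniform outside protected blocks, replacement residue uniform over the
# other 19 — because the simulator exists to exercise the analysis pipeline
# with a known ground truth, not to be a realistic evolutionary model.

#' Draw a random root protein sequence
#'
#' @param length Positive sequence length.
#' @param seed Optional RNG seed (caller's RNG state is preserved).
#' @return A `gapped_seq` with uniform residue composition and no gaps.
#' @export
random_root <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  draw <- function() paste(sample(.residue_codes(), length, replace = TRUE),
                           collapse = "")
  s <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  gapped_sequence("root", s)
}

.expand_blocks <- function(blocks, L) {
  if (is.null(blocks) || !length(blocks)) return(integer(0))
  if (!is.list(blocks)) blocks <- list(blocks)
  pos <- unlist(lapply(blocks, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || b[1] > b[2] || b[1] < 1L || b[2] > L) {
      stop("invalid position interval [", paste(b, collapse = ", "),
           "] for length ", L)
    }
    seq.int(b[1], b[2])
  }))
  sort(unique(pos))
}

.mutate <- function(chars, k, protected) {
  if (k == 0L) return(chars)
  avail <- setdiff(seq_along(chars), protected)
  if (k > length(avail)) {
    stop("requested ", k, " substitutions but only ", length(avail),
         " mutable positions")
  }
  pos <- if (length(avail) == 1L) avail else sample(avail, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(.residue_codes(), chars[p]), 1L)
  }
  chars
}

# Preorder walk helpers on an ape phylo object.
.children_of <- function(phy, node) phy$edge[phy$edge[, 1] == node, 2]
.tips_under <- function(phy, node) {
  nt <- length(phy$tip.label)
  if (node <= nt) return(node)
  unlist(lapply(.children_of(phy, node), .tips_under, phy = phy))
}
.branch_name <- function(phy, child) {
  nt <- length(phy$tip.label)
  if (child <= nt) return(phy$tip.label[child])
  paste(sort(phy$tip.label[.tips_under(phy, child)]), collapse = "+")
}

#' Evolve a synthetic aligned protein family with a planted phylogeny
#'
#' Walks a binary topology from the root to the leaves, applying the stated
#' number of random substitutions on each branch, then applies per-taxon
#' gap blocks. Because every leaf descends from the same root and indels
#' are modelled as assigned blocks (not evolved), the leaves are already
#' aligned.
#'
#' @param topology Newick-style topology string over taxon labels, e.g.
#'   `"((A,B),(C,D))"`, or an `ape::phylo` object.
#' @param root_length Root sequence length (alignment width).
#' @param substitutions Named non-negative integer vector of per-branch
#'   substitution counts. Leaf branches are named by the taxon label;
#'   internal branches by the sorted labels of their descendant leaves
#'   joined with `+` (e.g. `"A+B"`). Unnamed branches default to 0.
#' @param protected_blocks List of `c(start, end)` position intervals that
#'   are never mutated (conserved domains).
#' @param gap_blocks Named list (by taxon) of lists of `c(start, end)`
#'   intervals set to gaps in that leaf after substitution.
#' @param root Optional `gapped_seq` to use as root; drawn uniformly at
#'   random when `NULL`.
#' @param seed RNG seed; identical configs and seeds give identical
#'   families.
#' @return Object of class `sim_family`: list with `alignment`
#'   (an `alignment_set` of the leaves), `root`, `topology` (planted
#'   Newick), `substitutions` (resolved per-branch counts), and the
#'   configuration.
#' @export
evolve_family <- function(topology, root_length = 356,
                          substitutions = integer(0),
                          protected_blocks = list(),
                          gap_blocks = list(),
                          root = NULL, seed = 1) {
  phy <- if (inherits(topology, "phylo")) topology
         else tryCatch(
           ape::read.tree(text = paste0(sub(";\\s*$", "", topology), ";")),
           error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$tip.label)) {
    stop("could not parse topology: ", topology)
  }
  if (anyDuplicated(phy$tip.label)) stop("taxon labels must be unique")
  nt <- length(phy$tip.label)
  protected <- .expand_blocks(protected_blocks, root_length)
  branch_names <- vapply(phy$edge[, 2], .branch_name, character(1), phy = phy)
  subs <- stats::setNames(integer(length(branch_names)), branch_names)
  if (length(substitutions)) {
    if (is.null(names(substitutions))) {
      stop("substitutions must be named by branch (taxon label or 'A+B')")
    }
    unknown <- setdiff(names(substitutions), branch_names)
    if (length(unknown)) {
      stop("unknown branch name(s): ", paste(unknown, collapse = ", "),
           "; valid: ", paste(branch_names, collapse = ", "))
    }
    subs[names(substitutions)] <- as.integer(substitutions)
  }
  if (any(subs < 0)) stop("substitution counts must be non-negative")

  .with_seed(seed, {
    if (is.null(root)) {
      root <- gapped_sequence("root",
                              paste(sample(.residue_codes(), root_length,
                                           replace = TRUE), collapse = ""))
    }
    stopifnot(inherits(root, "gapped_seq"), root$length == root_length)
    root_chars <- strsplit(root$letters, "", fixed = TRUE)[[1]]
    node_seq <- vector("list", nt + phy$Nnode)
    root_node <- nt + 1L
    node_seq[[root_node]] <- root_chars
    phy <- ape::reorder.phylo(phy, "cladewise")  # parents before children
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      k <- subs[[.branch_name(phy, child)]]
      node_seq[[child]] <- .mutate(node_seq[[parent]], k, protected)
    }
    leaves <- vapply(seq_len(nt), function(i) {
      chars <- node_seq[[i]]
      gb <- gap_blocks[[phy$tip.label[i]]]
      if (!is.null(gb)) chars[.expand_blocks(gb, root_length)] <- "-"
      paste(chars, collapse = "")
    }, character(1))
    structure(
      list(alignment = alignment_set(phy$tip.label, leaves),
           root = root,
           topology = ape::write.tree(phy),
           substitutions = subs,
           protected_blocks = protected_blocks,
           gap_blocks = gap_blocks,
           seed = seed),
      class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat("Simulated protein family, planted topology ", x$topology, "\n",
      sep = "")
  cat("substitutions per branch: ",
      paste(sprintf("%s=%d", names(x$substitutions), x$substitutions),
            collapse = ", "), "\n", sep = "")
  print(x$alignment)
  invisible(x)
}

#' Simulate the standard planted four-taxon family
#'
#' The validation workhorse: topology `((A,B),(C,D))` with few
#' substitutions on the leaf branches and many on the two internal
#' branches, so that the within-pair distance is well separated from the
#' cross-pair distance.
#'
#' @param leaf_subs Substitutions per leaf branch (default 5).
#' @param internal_subs Substitutions per internal branch (default 60).
#' @param root_length Alignment width (default 356).
#' @param seed RNG seed.
#' @param ... Passed through to [evolve_family()].
#' @return A `sim_family`.
#' @export
planted_quartet <- function(leaf_subs = 5, internal_subs = 60,
                            root_length = 356, seed = 1, ...) {
  evolve_family("((A,B),(C,D))", root_length = root_length,
                substitutions = c(A = leaf_subs, B = leaf_subs,
                                  C = leaf_subs, D = leaf_subs,
                                  "A+B" = internal_subs,
                                  "C+D" = internal_subs),
                seed = seed, ...)
}

#' Write a simulated family as FASTA plus a JSON truth sidecar
#'
#' @param fam A `sim_family`.
#' @param fasta_path Output aligned-FASTA path.
#' @param json_path Output JSON path (default: `fasta_path` with
#'   `.json` extension) recording the planted topology, per-branch
#'   substitution counts, blocks and seed.
#' @return Character vector of paths written, invisibly.
#' @export
write_sim_family <- function(fam, fasta_path,
                             json_path = sub("\\.[^.]*$", ".json", fasta_path)) {
  stopifnot(inherits(fam, "sim_family"))
  write_alignment_fasta(fam$alignment, fasta_path)
  jsonlite::write_json(
    list(topology = fam$topology,
         substitutions = as.list(fam$substitutions),
         protected_blocks = fam$protected_blocks,
         gap_blocks = fam$gap_blocks,
         seed = fam$seed,
         width = fam$alignment$width),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta_path, json_path))
}
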