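#' Read a rooted phylogeny from a Newick file
#'
#' Parses a single rooted Newick tree and validates it for downstream
#' evolutionary-distinctness calculations: every non-root edge must carry a
#' non-negative branch length and tip labels must be unique. Underscores in
#' tip labels are normalized to spaces, so a tip written `Lactoris_fernandeziana`
#' becomes `"Lactoris fernandeziana"` and its genus is the token before the
#' first space.
#'
#' @param path Path to a Newick file containing one tree.
#' @return A rooted `phylo` object (see \pkg{ape}) with space-separated
#'   binomial tip labels. Any root edge present in the input is dropped: it
#'   contributes equally to every tip and cancels in all rankings.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree in ", path,
                                 ", found ", length(tree))
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse a Newick tree from ", path)
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param text A Newick string, as an alternative to `path`.
#' @export
read_newick_text <- function(text) {
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    # locate an offending edge for the message
    bad <- tree$edge[1L, ]
    stop("tree has no branch lengths (first edge ", bad[1L], "->", bad[2L], ")")
  }
  if (anyNA(tree$edge.length)) {
    i <- which(is.na(tree$edge.length))[1L]
    stop("missing branch length on edge ",
         tree$edge[i, 1L], "->", tree$edge[i, 2L])
  }
  if (any(tree$edge.length < 0)) {
    i <- which(tree$edge.length < 0)[1L]
    stop("negative branch length on edge ",
         tree$edge[i, 1L], "->", tree$edge[i, 2L])
  }
  tree$tip.label <- normalize_label(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  tree$root.edge <- NULL
  tree
}

#' @rdname read_newick
#' @param x Character vector of labels.
#' @export
normalize_label <- function(x) gsub("_", " ", x, fixed = TRUE)

#' Genus of binomial tip labels
#'
#' The genus is the first whitespace-separated token of the label.
#' @param x Character vector of normalized tip labels.
#' @return Character vector of genus names.
#' @export
tip_genus <- function(x) sub("\\s.*$", "", normalize_label(x))

#' Write a phylogeny to a Newick file
#'
#' Spaces in tip labels are written as underscores (Newick convention);
#' branch lengths are emitted at full double precision so a read/write
#' round trip is lossless.
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  out <- tree
  out$tip.label <- gsub(" ", "_", out$tip.label, fixed = TRUE)
  ape::write.tree(out, file = path, digits = 17)
  invisible(path)
}

#' Root-to-tip depths of all tips
#' @param tree A `phylo` object.
#' @return Named numeric vector of root-to-tip path lengths.
#' @export
tip_depths <- function(tree) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

# depth (distance from root) of every node, indexed by node id
node_depths <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n_node)
  pr <- rev(ape::postorder(tree)) # preorder over edges
  for (i in pr) {
    depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + tree$edge.length[i]
  }
  depth
}

#' Maximum relative deviation from ultrametricity
#'
#' Returns `max(|depth(tip) - mean depth|) / mean depth`; a tree is treated
#' as ultrametric when this is at most `rel_tol`.
#'
#' @param tree A `phylo` object with at least one tip.
#' @param rel_tol Relative tolerance used by [assert_ultrametric()]
#'   (default `1e-6`).
#' @return The maximum relative root-to-tip depth deviation (0 for a
#'   perfectly ultrametric tree).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- tip_depths(tree)
  m <- mean(d)
  if (m <= 0) return(0)
  max(abs(d - m)) / m
}

#' @rdname check_ultrametric
#' @export
assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  dev <- check_ultrametric(tree)
  if (dev > rel_tol) {
    stop(sprintf("tree is not ultrametric: relative depth deviation %.3g > %.3g",
                 dev, rel_tol))
  }
  invisible(tree)
}

#' Height (root-to-tip depth) of an ultrametric tree
#' @param tree A `phylo` object.
#' @return Mean root-to-tip depth.
#' @export
tree_height <- function(tree) mean(tip_depths(tree))

#' Rescale an ultrametric tree to a target root depth
#'
#' Multiplies every branch length by `depth / height(tree)` so the root sits
#' at the target depth (default 100, an arbitrary relative scale: all
#' rankings computed here are invariant to it).
#'
#' @param tree An ultrametric `phylo` object.
#' @param depth Target root-to-tip depth in the tree's (arbitrary) time units.
#' @param rel_tol Ultrametricity tolerance.
#' @return The rescaled `phylo` object.
#' @export
calibrate_root_depth <- function(tree, depth = 100, rel_tol = 1e-6) {
  assert_ultrametric(tree, rel_tol)
  h <- tree_height(tree)
  if (h <= 0) stop("cannot calibrate a zero-height tree")
  tree$edge.length <- tree$edge.length * (depth / h)
  tree
}

#' Remove tips from a phylogeny
#'
#' Drops the listed tips (e.g. an outgroup before calibration); degree-two
#' nodes left behind are suppressed with their branch lengths summed, so
#' pairwise path lengths among surviving tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param labels Tip labels to remove (underscores accepted).
#' @return The pruned `phylo` object (at least 2 tips must remain).
#' @export
prune_tips <- function(tree, labels) {
  labels <- normalize_label(labels)
  if (length(labels) == 0L) return(tree)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  if (length(tree$tip.label) - length(labels) < 2L) {
    stop("pruning would leave fewer than 2 tips")
  }
  ape::drop.tip(tree, labels, collapse.singles = TRUE)
}
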