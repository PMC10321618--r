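#' Placement plans for species without sequence data
#'
#' A placement plan lists species to be added to a backbone phylogeny, each
#' with one of two modes:
#' \describe{
#'   \item{`midpoint_sister`}{attach the new tip at the midpoint of the branch
#'     subtending a named target (a tip, a genus, or a labelled clade); used
#'     for placements fixed from the literature, identical in every replicate.}
#'   \item{`random_in_genus`}{attach the new tip at a random position inside
#'     the clade spanned by its congeners; re-drawn independently per replicate.}
#' }
#'
#' @param species Character vector of new species labels.
#' @param mode Character vector, `"midpoint_sister"` or `"random_in_genus"`.
#' @param target For midpoint placements the target label; for random
#'   placements the genus name.
#' @return A `placement_plan` data frame with columns `species`, `mode`,
#'   `target`.
#' @export
placement_plan <- function(species, mode, target) {
  species <- normalize_label(species)
  target <- normalize_label(target)
  bad <- setdiff(unique(mode), c("midpoint_sister", "random_in_genus"))
  if (length(bad)) stop("unknown placement mode(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(species)) {
    stop("duplicated species in plan: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  plan <- data.frame(species = species, mode = mode, target = target,
                     stringsAsFactors = FALSE)
  class(plan) <- c("placement_plan", "data.frame")
  plan
}

#' @rdname placement_plan
#' @param path CSV file with columns `species,mode,target`.
#' @export
read_placement_plan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "mode", "target")
  if (!all(need %in% names(df))) {
    stop("placement plan must have columns: ", paste(need, collapse = ", "))
  }
  placement_plan(df$species, df$mode, df$target)
}

#' @rdname placement_plan
#' @param plan A `placement_plan`.
#' @export
write_placement_plan <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname placement_plan
#' @param tree Backbone `phylo` the plan will be applied to.
#' @export
validate_plan <- function(plan, tree) {
  stopifnot(inherits(plan, "placement_plan"), inherits(tree, "phylo"))
  clash <- intersect(plan$species, tree$tip.label)
  if (length(clash)) {
    stop("planned species already in backbone: ", paste(clash, collapse = ", "))
  }
  genera <- tip_genus(tree$tip.label)
  for (i in seq_len(nrow(plan))) {
    if (plan$mode[i] == "random_in_genus") {
      # congeners may be earlier plan entries applied sequentially
      earlier <- tip_genus(plan$species[seq_len(i - 1L)])
      if (!(plan$target[i] %in% c(genera, earlier))) {
        stop("no backbone tip in genus '", plan$target[i],
             "' for planned species ", plan$species[i])
      }
    } else {
      tryCatch(resolve_target(tree, plan$target[i]),
               error = function(e) stop("midpoint target '", plan$target[i],
                                        "' not found for ", plan$species[i]))
    }
  }
  invisible(plan)
}

# resolve a target label to a node index: tip label, genus name (single tip or
# genus MRCA), or internal node label
resolve_target <- function(tree, target) {
  target <- normalize_label(target)
  hit <- match(target, tree$tip.label)
  if (!is.na(hit)) return(hit)
  gt <- which(tip_genus(tree$tip.label) == target)
  if (length(gt) == 1L) return(gt)
  if (length(gt) > 1L) return(ape::getMRCA(tree, gt))
  if (!is.null(tree$node.label)) {
    nl <- match(target, tree$node.label)
    if (!is.na(nl)) return(length(tree$tip.label) + nl)
  }
  stop("target '", target, "' matches no tip, genus or clade label")
}

# graft a new tip onto the edge subtending `node`, at absolute depth `h`
# (distance from root); terminal length chosen so the tip reaches the tree
# height, preserving ultrametricity exactly
graft_at_depth <- function(tree, new_species, node, h) {
  depth <- node_depths(tree)
  height <- mean(depth[seq_along(tree$tip.label)])
  edge_i <- which(tree$edge[, 2L] == node)
  if (length(edge_i) != 1L) stop("target node has no subtending edge (root?)")
  d_par <- depth[tree$edge[edge_i, 1L]]
  d_node <- depth[node]
  if (h <= d_par || h > d_node || h >= height) {
    stop("attachment depth outside target edge")
  }
  out <- phytools::bind.tip(tree, gsub(" ", "_", new_species, fixed = TRUE),
                            edge.length = height - h,
                            where = node, position = d_node - h)
  out$tip.label <- normalize_label(out$tip.label)
  out
}

#' Attach a species at the midpoint of a target branch
#'
#' Bisects the branch subtending `target` (a tip, genus, or labelled clade)
#' and grafts `new_species` there as its sister, with terminal branch length
#' chosen so the new tip is contemporaneous with the others. This mirrors
#' literature-based manual placements of species from monotypic or
#' unsequenced genera.
#'
#' @param tree An ultrametric `phylo`.
#' @param new_species Label of the species to add.
#' @param target Tip label, genus name, or internal node label.
#' @return The augmented `phylo` object.
#' @export
place_midpoint_sister <- function(tree, new_species, target) {
  new_species <- normalize_label(new_species)
  node <- resolve_target(tree, target)
  edge_i <- which(tree$edge[, 2L] == node)
  if (length(edge_i) != 1L) stop("target '", target, "' is the root; cannot bisect")
  len <- tree$edge.length[edge_i]
  if (len <= 0) stop("target branch has length 0; midpoint undefined")
  depth <- node_depths(tree)
  h <- depth[node] - len / 2
  graft_at_depth(tree, new_species, node, h)
}

# eligible edges for random within-genus placement, as child-node indices:
# terminal edges of the genus tips, internal edges wholly inside the genus
# MRCA clade, and the clade's subtending (stem) edge when it exists
eligible_genus_edges <- function(tree, genus) {
  gt <- which(tip_genus(tree$tip.label) == genus)
  if (length(gt) == 0L) stop("genus '", genus, "' absent from tree")
  if (length(gt) == 1L) return(gt)
  ntip <- length(tree$tip.label)
  mrca <- ape::getMRCA(tree, gt)
  desc <- clade_descendants(tree, mrca)
  internal <- desc[desc > ntip]
  nodes <- c(gt, internal)
  if (any(tree$edge[, 2L] == mrca)) nodes <- c(nodes, mrca)
  nodes
}

# all descendant node indices of `node` (excluding node itself)
clade_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  out <- kids
  while (length(kids)) {
    kids <- tree$edge[tree$edge[, 1L] %in% kids, 2L]
    out <- c(out, kids)
  }
  out
}

#' Randomly graft a species inside its genus
#'
#' Chooses uniformly at random one eligible edge of the genus clade (terminal
#' edges of congeneric tips, internal edges wholly within the clade, and the
#' clade stem), then a uniform attachment height along that edge, and grafts
#' the new tip so the tree stays ultrametric. With a single congener the new
#' tip forms a cherry with it, attached at a uniform height along its
#' terminal branch. Draws come from R's global random number generator unless
#' `seed` is given.
#'
#' @param tree An ultrametric `phylo`.
#' @param new_species Label of the species to add.
#' @param genus Genus name; must have at least one tip in `tree`.
#' @param seed Optional integer; when given, the draw is a pure function of
#'   `(tree, new_species, genus, seed)`.
#' @return The augmented `phylo` object.
#' @export
add_species_to_genus_random <- function(tree, new_species, genus, seed = NULL) {
  if (!is.null(seed)) {
    return(with_preserved_rng(seed, add_species_to_genus_random(
      tree, new_species, genus)))
  }
  new_species <- normalize_label(new_species)
  genus <- normalize_label(genus)
  nodes <- eligible_genus_edges(tree, genus)
  node <- if (length(nodes) == 1L) nodes else nodes[sample.int(length(nodes), 1L)]
  depth <- node_depths(tree)
  edge_i <- which(tree$edge[, 2L] == node)
  d_par <- depth[tree$edge[edge_i, 1L]]
  d_node <- depth[node]
  h <- stats::runif(1L, d_par, d_node)
  graft_at_depth(tree, new_species, node, h)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# apply a whole plan to the backbone (one replicate); midpoint directives are
# deterministic, random directives consume the current RNG stream
apply_plan <- function(tree, plan) {
  for (i in seq_len(nrow(plan))) {
    tree <- if (plan$mode[i] == "midpoint_sister") {
      place_midpoint_sister(tree, plan$species[i], plan$target[i])
    } else {
      add_species_to_genus_random(tree, plan$species[i], plan$target[i])
    }
  }
  tree
}

#' Replicate trees with randomly placed missing species
#'
#' Applies the placement plan to the backbone `n` times: midpoint directives
#' identically in every replicate, random within-genus directives re-drawn
#' per replicate from seed-derived substreams, so that replicate `i` is a
#' pure function of `(tree, plan, seed, i)`. Directives are applied in plan
#' order, so a species added earlier is available as attachment context for
#' later congeners. The resulting set of trees propagates the phylogenetic
#' uncertainty of the imputed placements into all downstream scores.
#'
#' @param tree Ultrametric backbone `phylo`.
#' @param plan A [placement_plan()].
#' @param n Number of replicate trees (default 100).
#' @param seed Master integer seed.
#' @return A `replicate_set`: list with `trees` (a `multiPhylo`), `backbone`,
#'   `plan`, `seed` and `replicate_seeds`.
#' @export
generate_replicates <- function(tree, plan, n = 100, seed = 1L) {
  assert_ultrametric(tree, rel_tol = 1e-6)
  validate_plan(plan, tree)
  rep_seeds <- with_preserved_rng(seed, sample.int(.Machine$integer.max - 1L, n))
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    trees[[i]] <- tryCatch(
      with_preserved_rng(rep_seeds[i], apply_plan(tree, plan)),
      error = function(e) stop("replicate ", i, ": ", conditionMessage(e)))
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, backbone = tree, plan = plan,
                 seed = seed, replicate_seeds = rep_seeds),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("replicate_set:", length(x$trees), "trees,",
      length(x$backbone$tip.label), "backbone tips +",
      nrow(x$plan), "planned species, master seed", x$seed, "\n")
  invisible(x)
}

#' @export
length.replicate_set <- function(x) length(x$trees)
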