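#' Configuration for synthetic study data
#'
#' Bundles the parameters of the synthetic data generators, chosen to mirror
#' the structure of a regional endemic flora analysis: a genus-structured
#' ultrametric phylogeny calibrated to root depth 100, strongly right-skewed
#' (log-normal) range sizes on a 0.5-degree grid whose extent is a long
#' narrow band of 20 x 80 cells, a threat-status distribution of
#' 7 CR / 54 EN / 23 VU / 7 NT / 4 LC over 95 evaluated species (the rest
#' not evaluated), and a quarter of the species withheld from the backbone
#' for within-genus imputation.
#'
#' @param n_species Total number of species (default 200).
#' @param n_genera Number of genera; species are split over genera with
#'   log-normally skewed sizes, at least 1 per genus.
#' @param birth_rate Speciation rate of the pure-birth tree generator.
#' @param depth Root-to-tip depth the tree is calibrated to.
#' @param range_meanlog,range_sdlog Log-normal parameters of range size in
#'   grid cells (rounded, minimum 1, clipped to the extent).
#' @param extent Integer vector `c(nx, ny)` of grid cells available.
#' @param cell_size Grid cell edge in degrees.
#' @param status_counts Named counts of evaluated species per category.
#' @param withheld_fraction Fraction of species withheld from the backbone
#'   and re-added by random within-genus placement.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 200L,
                              n_genera = 40L,
                              birth_rate = 1,
                              depth = 100,
                              range_meanlog = 1.5,
                              range_sdlog = 1.2,
                              extent = c(20L, 80L),
                              cell_size = 0.5,
                              status_counts = c(CR = 7L, EN = 54L, VU = 23L,
                                                NT = 7L, LC = 4L),
                              withheld_fraction = 0.25) {
  stopifnot(n_species >= 2, n_genera >= 2, n_genera <= n_species,
            birth_rate > 0, depth > 0, all(extent >= 1),
            withheld_fraction >= 0, withheld_fraction < 1)
  status_counts <- status_counts[iucn_categories()]
  names(status_counts) <- iucn_categories()
  if (anyNA(status_counts)) stop("status_counts must cover LC..CR")
  if (sum(status_counts) > n_species) {
    stop("more evaluated species than species")
  }
  structure(list(n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 birth_rate = birth_rate, depth = depth,
                 range_meanlog = range_meanlog, range_sdlog = range_sdlog,
                 extent = as.integer(extent), cell_size = cell_size,
                 status_counts = status_counts,
                 withheld_fraction = withheld_fraction),
            class = "simulation_config")
}

genus_name <- function(k) sprintf("Genus%02d", k)

#' Simulate a genus-structured ultrametric phylogeny
#'
#' Draws a pure-birth (Yule) genus backbone, splits the species over genera
#' with log-normally skewed sizes, and replaces each multi-species genus tip
#' by a pure-birth within-genus subtree whose crown sits partway down the
#' genus stem, so every genus is monophyletic by construction. The result is
#' ultrametric and calibrated to `config$depth`. Tips are labelled
#' `"GenusK spM"`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the tree is a pure function of
#'   `(config, seed)`.
#' @return A `phylo` with `config$n_species` tips.
#' @export
simulate_tree <- function(config, seed = 1L) {
  with_preserved_rng(seed, {
    ng <- config$n_genera
    sizes <- as.vector(stats::rmultinom(1L, config$n_species - ng,
                                        stats::rlnorm(ng, 0, 1))) + 1L
    tree <- ape::rphylo(ng, config$birth_rate, 0)
    tree$tip.label <- genus_name(seq_len(ng))
    tree <- calibrate_root_depth(tree, config$depth)
    for (k in seq_len(ng)) {
      g <- genus_name(k)
      if (sizes[k] == 1L) {
        tree$tip.label[tree$tip.label == g] <- paste(g, "sp01")
        next
      }
      tip <- which(tree$tip.label == g)
      edge_i <- which(tree$edge[, 2L] == tip)
      L <- tree$edge.length[edge_i]
      h <- stats::runif(1L, 0.25, 0.75) * L # genus crown age < stem length
      sub <- ape::rphylo(sizes[k], config$birth_rate, 0)
      sub$edge.length <- sub$edge.length * (h / tree_height(sub))
      sub$tip.label <- paste(g, sprintf("sp%02d", seq_len(sizes[k])))
      sub$root.edge <- 0
      tree$edge.length[edge_i] <- L - h
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == g),
                             position = 0)
    }
    tree
  })
}

#' Simulate log-normally skewed gridded ranges
#'
#' Each species receives a range size drawn from a log-normal distribution
#' (rounded, at least 1, clipped to the extent with a warning) and occupies a
#' contiguous, roughly square block of cells at a uniformly random location
#' inside the extent. Contiguous blocks create realistic nested cell unions
#' on internal branches.
#'
#' @param species Character vector of species labels (e.g. tree tips).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return An [occurrence_grid()].
#' @export
simulate_ranges <- function(species, config, seed = 1L) {
  with_preserved_rng(seed, {
    nx <- config$extent[1L]; ny <- config$extent[2L]
    n <- length(species)
    size <- pmax(1L, round(stats::rlnorm(n, config$range_meanlog,
                                         config$range_sdlog)))
    if (any(size > nx * ny)) {
      warning("clipping ", sum(size > nx * ny), " range(s) to the extent")
      size <- pmin(size, nx * ny)
    }
    cells <- vector("list", n)
    names(cells) <- species
    for (s in seq_len(n)) {
      w <- min(nx, ceiling(sqrt(size[s])))
      r <- min(ny, ceiling(size[s] / w))
      w <- min(nx, ceiling(size[s] / r)) # refit width after row clipping
      i0 <- sample.int(nx - w + 1L, 1L) - 1L
      j0 <- sample.int(ny - r + 1L, 1L) - 1L
      block <- expand.grid(i = i0 + seq_len(w) - 1L, j = j0 + seq_len(r) - 1L)
      block <- block[seq_len(min(size[s], nrow(block))), , drop = FALSE]
      cells[[s]] <- cell_key(block$i, block$j)
    }
    occurrence_grid(cells, config$cell_size)
  })
}

#' Simulate a threat-status table
#'
#' Assigns the configured category counts to a random subset of evaluated
#' species (the rest are `NE`). With `couple_to_range = TRUE`, threat
#' severity follows ascending range size — the smallest-ranged evaluated
#' species become CR, then EN, and so on, with random tie-breaking — the
#' structure under which geographic rarity is informative about threat and
#' RED is expected to track EDGE. With coupling off, categories are assigned
#' at random.
#'
#' @inheritParams simulate_ranges
#' @param couple_to_range Couple severity to range size (requires `grid`).
#' @param grid An [occurrence_grid()] covering `species` (only needed when
#'   coupling).
#' @return A [status_table()].
#' @export
simulate_statuses <- function(species, config, couple_to_range = FALSE,
                              grid = NULL, seed = 1L) {
  with_preserved_rng(seed, {
    counts <- config$status_counts
    n_eval <- sum(counts)
    evaluated <- sample(species, n_eval)
    # categories listed most to least severe, matching ascending range size
    cats <- rep(c("CR", "EN", "VU", "NT", "LC"),
                counts[c("CR", "EN", "VU", "NT", "LC")])
    if (couple_to_range) {
      if (is.null(grid)) stop("couple_to_range requires an occurrence grid")
      rs <- range_sizes(grid)[evaluated]
      evaluated <- evaluated[order(rs, stats::runif(n_eval))]
    } else {
      evaluated <- sample(evaluated)
    }
    category <- stats::setNames(rep("NE", length(species)), species)
    category[evaluated] <- cats
    status_table(species, unname(category))
  })
}

#' Simulate a complete study bundle
#'
#' Generates a tree, occurrence grid and status table, withholds a fraction
#' of species from the backbone (only species whose genus keeps at least one
#' other tip are eligible) and writes them into a random-in-genus placement
#' plan, reproducing the full input set of the prioritization pipeline.
#'
#' @inheritParams simulate_tree
#' @param couple_to_range Passed to [simulate_statuses()].
#' @return A list with `tree` (full), `backbone`, `plan`, `grid`,
#'   `statuses`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L,
                             couple_to_range = TRUE) {
  tree <- simulate_tree(config, seed)
  grid <- simulate_ranges(tree$tip.label, config, seed + 1L)
  statuses <- simulate_statuses(tree$tip.label, config, couple_to_range,
                                grid, seed + 2L)
  with_preserved_rng(seed + 3L, {
    n_hold <- round(config$withheld_fraction * config$n_species)
    genera <- tip_genus(tree$tip.label)
    withheld <- character(0)
    if (n_hold > 0) {
      pool <- sample(tree$tip.label)
      remaining <- table(genera)
      for (sp in pool) {
        g <- tip_genus(sp)
        if (remaining[g] >= 2L) { # keep >= 1 congener in the backbone
          withheld <- c(withheld, sp)
          remaining[g] <- remaining[g] - 1L
          if (length(withheld) == n_hold) break
        }
      }
    }
    backbone <- if (length(withheld)) prune_tips(tree, withheld) else tree
    plan <- placement_plan(withheld,
                           rep("random_in_genus", length(withheld)),
                           tip_genus(withheld))
    list(tree = tree, backbone = backbone, plan = plan, grid = grid,
         statuses = statuses, config = config, seed = seed)
  })
}
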