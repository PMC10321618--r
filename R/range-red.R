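#' Gridded species occurrences
#'
#' An `occurrence_grid` maps each species to the set of grid cells it
#' occupies on a plain longitude/latitude degree grid (no map projection).
#' Cells are half-open squares `[i*size, (i+1)*size) x [j*size, (j+1)*size)`
#' indexed by `(i, j) = (floor(lon/size), floor(lat/size))`, so a point on a
#' cell boundary belongs to the higher-index cell. The number of occupied
#' cells is the species' range, which drives range weighting.
#'
#' @param cells Named list: species -> character vector of cell keys
#'   (`"i:j"`), deduplicated.
#' @param cell_size Cell edge in decimal degrees.
#' @return An `occurrence_grid` object.
#' @export
occurrence_grid <- function(cells, cell_size = 0.5) {
  stopifnot(is.list(cells), !is.null(names(cells)))
  names(cells) <- normalize_label(names(cells))
  cells <- lapply(cells, function(x) sort(unique(as.character(x))))
  empty <- names(cells)[lengths(cells) == 0L]
  if (length(empty)) {
    stop("species with zero occupied cells: ", paste(empty, collapse = ", "))
  }
  structure(list(cells = cells, cell_size = cell_size),
            class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat("occurrence_grid:", length(x$cells), "species on a", x$cell_size,
      "degree grid; ranges", min(lengths(x$cells)), "-",
      max(lengths(x$cells)), "cells\n")
  invisible(x)
}

#' Range size (number of occupied cells) per species
#' @param grid An `occurrence_grid`.
#' @return Named integer vector.
#' @export
range_sizes <- function(grid) lengths(grid$cells)

cell_key <- function(i, j) paste0(i, ":", j)

#' Project occurrence points onto a degree grid
#'
#' Maps each longitude/latitude record to its grid cell with the half-open
#' floor convention and deduplicates cells per species.
#'
#' @param points Data frame with columns `species`, `lon`, `lat` in decimal
#'   degrees (`lon` in `[-180, 180]`, `lat` in `[-90, 90]`).
#' @param cell_size Cell edge in degrees (default 0.5).
#' @return An [occurrence_grid()].
#' @export
assign_grid_cells <- function(points, cell_size = 0.5) {
  stopifnot(all(c("species", "lon", "lat") %in% names(points)))
  bad <- which(!is.finite(points$lon) | !is.finite(points$lat) |
                 points$lon < -180 | points$lon > 180 |
                 points$lat < -90 | points$lat > 90)
  if (length(bad)) {
    stop("out-of-range coordinates at record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  i <- floor(points$lon / cell_size)
  j <- floor(points$lat / cell_size)
  keys <- cell_key(i, j)
  occurrence_grid(split(keys, normalize_label(points$species)), cell_size)
}

#' Read occurrences from CSV
#'
#' Accepts two dialects, auto-detected from the header: point records
#' (`species,lon,lat`) which are gridded with [assign_grid_cells()], or a
#' precomputed presence table (`species,cell_i,cell_j`).
#'
#' @param path CSV path.
#' @param cell_size Cell edge in degrees (used for the point dialect and
#'   recorded on the grid).
#' @return An [occurrence_grid()].
#' @export
read_occurrences <- function(path, cell_size = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("species", "lon", "lat") %in% names(df))) {
    assign_grid_cells(df, cell_size)
  } else if (all(c("species", "cell_i", "cell_j") %in% names(df))) {
    keys <- cell_key(df$cell_i, df$cell_j)
    occurrence_grid(split(keys, normalize_label(df$species)), cell_size)
  } else {
    stop("occurrence CSV must have columns species,lon,lat or species,cell_i,cell_j")
  }
}

#' @rdname read_occurrences
#' @param grid An `occurrence_grid` to write in the presence dialect.
#' @export
write_occurrences <- function(grid, path) {
  sp <- rep(names(grid$cells), lengths(grid$cells))
  key <- unlist(grid$cells, use.names = FALSE)
  ij <- do.call(rbind, strsplit(key, ":", fixed = TRUE))
  utils::write.csv(data.frame(species = sp,
                              cell_i = as.integer(ij[, 1L]),
                              cell_j = as.integer(ij[, 2L])),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Range of every branch of a phylogeny
#'
#' For each edge, the number of grid cells in which at least one of its
#' descendant species occurs (the cardinality of the union of their cell
#' sets). Computed bottom-up by set union over the tree.
#'
#' @param tree A `phylo` whose tips are all present in `grid` (or see
#'   `assume_range_one`).
#' @param grid An [occurrence_grid()].
#' @param assume_range_one If `TRUE`, tips absent from the grid are assigned
#'   a private single cell (range 1) with a warning instead of an error.
#' @return Numeric vector of cell counts, one per row of `tree$edge`.
#' @export
branch_ranges <- function(tree, grid, assume_range_one = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(grid, "occurrence_grid"))
  ntip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(grid$cells))
  if (length(missing) && !assume_range_one) {
    stop("tips missing from occurrence grid: ", paste(missing, collapse = ", "))
  }
  sets <- vector("list", ntip + tree$Nnode)
  sets[seq_len(ntip)] <- grid$cells[tree$tip.label]
  if (length(missing)) {
    warning("assigning range 1 (private cell) to: ",
            paste(missing, collapse = ", "))
    for (m in match(missing, tree$tip.label)) {
      sets[[m]] <- cell_key(.Machine$integer.max - m, m)
    }
  }
  for (i in ape::postorder(tree)) {
    par <- tree$edge[i, 1L]
    sets[[par]] <- union(sets[[par]], sets[[tree$edge[i, 2L]]])
  }
  lengths(sets)[tree$edge[, 2L]]
}

#' Range-weight a phylogeny
#'
#' Divides every branch length by the number of grid cells occupied by the
#' species descending from that branch. Branches subtending narrowly
#' distributed clades keep (almost) their original length, while branches
#' leading to widespread clades shrink proportionally; recomputing
#' fair-proportion ED on this tree yields the RED index.
#'
#' @inheritParams branch_ranges
#' @return A `phylo` with the same topology and weighted branch lengths.
#' @export
range_weight_tree <- function(tree, grid, assume_range_one = FALSE) {
  r <- branch_ranges(tree, grid, assume_range_one)
  tree$edge.length <- tree$edge.length / r
  tree
}

#' Relative Evolutionary Distinctness over a replicate set
#'
#' RED is fair-proportion ED computed on the range-weighted tree. Because it
#' needs only a phylogeny and occurrence data, it is computed for evaluated
#' and not-evaluated species alike, and serves as an EDGE surrogate where
#' threat statuses are missing (narrow ranges stand in for high threat).
#'
#' @inheritParams ed_table
#' @inheritParams branch_ranges
#' @return A `score_table` tagged `"RED"` with per-replicate scores and
#'   medians.
#' @export
red_scores <- function(replicates, grid, assume_range_one = FALSE) {
  trees <- replicate_trees(replicates)
  species <- sort(trees[[1L]]$tip.label)
  mat <- vapply(trees, function(tr) {
    fair_proportion_ed(range_weight_tree(tr, grid, assume_range_one))[species]
  }, numeric(length(species)))
  mat <- matrix(mat, nrow = length(species), dimnames = list(species, NULL))
  new_score_table(mat, "RED")
}
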