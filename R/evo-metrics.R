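#' Fair-proportion evolutionary distinctness
#'
#' ED of a tip is the sum, over the branches on its root-to-tip path, of the
#' branch length divided by the number of tips descending from that branch:
#' each branch is apportioned equally among the species that share it, so
#' long branches with few descendants score high. ED values over all tips sum
#' to the total branch length of the tree.
#'
#' @param tree A rooted `phylo` with branch lengths (polytomies allowed).
#' @return Named numeric vector of ED scores, one per tip.
#' @export
fair_proportion_ed <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    return(stats::setNames(sum(tree$edge.length), tree$tip.label))
  }
  po <- ape::postorder(tree)
  n_node <- ntip + tree$Nnode
  ndesc <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  for (i in po) {
    ndesc[tree$edge[i, 1L]] <- ndesc[tree$edge[i, 1L]] + ndesc[tree$edge[i, 2L]]
  }
  contrib <- tree$edge.length / ndesc[tree$edge[, 2L]]
  acc <- numeric(n_node)
  for (i in rev(po)) { # preorder
    acc[tree$edge[i, 2L]] <- acc[tree$edge[i, 1L]] + contrib[i]
  }
  stats::setNames(acc[seq_len(ntip)], tree$tip.label)
}

#' Threat status tables
#'
#' Maps species to red-list categories `LC`, `NT`, `VU`, `EN`, `CR`, or `NE`
#' (not evaluated; data-deficient species should be recorded as `NE`).
#'
#' @param species Character vector of species labels.
#' @param category Character vector of categories.
#' @return A `status_table` data frame with columns `species`, `category`.
#' @export
status_table <- function(species, category) {
  species <- normalize_label(species)
  category <- toupper(trimws(category))
  category[category %in% c("DD", "")] <- "NE"
  bad <- setdiff(unique(category), c(iucn_categories(), "NE"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(species)) {
    stop("duplicated species in status table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  out <- data.frame(species = species, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("status_table", "data.frame")
  out
}

#' @rdname status_table
#' @param path CSV file with columns `species,category`.
#' @export
read_status_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "category") %in% names(df))) {
    stop("status table must have columns species,category")
  }
  status_table(df$species, df$category)
}

#' @rdname status_table
#' @export
iucn_categories <- function() c("LC", "NT", "VU", "EN", "CR")

#' Globally Endangered rank of a red-list category
#'
#' The GE component of EDGE: `LC = 0`, `NT = 1`, `VU = 2`, `EN = 3`,
#' `CR = 4`. Not-evaluated species have no GE and must be filtered out by
#' the caller.
#'
#' @param category Character vector of categories (no `NE`).
#' @return Integer vector of GE ranks.
#' @export
ge_rank <- function(category) {
  r <- match(category, iucn_categories()) - 1L
  if (anyNA(r)) {
    stop("GE undefined for category: ",
         paste(unique(category[is.na(r)]), collapse = ", "))
  }
  r
}

#' Extinction-probability schemes for EDGE
#'
#' Four schemes are bundled. `isaac` uses the log-transform
#' `EDGE = ln(1 + ED) + GE * ln 2` (Isaac et al. 2007). `iucn50`, `iucn100`
#' and `iucn500` interpret the red-list category as a probability of
#' extinction within 50, 100 or 500 years (the transformations tabulated by
#' Mooers et al. 2008) and score the expected loss of distinct history,
#' `EDGE = ED * p(category)`. The probability table ships as an editable CSV
#' (`system.file("extdata", "schemes.csv", package = "redmetrics")`) so the
#' constants in use are always auditable; [extinction_probability()] reads
#' from it.
#'
#' @param scheme One of `"isaac"`, `"iucn50"`, `"iucn100"`, `"iucn500"`.
#' @param path Optional path to an alternative `scheme,category,probability`
#'   CSV.
#' @return For `extinction_probability`, a named numeric vector of
#'   probabilities over `LC..CR`, non-decreasing in threat severity.
#' @export
extinction_schemes <- function() c("isaac", "iucn50", "iucn100", "iucn500")

#' @rdname extinction_schemes
#' @export
extinction_probability <- function(scheme, path = NULL) {
  scheme <- match.arg(scheme, c("iucn50", "iucn100", "iucn500"))
  if (is.null(path)) {
    path <- system.file("extdata", "schemes.csv", package = "redmetrics")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$scheme == scheme, ]
  p <- stats::setNames(tab$probability, tab$category)[iucn_categories()]
  if (anyNA(p)) stop("scheme ", scheme, " does not cover every category")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  if (is.unsorted(p)) stop("probabilities must be non-decreasing LC -> CR")
  p
}

#' EDGE score of one species
#'
#' Combines evolutionary distinctness with threat level. Under the `isaac`
#' scheme, `EDGE = ln(1 + ED) + GE * ln 2`; under the probability schemes,
#' `EDGE = ED * p(category)`, the expected amount of unique evolutionary
#' history lost. Only the ranking of EDGE values is interpreted, and within a
#' scheme any strictly monotone variant ranks identically.
#'
#' @param ed Numeric vector of ED scores (>= 0).
#' @param category Red-list categories, same length or length 1 (no `NE`).
#' @param scheme One of [extinction_schemes()].
#' @param scheme_path Optional alternative probability table (see
#'   [extinction_probability()]).
#' @return Numeric vector of EDGE scores.
#' @export
edge_score <- function(ed, category, scheme = "isaac", scheme_path = NULL) {
  scheme <- match.arg(scheme, extinction_schemes())
  if (any(ed < 0)) stop("ED must be non-negative")
  if (any(category == "NE")) stop("EDGE undefined for not-evaluated species")
  if (scheme == "isaac") {
    log1p(ed) + ge_rank(category) * log(2)
  } else {
    p <- extinction_probability(scheme, scheme_path)
    ed * unname(p[match(category, iucn_categories())])
  }
}

# assemble a score_table from a species x replicate matrix
new_score_table <- function(mat, metric, scheme = NA_character_) {
  med <- apply(mat, 1L, stats::median)
  out <- data.frame(species = rownames(mat), median = med,
                    mat, check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("species", "median", paste0("rep_", seq_len(ncol(mat))))
  structure(out, class = c("score_table", "data.frame"),
            metric = metric, scheme = scheme)
}

#' @export
print.score_table <- function(x, ...) {
  cat(attr(x, "metric"),
      if (!is.na(attr(x, "scheme"))) paste0("(", attr(x, "scheme"), ")"),
      "scores:", nrow(x), "species x", ncol(x) - 2L, "replicates\n")
  utils::str(utils::head(as.data.frame(x)[, 1:2]))
  invisible(x)
}

#' Median score column of a score table
#' @param x A `score_table`.
#' @return Named numeric vector of per-species medians over replicates.
#' @export
score_medians <- function(x) {
  stopifnot(inherits(x, "score_table"))
  stats::setNames(x$median, x$species)
}

replicate_trees <- function(replicates) {
  if (inherits(replicates, "replicate_set")) return(replicates$trees)
  if (inherits(replicates, "phylo")) {
    trees <- list(replicates); class(trees) <- "multiPhylo"; return(trees)
  }
  if (inherits(replicates, "multiPhylo")) return(replicates)
  stop("expected a replicate_set, multiPhylo or phylo")
}

#' ED scores over a replicate set
#'
#' Computes fair-proportion ED on every replicate tree and the per-species
#' median over replicates (for an even number of replicates the median is the
#' mean of the two central values). Species fixed in the backbone have
#' identical root-to-tip paths in all replicates, hence zero ED variance.
#'
#' @param replicates A `replicate_set`, `multiPhylo`, or single `phylo`.
#' @return A `score_table` tagged `"ED"`.
#' @export
ed_table <- function(replicates) {
  trees <- replicate_trees(replicates)
  species <- sort(trees[[1L]]$tip.label)
  mat <- vapply(trees, function(tr) fair_proportion_ed(tr)[species],
                numeric(length(species)))
  mat <- matrix(mat, nrow = length(species), dimnames = list(species, NULL))
  new_score_table(mat, "ED")
}

#' EDGE scores over a replicate set
#'
#' ED is computed per replicate and combined with the threat status of each
#' evaluated species under the chosen extinction-probability scheme.
#' Not-evaluated (`NE`) species are excluded from the output; species listed
#' in the status table but absent from the trees are reported with a warning
#' and dropped.
#'
#' @inheritParams ed_table
#' @param statuses A [status_table()].
#' @inheritParams edge_score
#' @return A `score_table` tagged `"EDGE"` with the scheme recorded.
#' @export
edge_table <- function(replicates, statuses, scheme = "isaac",
                       scheme_path = NULL) {
  scheme <- match.arg(scheme, extinction_schemes())
  stopifnot(inherits(statuses, "status_table"))
  trees <- replicate_trees(replicates)
  tips <- trees[[1L]]$tip.label
  absent <- setdiff(statuses$species, tips)
  if (length(absent)) {
    warning("status table species absent from trees: ",
            paste(absent, collapse = ", "))
  }
  keep <- statuses[statuses$category != "NE" & statuses$species %in% tips, ]
  if (nrow(keep) == 0L) stop("no evaluated species present in the trees")
  species <- sort(keep$species)
  category <- keep$category[match(species, keep$species)]
  mat <- vapply(trees, function(tr) {
    ed <- fair_proportion_ed(tr)[species]
    edge_score(ed, category, scheme, scheme_path)
  }, numeric(length(species)))
  mat <- matrix(mat, nrow = length(species), dimnames = list(species, NULL))
  new_score_table(mat, "EDGE", scheme)
}

#' Summary of a status table
#'
#' Counts and whole-percent shares of each red-list category among evaluated
#' species, plus the threatened total (`VU + EN + CR`).
#'
#' @param statuses A [status_table()].
#' @return A list with `n_evaluated`, `n_total`, `counts`, `percent`
#'   (rounded to whole percent of evaluated), `n_threatened`,
#'   `pct_threatened`.
#' @export
status_summary <- function(statuses) {
  stopifnot(inherits(statuses, "status_table"))
  ev <- statuses$category[statuses$category != "NE"]
  counts <- vapply(iucn_categories(), function(k) sum(ev == k), integer(1L))
  n_ev <- length(ev)
  thr <- sum(counts[c("VU", "EN", "CR")])
  list(n_evaluated = n_ev,
       n_total = nrow(statuses),
       counts = counts,
       percent = round(100 * counts / n_ev),
       n_threatened = thr,
       pct_threatened = round(100 * thr / n_ev))
}

#' Write a score table to TSV
#' @param x A `score_table`.
#' @param path Output path.
#' @param keep_replicates Keep per-replicate columns (default: species and
#'   median only).
#' @export
write_score_table <- function(x, path, keep_replicates = FALSE) {
  df <- as.data.frame(x)
  if (!keep_replicates) df <- df[, c("species", "median")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
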