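#' Dense priority ranks from median scores
#'
#' Ranks species by descending score; species with identical scores share a
#' rank and the next distinct score takes the previous rank plus one, so the
#' ranks form a dense sequence 1, 2, 3, ... with no gaps after ties. This is
#' the convention used for presentation of priority lists; the concordance
#' statistics internally use midranks instead (see [kendall_w()]).
#'
#' @param scores Named numeric vector of scores (e.g. [score_medians()]), or
#'   a `score_table` whose median column is used.
#' @return A `rank_table` data frame with columns `species`, `rank`, sorted
#'   by rank.
#' @export
dense_rank <- function(scores) {
  if (inherits(scores, "score_table")) scores <- score_medians(scores)
  if (length(scores) == 0L) stop("no scores to rank")
  if (any(!is.finite(scores))) stop("scores must be finite")
  lev <- sort(unique(scores), decreasing = TRUE)
  out <- data.frame(species = names(scores),
                    rank = match(scores, lev),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$species), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' @rdname dense_rank
#' @param species,rank Explicit species/rank vectors (e.g. transcribed from a
#'   published priority list).
#' @export
rank_table <- function(species, rank) {
  out <- data.frame(species = normalize_label(species), rank = as.numeric(rank),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$species)) stop("duplicated species in rank table")
  out <- out[order(out$rank, out$species), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

# align two rank tables on an identical species universe; returns a list of
# midrank vectors (ties averaged), which the tie-corrected statistics need
aligned_midranks <- function(rank_a, rank_b) {
  stopifnot(inherits(rank_a, "rank_table"), inherits(rank_b, "rank_table"))
  diff <- c(setdiff(rank_a$species, rank_b$species),
            setdiff(rank_b$species, rank_a$species))
  if (length(diff)) {
    stop("species sets differ: ", paste(diff, collapse = ", "))
  }
  sp <- sort(rank_a$species)
  a <- rank_a$rank[match(sp, rank_a$species)]
  b <- rank_b$rank[match(sp, rank_b$species)]
  list(species = sp,
       a = rank(a, ties.method = "average"),
       b = rank(b, ties.method = "average"))
}

#' Kendall's coefficient of concordance for two rankings
#'
#' W for m = 2 judges with the standard tie correction:
#' `W = 12 S / (m^2 (n^3 - n) - m * sum(T_j))`, where `S` is the sum of
#' squared deviations of the per-species rank sums from their mean and
#' `T_j = sum(t^3 - t)` over tie groups of judge `j`. Ranks are converted to
#' midranks internally. For two rankings without ties,
#' `W = (1 + rho) / 2` where `rho` is the Spearman correlation.
#'
#' @param rank_a,rank_b `rank_table`s over the same species (n >= 3).
#' @return W in `[0, 1]`.
#' @export
kendall_w <- function(rank_a, rank_b) {
  al <- aligned_midranks(rank_a, rank_b)
  n <- length(al$species)
  if (n < 3L) stop("need at least 3 species")
  m <- 2
  R <- al$a + al$b
  S <- sum((R - mean(R))^2)
  tie_term <- function(r) {
    t <- table(r)
    sum(t^3 - t)
  }
  denom <- m^2 * (n^3 - n) - m * (tie_term(al$a) + tie_term(al$b))
  if (denom <= 0) stop("degenerate rankings: all species tied")
  12 * S / denom
}

#' Spearman rank correlation between two rankings
#'
#' Pearson correlation of the midrank vectors, with a two-sided p-value from
#' the large-sample t approximation.
#'
#' @inheritParams kendall_w
#' @return A list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(rank_a, rank_b) {
  al <- aligned_midranks(rank_a, rank_b)
  n <- length(al$species)
  if (n < 3L) stop("need at least 3 species")
  if (stats::sd(al$a) == 0 || stats::sd(al$b) == 0) {
    warning("zero variance in a rank vector; rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(al$a, al$b, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

# the species making up the top-k of a rank table: the k best-ranked species,
# extended to include every species tied at the k-th position
topk_species <- function(rt, k) {
  stopifnot(inherits(rt, "rank_table"))
  if (k < 1L) stop("k must be >= 1")
  ord <- rt[order(rt$rank), , drop = FALSE]
  if (nrow(ord) <= k) return(ord$species)
  cutoff <- ord$rank[k]
  sel <- ord$species[ord$rank <= cutoff]
  if (length(sel) > k) {
    message("top-", k, " boundary tie: including ", length(sel), " species")
  }
  sel
}

#' Overlap between the top-k of two priority rankings
#'
#' Takes the k best-ranked species of each table (a tie straddling the k-th
#' position includes all species at that rank) and counts the species shared
#' between the two lists; the percentage is relative to `k`.
#'
#' @inheritParams kendall_w
#' @param k List length (default 20).
#' @return List with `shared` (species), `count`, `pct`, `k`, and the two
#'   top-k sets `top_a`, `top_b`.
#' @export
topk_overlap <- function(rank_a, rank_b, k = 20) {
  common <- intersect(rank_a$species, rank_b$species)
  if (length(common) < length(rank_a$species) ||
      length(common) < length(rank_b$species)) {
    message("comparing on the ", length(common), "-species intersection")
  }
  ta <- topk_species(rank_a, k)
  tb <- topk_species(rank_b, k)
  shared <- intersect(ta, tb)
  list(shared = sort(shared), count = length(shared),
       pct = 100 * length(shared) / k, k = k, top_a = ta, top_b = tb)
}

#' Concordance summary between two rankings
#'
#' Bundles Kendall's W, the Spearman correlation with its p-value, and the
#' top-k list overlap; this is the validation applied to median RED versus
#' median EDGE ranks over evaluated species.
#'
#' @inheritParams topk_overlap
#' @return A `comparison_result` list: `W`, `rho`, `p`, `n`, `k`,
#'   `topk_shared`, `topk_pct`.
#' @export
compare_rankings <- function(rank_a, rank_b, k = 20) {
  sp <- spearman_rho(rank_a, rank_b)
  ov <- topk_overlap(rank_a, rank_b, k)
  structure(list(W = kendall_w(rank_a, rank_b),
                 rho = sp$rho, p = sp$p, n = sp$n,
                 k = k, topk_shared = ov$count, topk_pct = ov$pct),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("n = %d species: Kendall W = %.3f, Spearman rho = %.3f (p = %.3g), top-%d overlap = %d (%.0f%%)\n",
              x$n, x$W, x$rho, x$p, x$k, x$topk_shared, x$topk_pct))
  invisible(x)
}
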