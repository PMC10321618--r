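# random rooted tree with branch lengths, occasionally with polytomies
random_tree <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n)
  if (polytomies && n > 4) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.2))
  }
  tr
}

# random ultrametric tree
random_ultra <- function(n) ape::rcoal(n)

# small grid assigning each tip a random cell set from a shared pool
random_grid <- function(tips, n_cells = 12, max_range = 5) {
  pool <- paste0("c", seq_len(n_cells))
  occurrence_grid(stats::setNames(lapply(tips, function(t) {
    sample(pool, sample.int(max_range, 1L))
  }), tips))
}

cherry_with_outgroup <- function() {
  # genus A cherry (terminal edges 1,1; stem 2) plus outgroup: 3 eligible
  # edges for random placement inside genus A
  read_newick_text("((A_x:1,A_y:1):2,B_z:3);")
}

# tip labels of the sister clade of a named tip
sister_tips <- function(tree, tip) {
  i <- which(tree$tip.label == tip)
  par <- tree$edge[tree$edge[, 2] == i, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == par, 2], i)
  sort(tree$tip.label[unlist(phangorn::Descendants(tree, sibs, "tips"))])
}
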