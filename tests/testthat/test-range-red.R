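test_that("grid assignment follows the half-open floor convention", {
  pts <- data.frame(species = c("S a", "S a", "S b", "S b"),
                    lon = c(-71.2, -71.2, -71.0, -70.9),
                    lat = c(-33.6, -33.6, -33.5, -33.5))
  grid <- assign_grid_cells(pts, 0.5)
  expect_equal(grid$cells[["S a"]], "-143:-68") # floor(-71.2/.5), floor(-33.6/.5)
  # boundary point belongs to the upper cell, duplicates collapse
  expect_setequal(grid$cells[["S b"]], c("-142:-67", "-142:-67")[1])
  expect_equal(range_sizes(grid), c("S a" = 1L, "S b" = 1L))

  bad <- data.frame(species = "x", lon = 181, lat = 0)
  expect_error(assign_grid_cells(bad), "out-of-range")
})

test_that("occurrence CSV dialects are auto-detected and equivalent", {
  pt <- withr::local_tempfile(fileext = ".csv")
  pr <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("A a", "B b"), lon = c(0.1, 3.3),
                       lat = c(0.1, -2.2)), pt, row.names = FALSE)
  g1 <- read_occurrences(pt)
  write_occurrences(g1, pr)
  g2 <- read_occurrences(pr)
  expect_equal(g1$cells, g2$cells)
  expect_error(occurrence_grid(list(A = character(0))), "zero occupied")
})

test_that("branch ranges are descendant cell-set unions", {
  cherry <- read_newick_text("(A:1,B:1);")
  grid <- occurrence_grid(list(A = c("c1", "c2"), B = c("c2", "c3")))
  r <- branch_ranges(cherry, grid)
  expect_equal(r, c(2, 2)) # two terminal edges

  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  grid1 <- occurrence_grid(list(A = "c1", B = "c1", C = "c1"))
  expect_equal(branch_ranges(tr, grid1), rep(1, 4))

  expect_error(branch_ranges(tr, grid), "missing from occurrence grid")
  expect_warning(r1 <- branch_ranges(tr, grid, assume_range_one = TRUE),
                 "range 1")
  expect_true(all(r1 >= 1))
})

test_that("branch ranges equal a brute-force descendant-union oracle", {
  set.seed(47)
  for (rep in 1:8) {
    tr <- random_tree(12, polytomies = rep %% 2 == 0)
    grid <- random_grid(tr$tip.label)
    got <- branch_ranges(tr, grid)
    ntip <- length(tr$tip.label)
    root <- ntip + 1L
    # oracle: a tip descends from an edge iff the edge's child node lies on
    # the root-to-tip node path
    oracle <- vapply(seq_len(nrow(tr$edge)), function(i) {
      child <- tr$edge[i, 2L]
      desc <- Filter(function(t) child %in% ape::nodepath(tr, root, t),
                     seq_len(ntip))
      length(unique(unlist(grid$cells[tr$tip.label[desc]])))
    }, numeric(1))
    expect_equal(got, oracle)
  }
})

test_that("range weighting divides each branch by its range", {
  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  grid <- occurrence_grid(list(A = c("c1", "c2"), B = "c3",
                               C = c("c4", "c5", "c6", "c7")))
  rw <- range_weight_tree(tr, grid)
  expect_equal(sort(rw$edge.length), sort(c(0.5, 1, 1 / 3, 0.5)))
  # identity when every species shares a single cell
  grid1 <- occurrence_grid(list(A = "c", B = "c", C = "c"))
  expect_equal(range_weight_tree(tr, grid1), tr)
  # never longer than the original branch
  set.seed(8)
  big <- random_ultra(15); big$tip.label <- paste("G", big$tip.label)
  g <- random_grid(big$tip.label)
  expect_true(all(range_weight_tree(big, g)$edge.length <= big$edge.length))
})

test_that("RED worked example and conservation identity hold", {
  tr <- read_newick_text("((A:1,B:1):1,C:2);")
  grid <- occurrence_grid(list(A = c("c1", "c2"), B = "c3",
                               C = c("c4", "c5", "c6", "c7")))
  red <- score_medians(red_scores(tr, grid))
  expect_equal(red, c(A = 2 / 3, B = 7 / 6, C = 0.5))
  expect_equal(sum(red), sum(range_weight_tree(tr, grid)$edge.length))

  # RED == ED when all species share one cell
  grid1 <- occurrence_grid(list(A = "c", B = "c", C = "c"))
  expect_equal(score_medians(red_scores(tr, grid1)),
               fair_proportion_ed(tr))
})

test_that("shrinking a species' range never decreases its RED", {
  set.seed(12)
  for (rep in 1:5) {
    tr <- random_ultra(10); tr$tip.label <- paste("G", tr$tip.label)
    grid <- random_grid(tr$tip.label, max_range = 6)
    sp <- names(which(range_sizes(grid) >= 3))[1]
    if (is.na(sp)) next
    shrunk <- grid
    shrunk$cells[[sp]] <- shrunk$cells[[sp]][1:2] # strict subset
    red0 <- score_medians(red_scores(tr, grid))
    red1 <- score_medians(red_scores(tr, shrunk))
    expect_gte(red1[[sp]], red0[[sp]])
  }
})

test_that("RED is invariant to relabeling grid cells", {
  set.seed(13)
  tr <- random_ultra(8); tr$tip.label <- paste("G", tr$tip.label)
  grid <- random_grid(tr$tip.label)
  relab <- grid
  relab$cells <- lapply(relab$cells, function(x) paste0("zz", x))
  expect_equal(score_medians(red_scores(tr, grid)),
               score_medians(red_scores(tr, relab)))
})
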