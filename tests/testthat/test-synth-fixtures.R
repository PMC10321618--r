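small_cfg <- function(...) {
  simulation_config(n_species = 20, n_genera = 10,
                    status_counts = c(CR = 1, EN = 4, VU = 2, NT = 1, LC = 1),
                    ...)
}

test_that("simulated trees are ultrametric, genus-monophyletic and reproducible", {
  cfg <- small_cfg()
  tr <- simulate_tree(cfg, seed = 6)
  expect_length(tr$tip.label, 20)
  expect_lt(check_ultrametric(tr), 1e-9)
  expect_equal(tree_height(tr), 100, tolerance = 1e-9)
  genera <- tip_genus(tr$tip.label)
  for (g in unique(genera)) {
    tips <- which(genera == g)
    if (length(tips) < 2) next
    mrca <- ape::getMRCA(tr, tips)
    clade <- ape::extract.clade(tr, mrca)
    expect_setequal(clade$tip.label, tr$tip.label[tips])
  }
  expect_equal(ape::write.tree(simulate_tree(cfg, seed = 6)),
               ape::write.tree(tr))
  expect_false(ape::write.tree(simulate_tree(cfg, seed = 7)) ==
                 ape::write.tree(tr))
})

test_that("simulated ranges are contiguous blocks with log-normal sizes", {
  cfg <- simulation_config(n_species = 50, n_genera = 10,
                           status_counts = c(CR = 1, EN = 4, VU = 2, NT = 1, LC = 1))
  sp <- paste("G", 1:50)
  g1 <- simulate_ranges(sp, cfg, seed = 3)
  g2 <- simulate_ranges(sp, cfg, seed = 3)
  expect_equal(g1$cells, g2$cells)
  expect_true(all(range_sizes(g1) >= 1))
  expect_true(all(range_sizes(g1) <= prod(cfg$extent)))

  # Monte-Carlo: mean log range size tracks the configured meanlog; the
  # rounding to >= 1 cell biases log sizes upward, so allow a one-sided band
  big <- simulation_config(n_species = 10000, n_genera = 10,
                           range_meanlog = 1.5, range_sdlog = 1.2,
                           extent = c(200L, 200L),
                           status_counts = c(CR = 1, EN = 1, VU = 1, NT = 1, LC = 1))
  sizes <- range_sizes(simulate_ranges(paste("S", 1:10000), big, seed = 8))
  se <- 1.2 / sqrt(10000)
  expect_lt(abs(mean(log(sizes)) - 1.5), 3 * se + 0.1)
})

test_that("simulated statuses hit the configured counts exactly", {
  cfg <- simulation_config() # 7 CR, 54 EN, 23 VU, 7 NT, 4 LC of 95 evaluated
  sp <- paste("S", 1:200)
  st <- simulate_statuses(sp, cfg, seed = 2)
  ss <- status_summary(st)
  expect_equal(ss$n_evaluated, 95L)
  expect_equal(unname(ss$counts[c("CR", "EN", "VU", "NT", "LC")]),
               c(7L, 54L, 23L, 7L, 4L))
  expect_equal(sum(st$category == "NE"), 105L)
})

test_that("coupling threat to range size induces a strong negative association", {
  cfg <- simulation_config(n_species = 120, n_genera = 12)
  sp <- paste("S", 1:120)
  grid <- simulate_ranges(sp, cfg, seed = 5)
  coupled <- simulate_statuses(sp, cfg, couple_to_range = TRUE,
                               grid = grid, seed = 6)
  ev <- coupled[coupled$category != "NE", ]
  rho_c <- stats::cor(range_sizes(grid)[ev$species], ge_rank(ev$category),
                      method = "spearman")
  expect_lt(rho_c, -0.7)

  # uncoupled: association near zero on average over seeds
  rhos <- sapply(1:10, function(s) {
    un <- simulate_statuses(sp, cfg, couple_to_range = FALSE,
                            grid = grid, seed = 100 + s)
    ev <- un[un$category != "NE", ]
    stats::cor(range_sizes(grid)[ev$species], ge_rank(ev$category),
               method = "spearman")
  })
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("simulate_dataset wires a consistent bundle", {
  cfg <- small_cfg(withheld_fraction = 0.3)
  sim <- simulate_dataset(cfg, seed = 77)
  expect_setequal(c(sim$backbone$tip.label, sim$plan$species),
                  sim$tree$tip.label)
  expect_equal(nrow(sim$plan), 6) # 30% of 20
  # every withheld species has a congener left in the backbone
  expect_true(all(tip_genus(sim$plan$species) %in%
                    tip_genus(sim$backbone$tip.label)))
  expect_setequal(names(sim$grid$cells), sim$tree$tip.label)
  expect_setequal(sim$statuses$species, sim$tree$tip.label)
})
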