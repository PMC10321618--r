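test_that("midpoint sister placement bisects the target branch and stays ultrametric", {
  tr <- read_newick_text("(A:2,B:2);")
  out <- place_midpoint_sister(tr, "X", "A")
  expect_equal(ape::write.tree(out), "((A:1,X:1):1,B:2);")
  expect_equal(check_ultrametric(out), 0)

  # clade target: genus with several tips resolves to its MRCA stem
  tr2 <- read_newick_text("((Aimara_a:1,Aimara_b:1):1,B_c:2);")
  out2 <- place_midpoint_sister(tr2, "Ivania juncalensis", "Aimara")
  expect_equal(check_ultrametric(out2), 0)
  # genus stem spans depths 0..1, so the attachment sits at depth 0.5:
  # Ivania reaches either Aimara tip via 1.5 + 0.5 + 1 = 3
  cp <- ape::cophenetic.phylo(out2)
  expect_equal(cp["Ivania juncalensis", "Aimara a"], 3)
  expect_equal(cp["Ivania juncalensis", "Aimara b"], 3)
  expect_equal(cp["Ivania juncalensis", "B c"], 4)

  expect_error(place_midpoint_sister(tr, "X", "nope"), "matches no")
  zero <- read_newick_text("((A:0,B:2):1);")
  expect_error(place_midpoint_sister(zero, "X", "A"), "length 0")
})

test_that("random within-genus placement: forced cherry, determinism, tree height", {
  tr <- read_newick_text("((A_x:1,A_y:1):2,B_z:3);")
  # single-congener genus B: forced cherry with B z
  out <- add_species_to_genus_random(tr, "B w", "B", seed = 4)
  expect_setequal(sister_tips(out, "B w"), "B z")
  expect_equal(check_ultrametric(out), 0, tolerance = 1e-12)
  expect_equal(tree_height(out), 3)

  # same seed -> identical tree; different seed -> generally different
  a <- add_species_to_genus_random(tr, "A q", "A", seed = 99)
  b <- add_species_to_genus_random(tr, "A q", "A", seed = 99)
  expect_equal(ape::write.tree(a), ape::write.tree(b))

  expect_error(add_species_to_genus_random(tr, "C c", "C"), "absent")
})

test_that("random placement picks uniformly among eligible edges, not by length", {
  tr <- cherry_with_outgroup() # genus A: edges of length 1, 1 and stem 2
  n <- 4000
  set.seed(2024)
  attach_type <- character(n)
  for (i in seq_len(n)) {
    out <- add_species_to_genus_random(tr, "A new", "A")
    attach_type[i] <- paste(sister_tips(out, "A new"), collapse = "+")
  }
  freq <- table(attach_type) / n
  expect_setequal(names(freq), c("A x", "A y", "A x+A y"))
  # uniform per edge: 1/3 each regardless of the 1:1:2 length ratio
  expect_true(all(abs(freq - 1 / 3) < 0.025))
})

test_that("replicates share tip sets, stay ultrametric, and are reproducible", {
  cfg <- simulation_config(n_species = 40, n_genera = 8,
                           status_counts = c(CR = 2, EN = 8, VU = 4, NT = 2, LC = 2),
                           withheld_fraction = 0.25)
  sim <- simulate_dataset(cfg, seed = 21)
  reps <- generate_replicates(sim$backbone, sim$plan, n = 6, seed = 303)
  expect_length(reps, 6L)
  for (tr in reps$trees) {
    expect_setequal(tr$tip.label, sim$tree$tip.label)
    expect_lt(check_ultrametric(tr), 1e-6)
    expect_equal(tree_height(tr), tree_height(sim$backbone), tolerance = 1e-9)
  }
  reps2 <- generate_replicates(sim$backbone, sim$plan, n = 6, seed = 303)
  expect_equal(lapply(reps$trees, ape::write.tree),
               lapply(reps2$trees, ape::write.tree))

  # empty plan, n = 1: the backbone itself
  empty <- placement_plan(character(0), character(0), character(0))
  single <- generate_replicates(sim$backbone, empty, n = 1, seed = 1)
  expect_true(ape::all.equal.phylo(single$trees[[1]], sim$backbone))
})

test_that("backbone species keep identical root-to-tip paths across replicates", {
  cfg <- simulation_config(n_species = 30, n_genera = 6,
                           status_counts = c(CR = 1, EN = 4, VU = 2, NT = 1, LC = 1),
                           withheld_fraction = 0.2)
  sim <- simulate_dataset(cfg, seed = 9)
  reps <- generate_replicates(sim$backbone, sim$plan, n = 5, seed = 17)
  fixed <- setdiff(sim$backbone$tip.label, sim$plan$species)
  # grafting never moves a backbone tip: its root-to-tip path is identical in
  # every replicate (ED itself still varies, because added tips change the
  # descendant counts of shared branches)
  depths <- sapply(reps$trees, function(tr) tip_depths(tr)[fixed])
  # variance at double-precision rounding noise only (depths ~ 100)
  expect_lt(max(apply(depths, 1, stats::var)), 1e-12)
})
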