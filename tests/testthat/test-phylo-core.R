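test_that("newick parsing preserves structure and handles missing lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  root <- setdiff(unique(tr$edge[, 1]), tr$edge[, 2])
  expect_equal(sum(tr$edge[, 1] == root), 2)

  expect_warning(poly <- read_newick("(A,B,C);"), "branch lengths")
  expect_equal(ape::Ntip(poly), 3)
  expect_equal(poly$Nnode, 1)
  expect_true(all(poly$edge.length == 0))

  expect_error(suppressWarnings(read_newick("((A:1,B:1")), "parse error")
  expect_error(read_newick(text = NULL), "exactly one")
})

test_that("newick round-trip reproduces topology and branch lengths", {
  for (seed in 1:100) {
    n <- sample(3:20, 1)
    tr <- random_test_tree(n, seed)
    tr2 <- read_newick(write_newick(tr))
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_equal(patristic_matrix(tr2)[tr$tip.label, tr$tip.label],
                 patristic_matrix(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-8)  # limited by newick text precision
  }
})

test_that("patristic distances match hand sums and the path-walking oracle", {
  dm <- patristic_matrix(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(dm["A", "B"], 2)
  expect_equal(dm["A", "C"], 4)
  expect_equal(dm["B", "C"], 4)
  expect_true(all(diag(dm) == 0))

  for (seed in 1:10) {
    tr <- random_test_tree(8, 100 + seed)
    expect_equal(patristic_matrix(tr), oracle_patristic(tr), tolerance = 1e-12)
  }
})

test_that("grafting attaches at the genus MRCA and preserves ultrametricity", {
  tr <- read_newick("((G1_a:1,G1_b:1):1,G2_c:2);")
  expect_identical(graft_species(tr, data.frame(species = character(0),
                                                genus = character(0))), tr)

  tr2 <- graft_species(tr, data.frame(species = "G1_x", genus = "G1"))
  expect_equal(ape::Ntip(tr2), 4)
  dm2 <- patristic_matrix(tr2)
  # pendant length 1: new tip is 2 from its congeners, 4 from the outgroup
  expect_equal(dm2["G1_x", "G1_a"], 2)
  expect_equal(dm2["G1_x", "G2_c"], 4)
  # MRCA became a 3-way polytomy
  mrca <- ape::getMRCA(tr2, c("G1_a", "G1_b", "G1_x"))
  expect_equal(sum(tr2$edge[, 1] == mrca), 3)

  expect_error(graft_species(tr, data.frame(species = "Gx_y", genus = "Gx")),
               "unknown genera")
})

test_that("monotypic grafting splits the terminal branch at split_fraction", {
  tr <- read_newick("((G1_a:1,G1_b:1):1,G2_c:2);")
  tr2 <- graft_species(tr, data.frame(species = "G2_y", genus = "G2"),
                       split_fraction = 0.25)
  dm <- patristic_matrix(tr2)
  expect_equal(dm["G2_c", "G2_y"][[1]], 1)        # 2 * 0.25 * 2
  expect_equal(dm["G2_y", "G1_a"][[1]], 4)        # depth preserved
  expect_true(is_ultrametric_tree(tr2, tol = 1e-12))
})

test_that("grafting many species preserves existing distances and depth variance", {
  set.seed(42)
  tr <- simulate_tree(20, n_genera = 8, seed = 99)
  dm_before <- patristic_matrix(tr)
  genera <- unique(tip_genus(tr$tip.label))
  adds <- data.frame(species = sprintf("%s_new%02d",
                                       sample(genera, 50, replace = TRUE), 1:50))
  adds$genus <- tip_genus(adds$species)
  tr2 <- graft_species(tr, adds)
  expect_equal(ape::Ntip(tr2), 70)
  dm_after <- patristic_matrix(tr2)[rownames(dm_before), colnames(dm_before)]
  expect_equal(dm_after, dm_before, tolerance = 1e-12)
  depths <- root_to_tip_depths(tr2)
  expect_lt(stats::var(depths), 1e-9)
})

test_that("non-monophyletic genera attach at the MRCA with a warning", {
  tr <- read_newick("(((G1_a:1,G2_b:1):1,G1_c:2):1,G3_d:3);")
  expect_warning(tr2 <- graft_species(tr, data.frame(species = "G1_z", genus = "G1")),
                 "not monophyletic")
  expect_true("G1_z" %in% tr2$tip.label)
})

test_that("mean-path-length smoothing yields exactly ultrametric trees", {
  # fixed point: an ultrametric tree is unchanged
  tr <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  tr2 <- make_ultrametric(tr)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)

  # two-tip mean
  tr3 <- make_ultrametric(read_newick("(A:1,B:3);"))
  expect_equal(sort(tr3$edge.length), c(2, 2))

  # postcondition sweep on random non-ultrametric trees
  for (seed in 1:100) {
    n <- sample(4:30, 1)
    tr <- random_test_tree(n, 200 + seed)
    out <- make_ultrametric(tr)
    expect_true(is_ultrametric_tree(out, tol = 1e-9))
    expect_lt(stats::var(root_to_tip_depths(out)), 1e-9)
    expect_identical(out$edge, tr$edge)           # topology untouched
    expect_setequal(out$tip.label, tr$tip.label)
    expect_true(all(out$edge.length >= 0))
  }

  zero <- read_newick("((A:0,B:0):0,C:0);")
  expect_error(make_ultrametric(zero), "zero depth")
})
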