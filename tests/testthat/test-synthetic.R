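test_that("simulated trees are ultrametric, depth-1, reproducible", {
  tr <- simulate_tree(2, n_genera = 1, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sort(tr$edge.length), c(1, 1))

  for (n in c(5, 16, 64)) {
    tr <- simulate_tree(n, seed = n)
    expect_true(is_ultrametric_tree(tr, tol = 1e-9))
    expect_equal(max(root_to_tip_depths(tr)), 1)
    expect_false(anyDuplicated(tr$tip.label) > 0)
  }
  expect_identical(simulate_tree(32, seed = 9), simulate_tree(32, seed = 9))
  expect_error(simulate_tree(1, seed = 1))
  expect_error(simulate_tree(10), "seed is required")
})

test_that("genera form contiguous blocks in cladewise tip order", {
  tr <- simulate_tree(64, n_genera = 5, seed = 7)
  ord <- ethnophylo:::cladewise_tip_order(tr)
  genera <- tip_genus(tr$tip.label[ord])
  expect_false(is.unsorted(match(genera, unique(genera))))
  expect_equal(length(unique(genera)), 5)
  # each genus is a clade: the MRCA of its tips contains nothing else
  for (g in unique(tip_genus(tr$tip.label))) {
    tips <- which(tip_genus(tr$tip.label) == g)
    if (length(tips) < 2) next
    clade <- ethnophylo:::descendant_tips(tr)[[ape::getMRCA(tr, tips) - 64]]
    expect_setequal(clade, tips)
  }
})

test_that("lineage growth matches the pure-birth expectation", {
  # unconditioned Yule from 2 lineages: E[L(t)] = 2 * exp(lambda * t);
  # with n = 200 tips the stopping condition is essentially never binding
  # by t = 1, so the conditioned mean matches the closed form
  set.seed(90)
  nrep <- 300
  t_eval <- 1
  lt <- vapply(seq_len(nrep), function(i) {
    tr <- simulate_tree(200, seed = 9000 + i, rescale = FALSE)
    depths <- ape::node.depth.edgelength(tr)
    internal <- depths[-seq_len(200)]
    2 + sum(internal > 0 & internal <= t_eval)
  }, numeric(1))
  expected <- 2 * exp(t_eval)
  se <- stats::sd(lt) / sqrt(nrep)
  expect_lt(abs(mean(lt) - expected), 4 * se)
})

test_that("use scenarios respect prevalence and their defining geometry", {
  tr <- simulate_tree(64, seed = 3)
  dm <- patristic_matrix(tr)

  low <- simulate_use(tr, sim_config(n_tips = 64, prevalence = 1e-9), seed = 5)
  expect_equal(sum(low$used), 0)

  # overdispersed selection of 2 tips is the diameter pair
  sel2 <- maximin_tips(dm, 2)
  expect_equal(dm[sel2[1], sel2[2]], max(dm))

  od <- simulate_use(tr, sim_config(n_tips = 64, prevalence = 0.15,
                                    scenario = "overdispersed"), seed = 6)
  expect_equal(sum(od$used), ceiling(0.15 * 64))
  # deterministic given the tree
  od2 <- simulate_use(tr, sim_config(n_tips = 64, prevalence = 0.15,
                                     scenario = "overdispersed"), seed = 99)
  expect_identical(od$used, od2$used)
})

test_that("overdispersed samples stochastically dominate random MNTD", {
  nrep <- 50
  hits <- 0
  for (i in seq_len(nrep)) {
    tr <- simulate_tree(64, seed = 4000 + i)
    dm <- patristic_matrix(tr)
    od <- maximin_tips(dm, 10)
    set.seed(4000 + i)
    rand_mntd <- mean(vapply(1:30, function(j)
      mntd(sample(rownames(dm), 10), dm), numeric(1)))
    if (mntd(od, dm) >= rand_mntd) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("count simulation respects margins, independence and reproducibility", {
  tr <- simulate_tree(64, seed = 12)
  cfg <- sim_config(n_tips = 64, prevalence = 0.2)
  ds <- simulate_use(tr, cfg, seed = 13)
  ds1 <- simulate_counts(ds, cfg, seed = 14)
  expect_identical(ds1, simulate_counts(ds, cfg, seed = 14))
  expect_true(all(ds1$n_use_reports[ds1$used] >= 1))
  expect_true(all(ds1$n_use_reports[!ds1$used] == 0))

  # all-unused dataset keeps zero reports
  none <- ds; none$used <- FALSE; none$n_use_reports <- 0L
  out <- simulate_counts(none, cfg, seed = 15)
  expect_true(all(out$n_use_reports == 0))

  # rho target 0 gives near-zero empirical correlation at n = 286
  big <- species_dataset(data.frame(
    species = paste0("G1_s", 1:286), genus = "G1", used = TRUE,
    n_use_reports = 1L, n_studies = 0L, categories = ""))
  cfg0 <- sim_config(rho = 0)
  hits <- sum(vapply(1:20, function(i) {
    d <- simulate_counts(big, cfg0, seed = 100 + i)
    abs(stats::cor(d$n_use_reports, d$n_studies, method = "spearman")) < 0.15
  }, logical(1)))
  expect_gte(hits, 19)
})

test_that("the full bundle is reproducible bit-for-bit from one seed", {
  cfg <- sim_config(n_tips = 48, scenario = "clustered", prevalence = 0.15)
  b1 <- simulate_dataset(cfg, seed = 77)
  b2 <- simulate_dataset(cfg, seed = 77)
  expect_identical(b1$tree, b2$tree)
  expect_identical(b1$dataset, b2$dataset)
  b3 <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(b1$dataset, b3$dataset))
})
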