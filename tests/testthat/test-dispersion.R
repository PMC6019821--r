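test_that("mpd and mntd match hand computations and brute-force oracles", {
  dm <- patristic_matrix(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(mpd(c("A", "B"), dm), 2)
  expect_equal(mpd(c("A", "B", "C"), dm), 10 / 3)
  expect_equal(mntd(c("A", "B"), dm), 2)
  expect_equal(mntd(c("A", "B", "C"), dm), 8 / 3)
  expect_error(mpd("A", dm), "at least 2")
  expect_error(mntd(c("A", "Z"), dm), "not in distance matrix")

  for (seed in 1:20) {
    tr <- random_test_tree(sample(5:12, 1), 300 + seed)
    dm <- patristic_matrix(tr)
    k <- sample(2:ape::Ntip(tr), 1)
    s <- sample(tr$tip.label, k)
    expect_equal(mpd(s, dm), oracle_mpd(s, dm), tolerance = 1e-12)
    expect_equal(mntd(s, dm), oracle_mntd(s, dm), tolerance = 1e-12)
  }
})

test_that("ses results are deterministic under a fixed seed", {
  tr <- random_test_tree(20, 1)
  dm <- patristic_matrix(tr)
  s <- tr$tip.label[1:6]
  r1 <- ses_dispersion(s, dm, "mpd", runs = 199, seed = 42)
  r2 <- ses_dispersion(s, dm, "mpd", runs = 199, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$index, -r1$ses)
  expect_gte(r1$p_lower, 1 / 200)
  expect_lte(r1$p_lower, 1)
})

test_that("a sample of every tip is degenerate, not an error", {
  tr <- random_test_tree(8, 2)
  dm <- patristic_matrix(tr)
  r <- ses_dispersion(tr$tip.label, dm, "mpd", runs = 99, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$ses, 0)
  expect_equal(r$p_two, 1)
})

test_that("metrics scale with branch lengths but ses does not", {
  tr <- random_test_tree(16, 3)
  dm <- patristic_matrix(tr)
  s <- tr$tip.label[1:5]
  expect_equal(mpd(s, dm * 3), 3 * mpd(s, dm))
  expect_equal(mntd(s, dm * 3), 3 * mntd(s, dm))
  r1 <- ses_dispersion(s, dm, "mntd", runs = 199, seed = 7)
  r2 <- ses_dispersion(s, dm * 3, "mntd", runs = 199, seed = 7)
  expect_equal(r2$ses, r1$ses, tolerance = 1e-12)
  expect_equal(r2$p_two, r1$p_two)
})

test_that("null mean converges to the exhaustive subset average", {
  # for trees <= 7 tips and |sample| <= 3 the null mean can be enumerated
  for (seed in 1:3) {
    tr <- random_test_tree(sample(5:7, 1), 400 + seed)
    dm <- patristic_matrix(tr)
    combos <- utils::combn(tr$tip.label, 3)
    exact <- mean(apply(combos, 2, function(s) mpd(s, dm)))
    # combinatorial identity: the subset average equals the overall mean
    # pairwise distance
    expect_equal(exact, mean(dm[upper.tri(dm)]), tolerance = 1e-12)
    r <- ses_dispersion(tr$tip.label[1:3], dm, "mpd", runs = 5000, seed = seed)
    null_sd_of_mean <- r$null_sd / sqrt(r$runs)
    expect_lt(abs(r$null_mean - exact), 4 * null_sd_of_mean)
  }
})

test_that("observed metrics and SES agree with the picante implementation", {
  for (seed in 1:5) {
    tr <- random_test_tree(24, 900 + seed)
    dm <- patristic_matrix(tr)
    set.seed(seed)
    s <- sample(tr$tip.label, 8)
    comm <- matrix(as.integer(tr$tip.label %in% s), nrow = 2, ncol = 24,
                   byrow = TRUE, dimnames = list(c("a", "b"), tr$tip.label))
    expect_equal(mpd(s, dm), picante::mpd(comm, dm)[1], tolerance = 1e-12)
    expect_equal(mntd(s, dm), picante::mntd(comm, dm)[1], tolerance = 1e-12)
  }
  # null means/sds from the taxa-labels null agree within Monte-Carlo error
  tr <- random_test_tree(30, 950)
  dm <- patristic_matrix(tr)
  s <- tr$tip.label[1:10]
  mine <- ses_dispersion(s, dm, "mpd", runs = 2000, seed = 3)
  comm <- matrix(as.integer(tr$tip.label %in% s), nrow = 2, ncol = 30,
                 byrow = TRUE, dimnames = list(c("a", "b"), tr$tip.label))
  ref <- picante::ses.mpd(comm, dm, null.model = "taxa.labels", runs = 2000)
  expect_equal(mine$null_mean, ref$mpd.rand.mean[1],
               tolerance = 4 * mine$null_sd / sqrt(2000) / mine$null_mean)
  expect_equal(mine$ses, ref$mpd.obs.z[1], tolerance = 0.15)
})

test_that("structure classification follows NRI/NTI signs with significance gating", {
  mk <- function(metric, index, p) {
    structure(list(metric = metric, index = index, p_two = p, degenerate = FALSE),
              class = "ses_result")
  }
  expect_equal(classify_structure(mk("mpd", -2.1, 0.01), mk("mntd", -1.9, 0.02))$label,
               "overdispersion")
  expect_equal(classify_structure(mk("mpd", 3, 0.001), mk("mntd", 3, 0.001))$label,
               "clustering")
  expect_equal(classify_structure(mk("mpd", -2.5, 0.01), mk("mntd", 2.2, 0.03))$label,
               "terminal clustering, deep overdispersion")
  expect_equal(classify_structure(mk("mpd", 2.5, 0.01), mk("mntd", -2.2, 0.03))$label,
               "terminal overdispersion, deep clustering")
  expect_equal(classify_structure(mk("mpd", 1.2, 0.4), mk("mntd", -0.3, 0.9))$label,
               "random/random")
  cl <- classify_structure(mk("mpd", 2.8, 0.01), mk("mntd", 0.3, 0.7))
  expect_equal(cl$deep, "clustering")
  expect_equal(cl$terminal, "random")
  expect_error(classify_structure(mk("mntd", 1, 0.5), mk("mpd", 1, 0.5)),
               "MPD result")
})
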