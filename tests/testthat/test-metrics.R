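test_that("mpd and mntd match hand-computed values", {
  d2 <- patristic_distances(parse_newick("((a:1,b:1):0);"))
  expect_equal(mpd(d2, c("a", "b")), 2)
  expect_equal(mntd(d2, c("a", "b")), 2)  # forced equality with 2 members

  d4 <- patristic_distances(balanced4())
  expect_equal(mpd(d4, c("a", "b", "c")), 10 / 3)   # (2 + 4 + 4) / 3
  expect_equal(mntd(d4, c("a", "b", "c")), 8 / 3)   # (2 + 2 + 4) / 3

  expect_error(mpd(d4, "a"), "at least 2")
  expect_error(mntd(d4, "a"), "at least 2")
  expect_error(mpd(d4, c("a", "zz")), "not in the distance matrix")
})

test_that("mpd/mntd equal brute-force enumeration on random communities", {
  set.seed(51)
  for (i in 1:200) {
    tr <- simulate_yule_tree(sample(5:20, 1L))
    d <- patristic_distances(tr)
    k <- sample(2:(ape::Ntip(tr) - 1L), 1L)
    members <- sample(tr$tip.label, k)
    expect_equal(mpd(d, members), oracle_mpd(d, members), tolerance = 1e-12)
    expect_equal(mntd(d, members), oracle_mntd(d, members), tolerance = 1e-12)
    expect_lte(mntd(d, members), mpd(d, members) + 1e-12)
  }
})

test_that("mpd and mntd agree with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(52)
  for (i in 1:20) {
    tr <- simulate_yule_tree(sample(8:25, 1L))
    d <- patristic_distances(tr)
    k <- sample(3:(ape::Ntip(tr) - 2L), 1L)
    members <- sample(tr$tip.label, k)
    comm <- matrix(as.integer(colnames(d) %in% members), 1,
                   dimnames = list("c1", colnames(d)))
    expect_equal(mpd(d, members), picante::mpd(comm, d)[1], tolerance = 1e-12)
    expect_equal(mntd(d, members), picante::mntd(comm, d)[1], tolerance = 1e-12)
  }
})

test_that("p_from_rank follows the midrank convention", {
  # observed below every null value: rank 1, floor p = 1/(runs + 1)
  expect_equal(p_from_rank(0.5, seq_len(999)),
               list(rank = 1, p_value = 0.001))
  # observed at the median of 999 nulls: p = 0.5
  expect_equal(p_from_rank(500, setdiff(seq_len(1000), 500))$p_value, 0.5)
  # observed tied with all runs = 3 nulls: midrank (runs + 2)/2 = 2.5
  tie <- p_from_rank(7, c(7, 7, 7))
  expect_equal(tie$rank, 2.5)
  expect_equal(tie$p_value, 2.5 / 4)
  # observed above everything: p = (runs + 1)/(runs + 1) = 1
  expect_equal(p_from_rank(10, c(1, 2, 3))$p_value, 1)
})

test_that("ses_metric is deterministic under seed and flags degenerate nulls", {
  tr <- simulate_yule_tree(20, seed = 61)
  d <- patristic_distances(tr)
  members <- tr$tip.label[1:6]
  r1 <- ses_metric(d, members, "mpd", runs = 199, seed = 7)
  r2 <- ses_metric(d, members, "mpd", runs = 199, seed = 7)
  expect_identical(r1, r2)
  r3 <- ses_metric(d, members, "mpd", runs = 199, seed = 8)
  expect_false(identical(r1$null, r3$null))

  # community = entire pool: every label shuffle reproduces obs
  deg <- ses_metric(d, tr$tip.label, "mpd", runs = 99, seed = 1)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$ses))
  expect_equal(deg$null_mean, deg$obs)

  # SES identity and sign convention: ses > 0 iff obs < null mean
  expect_equal(r1$ses, -1 * (r1$obs - r1$null_mean) / r1$null_sd)
  expect_equal(r1$p_value, r1$rank / 200)
  expect_equal(sign(r1$ses), sign(r1$null_mean - r1$obs))
})

test_that("sampled null agrees with exact enumeration on a small pool", {
  # pool n = 8, k = 3: all C(8,3) = 56 communities enumerable
  tr <- balanced8()
  d <- patristic_distances(tr)
  exact_mpd <- oracle_exact_null(d, 3L, oracle_mpd)
  exact_mntd <- oracle_exact_null(d, 3L, oracle_mntd)
  runs <- 2000L
  r_mpd <- ses_metric(d, c("a", "b", "c"), "mpd", runs = runs, seed = 71)
  r_mntd <- ses_metric(d, c("a", "b", "c"), "mntd", runs = runs, seed = 72)
  for (pair in list(list(r_mpd, exact_mpd), list(r_mntd, exact_mntd))) {
    r <- pair[[1]]; ex <- pair[[2]]
    se_mean <- sd(ex) / sqrt(runs)
    expect_lt(abs(r$null_mean - mean(ex)), 3 * se_mean)
    se_sd <- sd(ex) / sqrt(2 * (runs - 1))
    expect_lt(abs(r$null_sd - sd(ex)), 3 * se_sd)
  }
})

test_that("a cherry community is detected as clustered at its exact p-value", {
  # one cherry {a, b} of the balanced 8-tip unit tree: obs MPD = 2; under the
  # taxa-label null the pair distance is 2 with probability 4/28, so the
  # limiting midrank p is (4/28)/2 = 1/14 ~ 0.071 (ties sit AT the observed
  # value; p <= 0.05 is unattainable under the midrank convention)
  tr <- balanced8()
  d <- patristic_distances(tr)
  hits_pos <- 0L; p_in_band <- 0L
  for (s in 1:100) {
    r <- ses_metric(d, c("a", "b"), "mpd", runs = 999, seed = 7000 + s)
    hits_pos <- hits_pos + (r$ses > 0)
    p_in_band <- p_in_band + (r$p_value >= 0.05 && r$p_value <= 0.10)
  }
  expect_gte(hits_pos, 95L)
  expect_gte(p_in_band, 95L)
})

test_that("ses_metric agrees with picante::ses.mpd / ses.mntd", {
  skip_if_not_installed("picante")
  tr <- simulate_yule_tree(32, seed = 81)
  d <- patristic_distances(tr)
  members <- sample_community(tr, 6, "clustered", seed = 82, dist = d)
  # two identical rows: picante's ses.* mishandles single-community input
  comm <- matrix(rep(as.integer(colnames(d) %in% members), 2), 2,
                 byrow = TRUE, dimnames = list(c("c1", "c2"), colnames(d)))
  runs <- 1999L

  mine <- ses_metric(d, members, "mpd", runs = runs, seed = 83)
  ref <- picante::ses.mpd(comm, d, null.model = "taxa.labels", runs = runs)
  expect_equal(mine$obs, ref$mpd.obs[1], tolerance = 1e-12)
  # independent RNG streams: agreement within Monte-Carlo error of the null
  expect_lt(abs(mine$null_mean - ref$mpd.rand.mean[1]),
            4 * mine$null_sd / sqrt(runs))
  expect_lt(abs(mine$ses - (-ref$mpd.obs.z[1])), 0.25)
  expect_lt(abs(mine$p_value - ref$mpd.obs.p[1]), 0.05)

  mine2 <- ses_metric(d, members, "mntd", runs = runs, seed = 84)
  ref2 <- picante::ses.mntd(comm, d, null.model = "taxa.labels", runs = runs)
  expect_equal(mine2$obs, ref2$mntd.obs[1], tolerance = 1e-12)
  expect_lt(abs(mine2$ses - (-ref2$mntd.obs.z[1])), 0.25)
})
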