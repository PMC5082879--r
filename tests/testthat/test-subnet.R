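test_that("subnetwork activity is the member mean and ignores duplicates", {
  m <- rbind(g1 = c(1, 0, 2, 1), g2 = c(3, 2, 0, 1), g3 = c(-1, 1, 1, 0))
  colnames(m) <- paste0("s", 1:4)
  ds <- expr_dataset(m, setNames(c("L", "L", "H", "H"), colnames(m)), "L")
  act <- subnetwork_activity(ds, c("g1", "g2"))
  expect_equal(unname(act[1]), 2)
  expect_equal(act, colMeans(m[c("g1", "g2"), ]))
  expect_equal(subnetwork_activity(ds, "g3"), m["g3", ])
  expect_equal(subnetwork_activity(ds, c("g1", "g2", "g1")),
               subnetwork_activity(ds, c("g1", "g2")))
  expect_error(subnetwork_activity(ds, c("g1", "gX")), "gX")
  # sqrt scaling differs only by a constant factor
  expect_equal(subnetwork_activity(ds, c("g1", "g2"), scaling = "sqrt"),
               act * sqrt(2))
})

test_that("discretization uses floor(log2 S) + 1 equal-width covering bins", {
  x <- rnorm(40)
  b <- discretize_activity(x)
  br <- attr(b, "breaks")
  expect_equal(length(br) - 1, floor(log2(40)) + 1) # 6 bins
  expect_true(all(b >= 1 & b <= 6))
  widths <- diff(br)
  expect_equal(max(widths) - min(widths), 0, tolerance = 1e-12)
  expect_lt(br[1], min(x))
  expect_gt(br[length(br)], max(x))
  # every value in exactly one bin, extremes included
  expect_equal(sum(table(b)), 40)
})

test_that("discrimination score matches hand-computable cases", {
  expect_equal(discrimination_score(c(-1, -1, 1, 1), factor(c("A", "A", "B", "B"))),
               1.0)
  expect_equal(discrimination_score(rep(2, 8), factor(rep(c("A", "B"), 4))), 0)
  # 8 values, 4 bins {1,2}{3,4}{5,6}{7,8}; labels A,A,A,B,A,B,B,B
  expect_equal(discrimination_score(1:8, factor(c("A", "A", "A", "B", "A", "B", "B", "B"))),
               0.5, tolerance = 1e-12)
  expect_error(discrimination_score(1:4, factor(rep("A", 4))), "constant")
})

test_that("discrimination score equals the entropy-identity oracle", {
  set.seed(11)
  for (i in 1:200) {
    s <- sample(6:32, 1)
    act <- rnorm(s)
    labs <- factor(sample(rep(c("A", "B"), length.out = s)))
    ours <- discrimination_score(act, labs)
    oracle <- mi_entropy_oracle(discretize_activity(act), labs)
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("the score is bounded, symmetric and affine-invariant", {
  set.seed(3)
  for (i in 1:50) {
    s <- sample(c(8, 16, 24), 1)
    act <- rnorm(s)
    labs <- factor(sample(rep(c("A", "B"), length.out = s)))
    ds <- discrimination_score(act, labs)
    bins <- discretize_activity(act)
    hx <- mi_entropy_oracle(bins, bins) # H(X)
    hy <- mi_entropy_oracle(as.integer(labs), as.integer(labs)) # H(Y)
    expect_gte(ds, 0)
    expect_lte(ds, min(hx, hy) + 1e-12)
    # positive affine transform leaves the equal-width binning pattern alone
    expect_equal(discrimination_score(3.7 * act + 11, labs), ds,
                 tolerance = 1e-12)
  }
})

test_that("growth stays home when the seed already separates the classes", {
  # 4-node star; seed z-row separates balanced labels perfectly, leaves are
  # pure noise
  g <- graph_lit("seed", "n1", "seed", "n2", "seed", "n3")
  set.seed(2)
  m <- rbind(seed = c(-2, -1.5, -1, 1, 1.5, 2),
             n1 = rnorm(6), n2 = rnorm(6), n3 = rnorm(6))
  colnames(m) <- paste0("s", 1:6)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 3), colnames(m)), "L")
  z <- zscore_normalize(ds)
  sn <- grow_subnetwork("seed", g, z)
  expect_identical(sn$members, "seed")
  expect_equal(sn$ds, 1.0)
})

test_that("growth respects the distance-2 rule and candidate admissibility", {
  # path seed - a - b - c: c is at distance 3 and must never join, even
  # when it carries all the signal
  g <- graph_lit("seed", "a", "a", "b", "b", "c")
  sep <- c(-2, -1.8, -1.2, 1.2, 1.8, 2)
  set.seed(4)
  m <- rbind(seed = sep + rnorm(6, 0, 2), a = rnorm(6), b = rnorm(6), c = sep)
  colnames(m) <- paste0("s", 1:6)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 3), colnames(m)), "L")
  z <- zscore_normalize(ds)
  sn <- grow_subnetwork("seed", g, z)
  expect_false("c" %in% sn$members)
  expect_true(all(igraph::distances(g, v = "seed")[1, sn$members] <= 2))
  expect_error(grow_subnetwork("zzz", g, z), "not in graph")
})

test_that("accepted greedy steps each improve DS by at least 10%", {
  fx <- planted_subnet_fixture(rng_seed = 1)
  z <- zscore_normalize(fx$dataset)
  sn <- grow_subnetwork(fx$truth$seed_gene, fx$graph, z)
  if (nrow(sn$trace) > 1) {
    ds_seq <- sn$trace$ds
    gains <- diff(ds_seq) / head(ds_seq, -1)
    expect_true(all(gains >= 0.1 - 1e-12))
  }
  expect_equal(sn$ds, sn$trace$ds[nrow(sn$trace)])
})

test_that("permutation p-values are valid and hit the add-one floor", {
  fx <- planted_subnet_fixture(rng_seed = 42)
  z <- zscore_normalize(fx$dataset)
  sn <- grow_subnetwork(fx$truth$seed_gene, fx$graph, z)
  sn <- subnetwork_significance(sn, z, reps = 200, rng_seed = 9)
  p <- sn$p_values
  expect_true(all(p >= 1 / 201 & p <= 1))
  expect_error(subnetwork_significance(sn, z, reps = 0), "reps")

  # strongly planted signal should sit at or near the floor for the label
  # permutation null
  expect_lt(p[["p_label_perm"]], 0.05)
})

test_that("identical member sets from different seeds collapse to one record", {
  # two connected signal genes; both seeds grow to the same pair
  g <- graph_lit("x", "y", "y", "n1", "x", "n2")
  set.seed(6)
  sep <- rep(c(0, 2.4), each = 20)
  m <- rbind(x = sep + rnorm(40, 0, 2), y = sep + rnorm(40, 0, 2),
             n1 = rnorm(40), n2 = rnorm(40))
  colnames(m) <- paste0("s", 1:40)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 20), colnames(m)), "L")
  z <- zscore_normalize(ds)
  res <- discover_subnetworks(z, g, seeds = c("x", "y"), ds_min = 0,
                              p_max = 1, reps = 100, rng_seed = 1)
  keys <- vapply(res$members, function(mm) paste(sort(mm), collapse = ";"),
                 character(1))
  expect_false(any(duplicated(keys)))
  both <- which(vapply(res$members, function(mm)
    setequal(mm, c("x", "y")), logical(1)))
  expect_length(both, 1)
  expect_setequal(res$seed[[both]], c("x", "y"))
})

test_that("cross-dataset overlap intersects member and seed sets", {
  A <- tibble::tibble(seed = list("s1", "s2"),
                      members = list(c("x", "y", "z"), c("q")))
  B <- tibble::tibble(seed = list("s2"), members = list(c("y", "z", "w")))
  ov <- cross_dataset_overlap(A, B)
  expect_setequal(ov$shared_members, c("y", "z"))
  expect_identical(ov$shared_seeds, "s2")
  empty <- cross_dataset_overlap(A, tibble::tibble(seed = list(), members = list()))
  expect_length(empty$shared_members, 0)
})
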