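test_that("zscore_normalize centers, scales, drops constants, is idempotent", {
  m4 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(5, 5, 5, 5), g3 = c(10, 0, 5, 2))
  colnames(m4) <- paste0("s", 1:4)
  ds <- expr_dataset(m4, setNames(c("L", "L", "H", "H"), colnames(m4)), "L")
  z <- zscore_normalize(ds)
  expect_false("g2" %in% rownames(z$values))
  expect_identical(attr(z, "n_dropped"), 1L)
  expect_equal(unname(rowMeans(z$values)), rep(0, 2), tolerance = 1e-10)
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 2), tolerance = 1e-10)
  # sample-sd convention: [1,2,3,4] -> centered / sd(1:4)
  expect_equal(unname(z$values["g1", ]), (1:4 - 2.5) / sd(1:4),
               tolerance = 1e-10)
  z2 <- zscore_normalize(z)
  expect_equal(z2$values, z$values, tolerance = 1e-10)
})

test_that("fold-change rankings report case-minus-reference log differences", {
  m <- rbind(gA = c(1, 2, 10, 2, 4, 20), gB = c(5, 6, 7, 5, 6, 7))
  colnames(m) <- paste0("s", 1:6)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 3), colnames(m)), "L")
  rk <- rank_genes(ds, "median_fc")
  expect_equal(rk$statistic[rk$gene == "gA"], 2) # median 4 - median 2
  expect_equal(rk$direction[rk$gene == "gA"], "up")
  expect_equal(rk$gene[1], "gA") # |2| > |0|
  rk2 <- rank_genes(ds, "mean_fc")
  expect_equal(rk2$statistic[rk2$gene == "gA"],
               mean(c(2, 4, 20)) - mean(c(1, 2, 10)))
})

test_that("wilcoxon p-values match exhaustive enumeration for small groups", {
  set.seed(5)
  for (i in 1:20) {
    nr <- sample(3:5, 1); nc <- sample(3:5, 1)
    ref <- rnorm(nr); case <- rnorm(nc) + 0.8 # continuous, so tie-free
    m <- matrix(c(ref, case), 1,
                dimnames = list("g", paste0("s", seq_len(nr + nc))))
    m <- rbind(m, filler = rnorm(nr + nc))
    ds <- expr_dataset(m, setNames(rep(c("L", "H"), c(nr, nc)), colnames(m)), "L")
    rk <- rank_genes(ds, "wilcoxon")
    expect_equal(rk$p[rk$gene == "g"], wilcoxon_exact_oracle(ref, case),
                 tolerance = 1e-12)
  }
  # the canonical worked case
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("g", paste0("s", 1:6)))
  m <- rbind(m, filler = c(0, 1, 0, 1, 0, 1))
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 3), colnames(m)), "L")
  expect_equal(rank_genes(ds, "wilcoxon")$p[1], 0.1, tolerance = 1e-12)
})

test_that("t-test on identically distributed groups is non-significant", {
  m <- rbind(g1 = c(1, 2, 3, 1.001, 2.001, 2.998), g2 = rnorm(6))
  colnames(m) <- paste0("s", 1:6)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 3), colnames(m)), "L")
  rk <- rank_genes(ds, "ttest")
  expect_gt(rk$p[rk$gene == "g1"], 0.99)
})

test_that("rankings are invariant to sample order within groups", {
  ds <- noise_ds(30, 5, seed = 2)
  perm <- c(sample(1:5), sample(6:10))
  dsp <- expr_dataset(ds$values[, perm], ds$labels[perm], ref_level = "LMP")
  for (meth in c("mean_fc", "median_fc", "ttest", "wilcoxon")) {
    a <- rank_genes(ds, meth)
    b <- rank_genes(dsp, meth)
    expect_identical(a$gene, b$gene)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  }
})

test_that("reproducibility_rate obeys identity, disjointness and symmetry", {
  ds <- noise_ds(40, 4, seed = 3)
  a <- rank_genes(ds, "wilcoxon")
  for (k in c(1, 5, 20)) expect_equal(reproducibility_rate(a, a, k), 1)
  dsB <- noise_ds(40, 4, seed = 4, gene_prefix = "h")
  b <- rank_genes(dsB, "wilcoxon")
  expect_equal(reproducibility_rate(a, b, 10), 0)
  dsC <- noise_ds(40, 4, seed = 5)
  cc <- rank_genes(dsC, "wilcoxon")
  expect_equal(reproducibility_rate(a, cc, 7), reproducibility_rate(cc, a, 7))
  expect_error(reproducibility_rate(a, cc, 0), "positive")
})

test_that("random baseline matches the hypergeometric expectation", {
  base <- random_baseline(100, 10, reps = 1000, rng_seed = 1)
  se <- sd(base$null) / sqrt(1000)
  expect_lt(abs(base$mean - 0.1), 3 * se)
  expect_equal(random_baseline(100, 10, reps = 500, rng_seed = 1,
                               observed = 1.0)$p, 1 / 501)
  expect_equal(random_baseline(100, 10, reps = 500, rng_seed = 1,
                               observed = 0)$p, 1)
})

test_that("concordant genes need both thresholds and matching directions", {
  mk <- function(p, fc) {
    list(w = structure(tibble::tibble(gene = c("a", "b", "c"), statistic = 1,
                                      p = p, direction = "up",
                                      rank = 1:3),
                       class = c("ranked_genes", class(tibble::tibble()))),
         f = structure(tibble::tibble(gene = c("a", "b", "c"), statistic = fc,
                                      p = NA_real_,
                                      direction = ifelse(fc > 0, "up", "down"),
                                      rank = 1:3),
                       class = c("ranked_genes", class(tibble::tibble()))))
  }
  A <- mk(p = c(0.001, 0.001, 0.5), fc = c(1.2, 1.5, 2))
  B <- mk(p = c(0.002, 0.001, 0.001), fc = c(1.1, -1.4, 2))
  res <- select_concordant(A$w, A$f, B$w, B$f,
                           p_max_a = 0.01, fc_min_a = 0.6, fc_scale_a = "log2",
                           p_max_b = 0.01, fc_min_b = 1.5, fc_scale_b = "linear")
  # a: passes everywhere, same direction -> in; b: direction flips -> out;
  # c: fails p in A -> out
  expect_identical(res$gene, "a")
  expect_identical(res$direction, "up")
  expect_identical(attr(res, "n_up"), 1L)
  expect_identical(attr(res, "n_down"), 0L)
})

test_that("cluster homogeneity separates separable data and not noise", {
  set.seed(1)
  m <- rbind(sig = c(rep(0, 10), rep(5, 10)),
             n1 = rnorm(20), n2 = rnorm(20), n3 = rnorm(20))
  colnames(m) <- paste0("s", 1:20)
  ds <- expr_dataset(m, setNames(rep(c("L", "H"), each = 10), colnames(m)), "L")
  # one signature gene with disjoint group ranges separates the samples
  ch <- cluster_homogeneity(ds, "sig", n_clusters = 2)
  expect_equal(ch$overall, 1)

  # single cluster reduces to the majority-class fraction
  ch1 <- cluster_homogeneity(ds, "sig", n_clusters = 1)
  expect_equal(ch1$overall, 0.5)

  # permuted labels: homogeneity hovers near chance even though the
  # clustering itself still splits on the bimodal gene
  set.seed(7)
  hs <- replicate(100, {
    perm <- sample(20)
    dsp <- expr_dataset(m, setNames(rep(c("L", "H"), each = 10)[perm],
                                    colnames(m)), "L")
    cluster_homogeneity(dsp, c("sig", "n1", "n2", "n3"),
                        n_clusters = 2)$overall
  })
  expect_lt(mean(hs), 0.85)

  expect_error(cluster_homogeneity(ds, character(0)), "empty")
  expect_error(cluster_homogeneity(ds, "nope"), "not measured")
})
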