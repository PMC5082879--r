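test_that("expression TSV round-trips through write and read", {
  ds <- make_ds(matrix(round(rnorm(12), 6), 3, 4))
  ef <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, ef, lf)
  back <- read_expression(ef, lf, ref_level = "LMP")
  expect_equal(dim(back), c(3L, 4L))
  expect_equal(back$values, ds$values, tolerance = 1e-9)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_identical(attr(back, "n_dropped"), 0L)
})

test_that("duplicate symbols collapse per policy and bad rows are dropped", {
  ef <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "A\t1\t2\t3\t4",
               "A\t3\t4\t5\t6",
               "B\t0\t0\t1\t1",
               "C\tNA\t1\t2\t3"), ef)
  writeLines(c("s1\tL", "s2\tL", "s3\tH", "s4\tH"), lf)
  ds <- read_expression(ef, lf, dup_policy = "median", ref_level = "L")
  expect_setequal(rownames(ds$values), c("A", "B"))
  expect_equal(unname(ds$values["A", ]), c(2, 3, 4, 5)) # per-sample median
  expect_identical(attr(ds, "n_dropped"), 1L)
  expect_identical(attr(ds, "n_duplicate_symbols"), 1L)

  ds2 <- read_expression(ef, lf, dup_policy = "drop", ref_level = "L")
  expect_setequal(rownames(ds2$values), "B")
})

test_that("label problems are reported by name", {
  ef <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "A\t1\t2\t3\t4", "B\t0\t1\t0\t1"), ef)
  writeLines(c("s1\tL", "s2\tL", "s3\tH", "s9\tH"), lf)
  expect_error(read_expression(ef, lf), "s9")
  writeLines(c("s1\tL", "s2\tM", "s3\tH", "s4\tH"), lf)
  expect_error(read_expression(ef, lf), "two phenotype levels")
})

test_that("merge_ppi deduplicates orientations and drops self-loops", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tB", "B\tC"), f1)
  writeLines(c("B pp A", "C pp C"), f2)
  g <- merge_ppi(c(f1, f2))
  expect_equal(igraph::ecount(g), 2)
  el <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(el, c("A-B", "B-C"))
})

test_that("merge_ppi union is idempotent and file-order invariant", {
  fs <- c(withr::local_tempfile(fileext = ".tsv"),
          withr::local_tempfile(fileext = ".tsv"),
          withr::local_tempfile(fileext = ".tsv"))
  for (f in fs) writeLines("A\tB", f)
  g <- merge_ppi(fs)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)

  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C\tD"), fa)
  writeLines(c("D\tC", "B\tE"), fb)
  key <- function(g) sort(apply(igraph::as_edgelist(g), 1,
                                function(e) paste(sort(e), collapse = "-")))
  expect_identical(key(merge_ppi(c(fa, fb))), key(merge_ppi(c(fb, fa))))
})

test_that("merge_ppi reports malformed lines with their number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "oops"), f)
  expect_error(merge_ppi(f), "line 2")
})

test_that("intersect_universe restricts, induces, and is idempotent", {
  dsA <- make_ds(matrix(rnorm(16), 4, 4,
                        dimnames = list(c("A", "B", "C", "X"), NULL)))
  dsB <- make_ds(matrix(rnorm(16), 4, 4,
                        dimnames = list(c("B", "C", "D", "X"), NULL)))
  g <- graph_lit("A", "B", "C", "D")
  out <- intersect_universe(dsA, dsB, g)
  expect_setequal(out$genes, c("B", "C", "X"))
  expect_setequal(rownames(out$dsA$values), c("B", "C", "X"))
  # induced graph: B-? A not measured in both, so only isolated B, C remain
  expect_setequal(igraph::V(out$graph)$name, c("B", "C"))
  expect_equal(igraph::ecount(out$graph), 0)

  again <- intersect_universe(out$dsA, out$dsB, out$graph)
  expect_identical(again$dsA$values, out$dsA$values)
  expect_identical(again$genes, out$genes)

  dsE <- make_ds(matrix(rnorm(8), 2, 4, dimnames = list(c("Q", "R"), NULL)))
  expect_error(intersect_universe(dsA, dsE), "no genes")
})

test_that("isolated measured nodes survive graph induction", {
  dsA <- make_ds(matrix(rnorm(12), 3, 4,
                        dimnames = list(c("A", "B", "C"), NULL)))
  g <- graph_lit("A", "B", "C", "D")
  out <- intersect_universe(dsA, dsA, g)
  expect_setequal(igraph::V(out$graph)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(out$graph), 1) # only A-B survives
  expect_equal(igraph::degree(out$graph)[["C"]], 0)
})

test_that("GMT files round-trip", {
  sets <- list(cycle = c("A", "B", "C"), repair = c("B", "D"))
  attr(sets, "description") <- c(cycle = "cell cycle", repair = "DNA repair")
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(back[], sets[])
  expect_identical(attr(back, "description"), attr(sets, "description"))
  writeLines("onefield", f)
  expect_error(read_gmt(f), "line 1")
})
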