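test_that("tanimoto matches its set definition and handles edge cases", {
  a <- fingerprint(c(1, 2, 3), 16)
  b <- fingerprint(c(2, 3, 4), 16)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, fingerprint(c(5, 6), 16)), 0)
  expect_error(tanimoto(a, fingerprint(1, 32)), "lengths differ")
  empty <- fingerprint(integer(), 16)
  expect_warning(tc <- tanimoto(empty, empty), "empty")
  expect_equal(tc, 0)
})

test_that("tanimoto is symmetric, bounded, and 1 on the diagonal", {
  set.seed(42)
  for (i in 1:50) {
    a <- rand_fp()
    b <- rand_fp()
    tc <- tanimoto(a, b)
    expect_equal(tc, tanimoto(b, a))
    expect_gte(tc, 0)
    expect_lte(tc, 1)
    if (n_set(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("tanimoto_matrix agrees with scalar tanimoto", {
  set.seed(7)
  fa <- setNames(replicate(8, rand_fp(), simplify = FALSE), letters[1:8])
  fb <- setNames(replicate(5, rand_fp(), simplify = FALSE), LETTERS[1:5])
  m <- tanimoto_matrix(fa, fb)
  for (i in seq_along(fa)) for (j in seq_along(fb))
    expect_equal(m[i, j], tanimoto(fa[[i]], fb[[j]]))
})

test_that("SMILES libraries parse with per-record validation", {
  path <- write_smi(c("CCO", "c1ccccc1", "C1CC", "CC(=O)O"),
                    c("ethanol", "benzene", "broken", "acetic"))
  expect_message(mols <- parse_library(path), "1 invalid record")
  expect_equal(nrow(mols), 3L)
  expect_equal(attr(mols, "n_rejected"), 1L)
  expect_setequal(mols$id, c("ethanol", "benzene", "acetic"))

  empty <- tempfile(fileext = ".smi")
  writeLines(character(), empty)
  expect_error(parse_library(empty), "no records")
  expect_error(parse_library(tempfile(fileext = ".smi")), "cannot read")
})

test_that("structure fingerprints are deterministic and SMILES-form invariant", {
  fp1 <- fingerprint_molecules(c(x = "OC(=O)C"))[[1]]
  fp2 <- fingerprint_molecules(c(x = "CC(=O)O"))[[1]]  # same molecule, rewritten
  fp3 <- fingerprint_molecules(c(x = "OC(=O)C"))[[1]]
  expect_identical(fp1, fp3)
  expect_identical(fp1$bits, fp2$bits)
  expect_equal(fp1$nbits, 1024L)
  # near-degenerate molecule fingerprints without error
  tiny <- fingerprint_molecules(c(m = "CO"))[[1]]
  expect_lt(n_set(tiny), 10)
})

test_that("single-linkage clustering matches the union-find oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    fps <- setNames(replicate(n, rand_fp(32, 0.3), simplify = FALSE),
                    sprintf("m%02d", seq_len(n)))
    cutoff <- runif(1, 0.2, 0.8)
    got <- cluster_by_tc(fps, cutoff)
    want <- oracle_cluster(fps, cutoff)
    # same partition up to label renaming
    expect_equal(got$n_clusters, length(unique(want)))
    expect_true(all(tapply(want, got$labels, function(v) length(unique(v))) == 1))
  }
})

test_that("clustering honors transitivity of single linkage", {
  # chain: TC(a,b), TC(b,c) above cutoff, TC(a,c) below -> one cluster
  a <- fingerprint(1:10, 64)
  b <- fingerprint(3:12, 64)    # TC(a,b) = 8/12
  c_ <- fingerprint(5:14, 64)   # TC(b,c) = 8/12, TC(a,c) = 6/14
  cl <- cluster_by_tc(list(a = a, b = b, c = c_, d = fingerprint(40:50, 64)),
                      cutoff = 0.6)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(unname(cl$labels[c("a", "b", "c")]), rep(cl$labels[["a"]], 3))
  expect_false(cl$labels[["a"]] == cl$labels[["d"]])
})

test_that("clustering limits: tiny cutoff joins all, cutoff > 1 isolates all", {
  set.seed(3)
  fps <- setNames(replicate(6, rand_fp(32, 0.5), simplify = FALSE), letters[1:6])
  expect_equal(cluster_by_tc(fps, 1e-9)$n_clusters, 1L)
  expect_equal(cluster_by_tc(fps, 1.000001)$n_clusters, 6L)
  expect_equal(cluster_by_tc(fps["a"], 0.7)$n_clusters, 1L)
})

test_that("aggregator flagging is inclusive at the cutoff and safe when empty", {
  q <- fingerprint(1:10, 64)
  aggs <- list(agg1 = fingerprint(1:9, 64),      # TC 0.9 exactly (9/10)
               agg2 = fingerprint(40:45, 64))
  hit <- is_aggregator_like(q, aggs, cutoff = 0.9)
  expect_true(hit$flag)
  expect_equal(hit$best_tc, 0.9)
  expect_equal(hit$best_id, "agg1")
  miss <- is_aggregator_like(fingerprint(20:30, 64), aggs, cutoff = 0.9)
  expect_false(miss$flag)
  none <- is_aggregator_like(q, list(), cutoff = 0.9)
  expect_false(none$flag)
  expect_true(is.na(none$best_tc))
})
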