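test_that("embedded BLOSUM62 agrees with the Biostrings reference", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- rownames(blosum62())[1:20]
  expect_equal(unname(blosum62()[aa, aa]), unname(BLOSUM62[aa, aa]))
})

test_that("sp_score sums substitution scores over aligned pairs", {
  aln <- residue_alignment(1:2, c("A", "R"), 1:2, c("A", "K"))
  expect_equal(sp_score(aln), 6)  # 4 + 2
  expect_equal(sp_score(residue_alignment(1, "W", 1, "W")), 11)
  empty <- residue_alignment(integer(), character(), integer(), character())
  expect_equal(sp_score(empty), 0L)
  bad <- residue_alignment(1:2, c("A", "B"), 1:2, c("A", "A"))
  expect_error(sp_score(bad), "row\\(s\\) 2")
})

test_that("sp_score is additive over concatenated alignments", {
  set.seed(5)
  aa <- rownames(blosum62())[1:20]
  for (i in 1:10) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    a1 <- residue_alignment(1:n1, sample(aa, n1, TRUE), 1:n1, sample(aa, n1, TRUE))
    a2 <- residue_alignment(n1 + (1:n2), sample(aa, n2, TRUE),
                            n1 + (1:n2), sample(aa, n2, TRUE))
    cat_aln <- residue_alignment(c(a1$target_pos, a2$target_pos),
                                 c(a1$target_aa, a2$target_aa),
                                 c(a1$template_pos, a2$template_pos),
                                 c(a1$template_aa, a2$template_aa))
    expect_equal(sp_score(cat_aln), sp_score(a1) + sp_score(a2))
  }
})

test_that("sequence identity counts identical aligned pairs", {
  aln <- residue_alignment(1:3, c("A", "R", "N"), 1:3, c("A", "K", "N"))
  expect_equal(sequence_identity(aln), 2 / 3)
  all_id <- residue_alignment(1:4, rep("G", 4), 1:4, rep("G", 4))
  expect_equal(sequence_identity(all_id), 1)
  none <- residue_alignment(1:2, c("A", "R"), 1:2, c("G", "K"))
  expect_equal(sequence_identity(none), 0)
  empty <- residue_alignment(integer(), character(), integer(), character())
  expect_error(sequence_identity(empty), "empty")
})

test_that("homology filter excludes strictly above the cutoff and is idempotent", {
  mk <- function(id, sid) {
    n <- 10L
    aln <- residue_alignment(1:n, rep("A", n), 1:n,
                             c(rep("A", round(sid * n)),
                               rep("G", n - round(sid * n))))
    holo_template(id, aln, "lig1")
  }
  ts <- list(mk("t35", 0.35), mk("t30", 0.30), mk("t10", 0.10))
  f <- filter_homologs(ts, 0.30)
  expect_equal(vapply(f$retained, `[[`, character(1), "id"), c("t30", "t10"))
  expect_equal(vapply(f$excluded, `[[`, character(1), "id"), "t35")
  again <- filter_homologs(f$retained, 0.30)
  expect_equal(length(again$retained), 2L)
  expect_equal(length(again$excluded), 0L)
  empty <- filter_homologs(list(), 0.30)
  expect_equal(length(empty$retained), 0L)
})

test_that("template ranking sorts by score with deterministic tie-break", {
  set.seed(9)
  ts <- simulate_templates(30, seed = 4)
  ranked <- rank_templates(ts)
  scores <- vapply(ranked, `[[`, numeric(1), "sp_score")
  expect_false(any(is.na(scores)))
  expect_true(all(diff(scores) <= 0))
  expect_setequal(vapply(ranked, `[[`, character(1), "id"),
                  vapply(ts, `[[`, character(1), "id"))
  # brute-force comparison sort oracle
  want <- vapply(ts, function(t) sp_score(t$alignment), numeric(1))
  ids <- vapply(ts, `[[`, character(1), "id")
  ord <- order(-want, ids)
  expect_equal(vapply(ranked, `[[`, character(1), "id"), ids[ord])
  # ties break by id
  aln <- residue_alignment(1, "A", 1, "A")
  tie <- rank_templates(list(holo_template("zz", aln, "l1"),
                             holo_template("aa", aln, "l2")))
  expect_equal(vapply(tie, `[[`, character(1), "id"), c("aa", "zz"))
})

test_that("template-ligand harvest keeps top-n ligands deduplicated in order", {
  aln <- residue_alignment(1, "A", 1, "A")
  ts <- list(holo_template("t1", aln, c("ligA", "ligB")),
             holo_template("t2", aln, c("ligB", "ligC")),
             holo_template("t3", aln, "ligD"))
  expect_equal(harvest_template_ligands(ts, n_top = 2),
               c("ligA", "ligB", "ligC"))
  expect_equal(harvest_template_ligands(ts, n_top = 100),
               c("ligA", "ligB", "ligC", "ligD"))
})

test_that("alignment files round-trip through the text format", {
  path <- tempfile(fileext = ".aln")
  writeLines(c("#target tgt1 template tmpl7",
               "1\tA\t4\tA", "2\tR\t5\tK", "5\tW\t9\tW"), path)
  aln <- read_alignment(path)
  expect_equal(attr(aln, "target_id"), "tgt1")
  expect_equal(attr(aln, "template_id"), "tmpl7")
  expect_equal(nrow(aln), 3L)
  expect_equal(sp_score(aln), 4 + 2 + 11)
  expect_equal(sequence_identity(aln), 2 / 3)
  writeLines("no header", path)
  expect_error(read_alignment(path), "header")
})
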