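# Genome selection and supermatrix bookkeeping.

test_that("representative score is completeness minus five times contamination", {
  expect_equal(representative_score(100, 0), 100)
  expect_equal(representative_score(90, 4), 70)
  expect_equal(representative_score(50, 10), 0)
  expect_error(representative_score(120, 0), "completeness")
})

make_ani <- function(ids, pairs = list()) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  }
  m
}

test_that("greedy dereplication merges above and splits below the ANI threshold", {
  q <- tibble::tibble(mag_id = c("a", "b"), completeness = c(90, 80),
                      contamination = c(1, 1))
  merged <- greedy_dereplicate(q, make_ani(c("a", "b"), list(list("a", "b", 0.995))))
  expect_equal(dplyr::n_distinct(merged$cluster), 1)
  expect_equal(merged$representative, c("a", "a"))  # higher score leads
  split <- greedy_dereplicate(q, make_ani(c("a", "b"), list(list("a", "b", 0.95))))
  expect_equal(dplyr::n_distinct(split$cluster), 2)
})

test_that("dereplication drops genomes below minimum completeness first", {
  q <- tibble::tibble(mag_id = c("a", "b", "c"),
                      completeness = c(90, 49, 50), contamination = 0)
  res <- greedy_dereplicate(q, make_ani(c("a", "b", "c")))
  expect_false("b" %in% res$mag_id)  # 49 < 50
  expect_true("c" %in% res$mag_id)   # 50 kept (inclusive)
})

test_that("dereplication partitions the retained set with max-score representatives", {
  set.seed(31)
  n <- 12
  ids <- sprintf("m%02d", 1:n)
  q <- tibble::tibble(mag_id = ids, completeness = runif(n, 40, 100),
                      contamination = runif(n, 0, 8))
  m <- matrix(runif(n * n, 0.8, 1), n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  res <- greedy_dereplicate(q, m)
  expect_setequal(res$mag_id, q$mag_id[q$completeness >= 50])
  by_cluster <- split(res, res$cluster)
  for (cl in by_cluster) {
    expect_equal(cl$representative[1], cl$mag_id[which.max(cl$score)])
  }
  # deterministic given the sort order
  expect_identical(res, greedy_dereplicate(q, m))
  bad <- m; bad[1, 2] <- bad[1, 2] + 0.01
  expect_error(greedy_dereplicate(q, bad), "symmetric")
})

test_that("single-copy rule keeps exactly the count == 1 families", {
  counts <- tibble::tibble(genome = "g1", family = c("c1", "c2", "c3"),
                           count = c(1, 2, 0))
  expect_equal(single_copy_markers(counts)$family, "c1")
  all_zero <- tibble::tibble(genome = "g1", family = c("c1", "c2"), count = 0)
  expect_equal(nrow(single_copy_markers(all_zero)), 0)
  all_one <- tibble::tibble(genome = "g1", family = c("c1", "c2"), count = 1)
  expect_equal(nrow(single_copy_markers(all_one)), 2)
})

test_that("gap filter drops strictly above the threshold", {
  at_60 <- paste0(strrep("-", 60), strrep("A", 40))
  at_61 <- paste0(strrep("-", 61), strrep("A", 39))
  expect_true(gap_fraction_filter(at_60))     # 0.60 kept (strict >)
  expect_false(gap_fraction_filter(at_61))    # 0.61 dropped
  expect_true(gap_fraction_filter(strrep("A", 10)))
  expect_error(gap_fraction_filter(""), "zero-length")
})

test_that("supermatrix concatenation gap-fills absent families with a partition map", {
  aln <- list(
    f1 = c(gA = "MKTAY", gB = "MKTA-"),
    f2 = c(gA = "GGG")
  )
  sm <- concatenate_supermatrix(aln)
  expect_equal(unname(nchar(sm$alignment)), c(8, 8))
  expect_equal(sm$alignment[["gB"]], "MKTA----")
  expect_equal(sm$partitions$start, c(0L, 5L))
  expect_equal(sm$partitions$end, c(5L, 8L))
  # three equal families partition as [0,4),[4,8),[8,12)
  aln3 <- list(a = c(g = "AAAA"), b = c(g = "CCCC"), c = c(g = "DDDD"))
  sm3 <- concatenate_supermatrix(aln3)
  expect_equal(sm3$partitions$start, c(0L, 4L, 8L))
  expect_equal(sm3$partitions$end, c(4L, 8L, 12L))
  expect_equal(sum(with(sm3$partitions, end - start)),
               unique(nchar(sm3$alignment)))
  expect_error(concatenate_supermatrix(aln, genomes = c("gA", "gA")),
               "duplicate genome")
  expect_error(concatenate_supermatrix(list(f1 = c(a = "AA", b = "AAA"))),
               "unequal length")
})

test_that("supermatrix round-trips through FASTA with a RAxML partition file", {
  aln <- list(f1 = c(gA = "MKTAY", gB = "MKAAY"), f2 = c(gA = "GG", gB = "GA"))
  sm <- concatenate_supermatrix(aln)
  fa <- tempfile(fileext = ".fasta"); pt <- tempfile(fileext = ".txt")
  write_supermatrix(sm, fa, pt)
  expect_equal(read_fasta(fa), sm$alignment)
  expect_equal(readLines(pt), c("AA, f1 = 1-5", "AA, f2 = 6-7"))
})
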