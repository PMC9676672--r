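test_that("p-distance handles the textbook cases", {
  aln <- alignment(c(a = "ACGT", b = "AGGT"))
  expect_equal(p_distance_matrix(aln)$d["a", "b"], 0.25)

  aln <- alignment(c(a = "AC-T", b = "ACGT"))
  dm <- p_distance_matrix(aln)
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$comparable_sites["a", "b"], 3L)

  aln <- alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_identical(p_distance_matrix(aln)$d["a", "b"], 0)
})

test_that("p-distance matrix equals the per-pair brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- random_sequences(8, 20, alphabet = c("A", "C", "G", "T", "-", "N"))
    aln <- alignment(seqs)
    dm <- suppressWarnings(p_distance_matrix(aln))
    expect_equal(dm$d, brute_p_distance(seqs), tolerance = 1e-14)
  }
})

test_that("generic policy engine agrees with the fast path on defaults", {
  set.seed(7)
  seqs <- random_sequences(6, 30, alphabet = c("A", "C", "G", "T", "-", "R", "N"))
  aln <- alignment(seqs)
  fast <- suppressWarnings(p_distance_matrix(aln))
  slow <- suppressWarnings(
    plectax:::pdist_generic(unclass(aln), "pairwise-exclude", "exclude"))
  d_slow <- slow$mismatch / slow$comparable
  diag(d_slow) <- 0
  expect_equal(fast$d, d_slow, tolerance = 1e-14)
})

test_that("distances satisfy the metric-like invariants", {
  set.seed(1)
  aln <- alignment(random_sequences(10, 50))
  dm <- p_distance_matrix(aln)
  expect_true(all(dm$d >= 0 & dm$d <= 1))
  expect_identical(unname(diag(dm$d)), rep(0, 10))
  expect_equal(dm$d, t(dm$d))

  # permutation invariance: reordering rows permutes the matrix
  perm <- sample(rownames(dm$d))
  dm2 <- p_distance_matrix(alignment(unclass(aln)[perm, ]))
  expect_equal(dm2$d, dm$d[perm, perm])
})

test_that("gap policies coincide on gap-free pairs and nest on others", {
  aln <- alignment(c(a = "ACGTACGT", b = "ACCTACGT", c = "AC--ACGT"))
  ex <- p_distance_matrix(aln, gap_policy = "pairwise-exclude")
  im <- p_distance_matrix(aln, gap_policy = "include-as-mismatch")
  expect_equal(im$d["a", "b"], ex$d["a", "b"])   # no gaps in this pair
  expect_true(im$d["a", "c"] >= ex$d["a", "c"])  # gap sites now mismatches
  expect_equal(im$comparable_sites["a", "c"], 8L)
})

test_that("ambiguity compatible-match scores intersecting codes as matches", {
  aln <- alignment(c(a = "ARGT", b = "AAGT", c = "ATGT"))
  dm <- p_distance_matrix(aln, ambiguity_policy = "compatible-match")
  expect_equal(dm$d["a", "b"], 0)     # R = {A,G} intersects A
  expect_equal(dm$d["a", "c"], 0.25)  # R does not cover T
  ex <- p_distance_matrix(aln, ambiguity_policy = "exclude")
  expect_equal(ex$comparable_sites["a", "b"], 3L)
})

test_that("pairs with zero comparable sites are flagged, not zeroed", {
  aln <- alignment(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_warning(dm <- p_distance_matrix(aln), "no comparable sites")
  expect_true(is.na(dm$d["a", "b"]))
  expect_identical(dm$d["a", "a"], 0)
})

test_that("group distance summary reproduces hand-computable cases", {
  aln <- alignment(c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC",
                     b1 = "GTATGTACGG", b2 = "GTACGTGCGG"))
  dm <- p_distance_matrix(aln)
  part <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gs <- group_distance_summary(dm, part)
  expect_equal(gs$within$mean[gs$within$group == "A"], 0)
  expect_equal(gs$within$max[gs$within$group == "A"], 0)

  # constructed cross-group distances average correctly
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "c"] <- d["c", "a"] <- 0.1
  d["a", "d"] <- d["d", "a"] <- 0.2
  d["b", "c"] <- d["c", "b"] <- 0.1
  d["b", "d"] <- d["d", "b"] <- 0.2
  dm2 <- structure(list(ids = letters[1:4], d = d,
                        comparable_sites = matrix(10L, 4, 4)),
                   class = "p_dist")
  gs2 <- group_distance_summary(dm2, c(a = "X", b = "X", c = "Y", d = "Y"))
  expect_equal(gs2$between$mean, 0.15)
})

test_that("singleton groups have undefined (not zero) within distance", {
  set.seed(3)
  aln <- alignment(random_sequences(5, 40))
  dm <- p_distance_matrix(aln)
  gs <- group_distance_summary(dm, c(s01 = "A", s02 = "A", s03 = "B",
                                     s04 = "B", s05 = "C"))
  wC <- gs$within[gs$within$group == "C", ]
  expect_false(wC$defined)
  expect_true(is.na(wC$mean))
  expect_equal(wC$n_pairs, 0L)
})

test_that("group means agree between pair enumeration and submatrix sums", {
  set.seed(11)
  aln <- alignment(random_sequences(12, 60))
  dm <- p_distance_matrix(aln)
  part <- stats::setNames(rep(c("A", "B", "C"), each = 4), alignment_ids(aln))
  gs <- group_distance_summary(dm, part)
  for (g in c("A", "B", "C")) {
    ids <- names(part)[part == g]
    sub <- dm$d[ids, ids]
    expect_equal(gs$within$mean[gs$within$group == g],
                 sum(sub) / 2 / choose(length(ids), 2), tolerance = 1e-12)
  }
  for (k in seq_len(nrow(gs$between))) {
    i1 <- names(part)[part == gs$between$group1[k]]
    i2 <- names(part)[part == gs$between$group2[k]]
    expect_equal(gs$between$mean[k], sum(dm$d[i1, i2]) / (length(i1) * length(i2)),
                 tolerance = 1e-12)
  }
})

test_that("distance_range finds the extreme group pairs", {
  b <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                  mean = c(0.05, 0.18, 0.12))
  s <- structure(list(within = data.frame(), between = b),
                 class = "group_dist_summary")
  r <- distance_range(s)
  expect_equal(r$min_between, 0.05)
  expect_equal(r$max_between, 0.18)
  expect_equal(r$argmax, c("A", "C"))

  s1 <- structure(list(within = data.frame(),
                       between = b[1, , drop = FALSE]),
                  class = "group_dist_summary")
  r1 <- distance_range(s1)
  expect_equal(r1$argmin, r1$argmax)
  s0 <- structure(list(within = data.frame(), between = b[0, ]),
                  class = "group_dist_summary")
  expect_error(distance_range(s0), class = "plectax_value_error")
})

test_that("unknown partitioned ids raise a key error", {
  aln <- alignment(c(a = "ACGT", b = "ACGA"))
  dm <- p_distance_matrix(aln)
  expect_error(group_distance_summary(dm, c(a = "A", z = "A")),
               class = "plectax_key_error")
})
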