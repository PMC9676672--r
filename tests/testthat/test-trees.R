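test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  expect_equal(length(phy$tip.label), 3L)
  # x_a = (d_ab + d_ac - d_bc)/2 etc.
  lens <- stats::setNames(phy$edge.length[match(1:3, phy$edge[, 2])],
                          phy$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.2, 0.1, 0.3),
               tolerance = 1e-12)
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(99)
  for (rep in 1:20) {
    case <- random_additive_case(sample(6:10, 1))
    phy <- nj_tree(case$d)
    expect_equal(as.numeric(ape::dist.topo(phy, case$tree)), 0)
    # branch lengths are recovered too: path-length matrices agree
    expect_equal(ape::cophenetic.phylo(phy)[rownames(case$d), colnames(case$d)],
                 case$d, tolerance = 1e-8)
  }
})

test_that("degenerate and invalid matrices are handled", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  expect_silent(phy <- nj_tree(d))   # ties resolved deterministically
  expect_equal(sort(phy$tip.label), letters[1:4])
  expect_identical(ape::write.tree(nj_tree(d)), ape::write.tree(phy))

  d[1, 2] <- d[2, 1] <- NA
  expect_error(nj_tree(d), regexp = "undefined distance between 'a' and 'b'",
               class = "plectax_value_error")
  expect_error(nj_tree(d[1:2, 1:2]), class = "plectax_value_error")
})

test_that("negative NJ branch estimates are clamped to zero", {
  # classic non-additive matrix producing a negative internal estimate
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 1,
                9, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.01  # force distortion
  phy <- nj_tree(d)
  expect_true(all(phy$edge.length >= 0))
  expect_true(attr(phy, "clamped") >= 0)
})

test_that("well-separated clusters earn maximal bootstrap support", {
  # two 5-sequence clusters on 200 positions: 1 within-cluster difference,
  # 40 between-cluster differences
  set.seed(5)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  other <- base
  flip <- sample(200, 40)
  other[flip] <- vapply(other[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  mk <- function(founder, i) {
    s <- founder
    pos <- sample(200, 1)
    s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
    paste(s, collapse = "")
  }
  seqs <- c(stats::setNames(vapply(1:5, function(i) mk(base, i), character(1)),
                            paste0("x", 1:5)),
            stats::setNames(vapply(1:5, function(i) mk(other, i), character(1)),
                            paste0("y", 1:5)))
  aln <- alignment(seqs)
  tr <- bootstrap_supports(aln, replicates = 100, seed = 12)
  cc <- clades(tr)
  key <- vapply(cc$tips, function(s) paste(sort(s), collapse = ","),
                character(1))
  sx <- cc$support[key == paste(sort(paste0("x", 1:5)), collapse = ",")]
  sy <- cc$support[key == paste(sort(paste0("y", 1:5)), collapse = ",")]
  expect_true(sx >= 99)
  expect_true(sy >= 99)
})

test_that("bootstrap supports are reproducible and order-invariant", {
  ds <- simulate_dataset(sim_params(K = 3, n_per_group = 3, seed = 21))
  t1 <- bootstrap_supports(ds$coi, replicates = 30, seed = 77)
  t2 <- bootstrap_supports(ds$coi, replicates = 30, seed = 77)
  expect_identical(t1$node.label, t2$node.label)

  # same seed, permuted input rows: same support per bipartition
  perm <- rev(alignment_ids(ds$coi))
  t3 <- bootstrap_supports(alignment(unclass(ds$coi)[perm, ]),
                           replicates = 30, seed = 77)
  sup <- function(tr) {
    cc <- clades(tr)
    key <- vapply(cc$tips, function(s) paste(sort(s), collapse = ","),
                  character(1))
    internal <- lengths(cc$tips) >= 2 & lengths(cc$tips) <= 7
    stats::setNames(cc$support[internal], key[internal])
  }
  s1 <- sup(t1); s3 <- sup(t3)
  shared <- intersect(names(s1), names(s3))
  expect_true(length(shared) >= 4)
  expect_equal(s1[shared], s3[shared])
})

test_that("a single replicate yields only 0 or 100 percent support", {
  ds <- simulate_dataset(sim_params(K = 2, n_per_group = 4, seed = 3))
  tr <- bootstrap_supports(ds$coi, replicates = 1, seed = 9)
  s <- node_supports(tr)
  expect_true(all(s[!is.na(s)] %in% c(0, 100)))
})

test_that("clade enumeration respects rooting and outgroups", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((a,b)99,(c,d)87);", f)
  tr <- read_newick_with_support(f)
  cc <- clades(tr, outgroup = "c")
  key <- vapply(cc$tips, function(s) paste(sort(s), collapse = ","),
                character(1))
  expect_true("a,b" %in% key)
  expect_equal(cc$support[key == "a,b"], 99)
  expect_error(clades(tr, outgroup = "zz"), class = "plectax_key_error")

  # 4-leaf unrooted tree: one internal edge, both sides enumerated
  cc <- clades(tr)
  sizes <- lengths(cc$tips)
  two_sided <- cc[sizes == 2, ]
  key2 <- vapply(two_sided$tips, function(s) paste(sort(s), collapse = ","),
                 character(1))
  expect_setequal(key2, c("a,b", "c,d"))
})

test_that("bipartition support records each edge once", {
  ds <- simulate_dataset(sim_params(K = 2, n_per_group = 3, seed = 13))
  tr <- bootstrap_supports(ds$coi, replicates = 20, seed = 2)
  cc <- clades(tr)
  key <- vapply(cc$tips, function(s) paste(sort(s), collapse = ","),
                character(1))
  expect_false(any(duplicated(key)))
  # a bipartition's two sides carry the same support (single edge record)
  compl <- vapply(cc$tips, function(s)
    paste(sort(setdiff(tr$tip.label, s)), collapse = ","), character(1))
  for (i in seq_along(key)) {
    j <- match(compl[i], key)
    if (!is.na(j)) expect_equal(cc$support[i], cc$support[j])
  }
})
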