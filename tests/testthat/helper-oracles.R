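# Independent oracles used across the test files.  These deliberately
# avoid the package's vectorized code paths: distances by a per-position
# loop, group statistics by naive accumulation, partitions re-validated
# from first principles.

# per-pair, per-position p-distance count; only A/C/G/T vs A/C/G/T
# positions are comparable (mirrors the default pairwise-exclude /
# exclude policies)
brute_p_distance <- function(seqs) {
  ids <- names(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  chars <- strsplit(seqs, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- chars[[i]]; b <- chars[[j]]
    comparable <- 0L; mism <- 0L
    for (k in seq_along(a)) {
      if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
        comparable <- comparable + 1L
        if (a[k] != b[k]) mism <- mism + 1L
      }
    }
    d[i, j] <- if (comparable == 0L) NA_real_ else mism / comparable
  }
  d
}

random_sequences <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("s%02d", seq_len(n)))
}

# random unrooted binary tree with positive edge lengths and its exact
# path-length (additive) distance matrix
random_additive_case <- function(n_tips) {
  phy <- ape::rtree(n_tips, rooted = FALSE,
                    br = function(k) stats::runif(k, 0.05, 1))
  list(tree = phy, d = ape::cophenetic.phylo(phy))
}

# first-principles re-validation of a delimited partition: every group
# must satisfy all enabled criteria when support, within-distance and
# nearest-neighbor separation are recomputed independently
validate_partition <- function(part, tree, dm, criteria) {
  d <- dm$d
  all_ids <- tree$tip.label
  supports <- suppressWarnings(as.numeric(tree$node.label))
  pp <- ape::prop.part(tree)
  groups <- setdiff(unique(part$assignment), unassigned_label())
  for (g in groups) {
    ids <- names(part$assignment)[part$assignment == g]
    if (length(ids) < 2) return(FALSE)
    sub <- d[ids, ids]
    vals <- sub[upper.tri(sub)]
    within <- if (criteria$within_statistic == "max") max(vals) else mean(vals)
    if (within > criteria$max_within) return(FALSE)
    others <- setdiff(all_ids, ids)
    if (criteria$nn_rule && length(others) &&
        !(min(d[ids, others]) > within)) return(FALSE)
    if (max(vals) > 0) {
      # locate the clade (one side of some edge) and check its support
      support <- NA_real_
      if (setequal(ids, all_ids)) support <- 100
      if (length(ids) == length(all_ids) - 1) support <- 100
      for (k in seq_along(pp)[-1]) {
        side <- all_ids[pp[[k]]]
        if (setequal(side, ids) || setequal(setdiff(all_ids, side), ids))
          support <- supports[k]
      }
      if (is.na(support) || support < criteria$min_support) return(FALSE)
    }
  }
  TRUE
}

# coarse labelling induced by identical companion (18S) sequences
ssu_identity_labels <- function(ssu) {
  s <- alignment_strings(ssu)
  stats::setNames(paste0("ssu_class_", as.integer(factor(s))), names(s))
}
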