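# Neighbor-joining trees, column-resampling bootstrap supports, and
# candidate-clade enumeration for haplotype-group delimitation.
#
# Tree construction itself is the standard Saitou-Nei algorithm as
# implemented in ape::nj(); this module owns the policies around it
# (undefined-entry checks, negative-branch clamping, the bootstrap
# resampling loop and support attachment, and bipartition queries).

#' Neighbor-joining tree from a p-distance matrix
#'
#' @param dm a `p_dist` (see [p_distance_matrix()]) or a square numeric
#'   matrix with dimnames.
#' @return an unrooted ape `phylo`.  Negative branch-length estimates
#'   (a known artifact of neighbor joining) are clamped to zero; the
#'   total clamped length is recorded in the `"clamped"` attribute.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "p_dist")) dm$d else dm
  if (is.null(rownames(d))) value_error("distance matrix must have ids")
  if (nrow(d) < 3L) value_error("neighbor joining needs >= 3 sequences")
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    value_error(sprintf(
      "undefined distance between '%s' and '%s'; cannot build tree",
      rownames(d)[min(bad)], colnames(d)[max(bad)]))
  }
  # canonical row order makes the result (including ape's internal
  # tie-breaking on the Q criterion) independent of input sequence order
  ord <- order(rownames(d))
  phy <- ape::nj(d[ord, ord])
  deficit <- -sum(phy$edge.length[phy$edge.length < 0])
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- deficit
  phy
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then for
#' each replicate resamples alignment columns with replacement, recomputes
#' the p-distance matrix and NJ tree, and scores every internal edge of
#' the point tree by the percentage of replicate trees containing the
#' same bipartition.  Replicates in which some pair has no comparable
#' sites are skipped with a warning; supports are percentages of the
#' replicates actually used.
#'
#' @inheritParams p_distance_matrix
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed making the resampling reproducible; the
#'   column-index draws depend only on the alignment length, so supports
#'   are invariant to the input order of the sequences.
#' @return an ape `phylo` whose `node.label` carries percent supports
#'   (root label empty), with attributes `replicates_used` and `skipped`.
#' @export
bootstrap_supports <- function(aln, replicates = 1000L, seed = NULL,
                               gap_policy = c("pairwise-exclude",
                                              "include-as-mismatch"),
                               ambiguity_policy = c("exclude",
                                                    "compatible-match")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (replicates < 1L) value_error("replicates must be >= 1")
  point <- nj_tree(p_distance_matrix(aln, gap_policy, ambiguity_policy))
  L <- alignment_length(aln)
  m <- unclass(aln)

  boot <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      res <- alignment(m[, idx, drop = FALSE])
      dmr <- suppressWarnings(
        p_distance_matrix(res, gap_policy, ambiguity_policy))
      if (anyNA(dmr$d)) return(NULL)
      nj_tree(dmr)
    })
  })
  skipped <- sum(vapply(boot, is.null, logical(1)))
  boot <- boot[!vapply(boot, is.null, logical(1))]
  if (skipped > 0L)
    warning(sprintf("%d bootstrap replicate(s) skipped (undefined pair)",
                    skipped), call. = FALSE)
  if (length(boot) == 0L)
    value_error("all bootstrap replicates had undefined pairs")
  tally <- table(unlist(lapply(boot, bipartition_keys)))
  keys <- bipartition_keys(point)
  counts <- as.integer(tally[keys])
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(boot)
  point$node.label <- format_support(support)
  # the root of the (arbitrarily rooted) phylo representation is not a
  # bipartition; leave it unlabelled
  point$node.label[is.na(keys)] <- ""
  attr(point, "replicates_used") <- length(boot)
  attr(point, "skipped") <- skipped
  point
}

# Canonical keys of the non-trivial bipartitions of an unrooted tree,
# one per internal node in node-number order (NA for the root, whose
# "clade" is the full tip set, and for any node realizing a trivial
# split).  Each edge's tip side is normalized to the side NOT containing
# the lexicographically smallest tip label, making keys independent of
# rooting and of leaf input order.
bipartition_keys <- function(phy) {
  tips <- phy$tip.label
  anchor <- min(tips)
  pp <- ape::prop.part(phy)
  vapply(seq_along(pp), function(k) {
    side <- tips[pp[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L)
      return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
}

#' Candidate clades of a support-labelled tree
#'
#' With an `outgroup`, the tree is rooted on that tip's pendant edge and
#' the rooted clades (tip sets of the internal nodes) are returned.
#' Without one, both sides of every edge are emitted as candidate groups:
#' internal edges carry their bootstrap support, while pendant-edge sides
#' and the full tip set are trivial bipartitions present in every tree
#' and carry support 100.
#'
#' @param tree a `phylo`, typically from [bootstrap_supports()] or
#'   [read_newick_with_support()].
#' @param outgroup a tip id, or `NULL` for unrooted edge-side enumeration.
#' @return a data.frame with list column `tips` and numeric `support`
#'   (`NA` where the tree carries no label for that edge).
#' @export
clades <- function(tree, outgroup = NULL) {
  tips <- tree$tip.label
  n <- length(tips)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tips)
      key_error(sprintf("unknown outgroup id: %s", outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  supports <- node_supports(tree)
  pp <- ape::prop.part(tree)
  sets <- lapply(pp, function(ix) tips[ix])

  if (!is.null(outgroup)) {
    out <- data.frame(support = supports)
    out$tips <- sets
    return(out[, c("tips", "support")])
  }
  # unrooted: each internal node's tip set and its complement share the
  # support of the edge above that node; the root set spans all tips
  cand_tips <- list(tips)
  cand_support <- 100
  # trivial bipartitions (single tip vs rest) are present in every tree
  for (tp in tips) {
    cand_tips <- c(cand_tips, list(tp, setdiff(tips, tp)))
    cand_support <- c(cand_support, 100, 100)
  }
  # each node's own tip set first, complements afterwards, so that when a
  # binary root duplicates a bipartition the label written at a node wins
  # over the one inferred from the other side
  for (k in seq_along(sets)[-1]) {
    cand_tips <- c(cand_tips, list(sets[[k]]))
    cand_support <- c(cand_support, supports[k])
  }
  for (k in seq_along(sets)[-1]) {
    cand_tips <- c(cand_tips, list(setdiff(tips, sets[[k]])))
    cand_support <- c(cand_support, supports[k])
  }
  out <- data.frame(support = cand_support)
  out$tips <- cand_tips
  # drop duplicate tip sets (e.g. complements already enumerated)
  keyf <- vapply(out$tips, function(s) paste(sort(s), collapse = "\r"),
                 character(1))
  out <- out[!duplicated(keyf), c("tips", "support")]
  rownames(out) <- NULL
  out
}
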