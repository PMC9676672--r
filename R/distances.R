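# Pairwise p-distances (uncorrected proportion of differing sites) and
# within/between-group distance summaries.
#
# The default policies mirror pairwise deletion: for each pair of
# sequences, positions where either member carries a gap or an ambiguity
# code are dropped, and the distance is (mismatches) / (comparable sites).

#' Pairwise p-distance matrix
#'
#' @param aln a `plectax_alignment` (see [alignment()]).
#' @param gap_policy `"pairwise-exclude"` drops, per pair, every position
#'   where either sequence has a gap; `"include-as-mismatch"` keeps such
#'   positions, scoring gap-vs-base as a mismatch and gap-vs-gap as a
#'   match (gap treated as a fifth state).
#' @param ambiguity_policy `"exclude"` drops, per pair, every position
#'   where either sequence has an IUPAC ambiguity code;
#'   `"compatible-match"` keeps them, scoring a match whenever the two
#'   codes' base sets intersect.
#' @return an object of class `"p_dist"`: list with `ids`, `d` (square
#'   matrix of distances in `[0, 1]`, exact 0 diagonal, `NA` for pairs
#'   with zero comparable sites) and `comparable_sites` (square integer
#'   matrix).  Pairs with no comparable sites raise a warning.
#' @export
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "AGGT"))
#' p_distance_matrix(aln)$d["a", "b"]  # 0.25
p_distance_matrix <- function(aln,
                              gap_policy = c("pairwise-exclude",
                                             "include-as-mismatch"),
                              ambiguity_policy = c("exclude",
                                                   "compatible-match")) {
  gap_policy <- match.arg(gap_policy)
  ambiguity_policy <- match.arg(ambiguity_policy)
  m <- unclass(aln)
  if (ncol(m) < 1L) alignment_error("alignment length must be >= 1")

  if (gap_policy == "pairwise-exclude" && ambiguity_policy == "exclude") {
    res <- pdist_crossprod(m)
  } else {
    res <- pdist_generic(m, gap_policy, ambiguity_policy)
  }
  d <- res$mismatch / res$comparable
  d[res$comparable == 0L] <- NA_real_
  diag(d) <- 0
  undef <- which(res$comparable == 0L & upper.tri(d), arr.ind = TRUE)
  if (nrow(undef))
    warning(sprintf("%d sequence pair(s) share no comparable sites; %s",
                    nrow(undef), "their distances are undefined (NA)"),
            call. = FALSE)
  diag(res$comparable) <- ncol(m)
  structure(list(ids = rownames(m), d = d,
                 comparable_sites = res$comparable),
            class = "p_dist")
}

# fast path for the default policies: one 0/1 indicator matrix per base,
# matches and comparable-site counts via crossproducts
pdist_crossprod <- function(m) {
  n <- nrow(m)
  valid <- matrix(m %in% c("A", "C", "G", "T"), n, ncol(m))
  comparable <- tcrossprod(valid * 1L)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T"))
    matches <- matches + tcrossprod((m == b) * 1L)
  dimnames(comparable) <- dimnames(matches) <-
    list(rownames(m), rownames(m))
  list(mismatch = comparable - matches,
       comparable = matrix(as.integer(comparable), n, n,
                           dimnames = dimnames(comparable)))
}

# general path: 4-bit base-set mask per residue; a position is a match
# when the masks intersect.  Gap carries an empty mask (never matches a
# base) unless excluded pairwise.
pdist_generic <- function(m, gap_policy, ambiguity_policy) {
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  mask_of <- vapply(IUPAC_SETS, function(s) sum(base_bit[s]), integer(1))
  mask_of <- c(mask_of, "-" = 0L)
  n <- nrow(m); L <- ncol(m)
  masks <- matrix(mask_of[m], n, L)
  is_gap <- m == "-"
  is_amb <- !is_gap & !(m %in% c("A", "C", "G", "T"))
  ids <- rownames(m)
  mism <- comp <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- rep(TRUE, L)
    if (gap_policy == "pairwise-exclude") use <- use & !is_gap[i, ] & !is_gap[j, ]
    if (ambiguity_policy == "exclude")    use <- use & !is_amb[i, ] & !is_amb[j, ]
    nc <- sum(use)
    match_at <- bitwAnd(masks[i, use], masks[j, use]) > 0L |
      (is_gap[i, use] & is_gap[j, use])
    comp[i, j] <- comp[j, i] <- nc
    mism[i, j] <- mism[j, i] <- nc - sum(match_at)
  }
  list(mismatch = mism, comparable = comp)
}

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("p-distance matrix over %d sequences (mean off-diagonal %.4f)\n",
              length(x$ids),
              mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

as_assignment <- function(partition) {
  if (inherits(partition, "group_partition")) partition$assignment
  else if (is.character(partition) && !is.null(names(partition))) partition
  else value_error("partition must be a group_partition or named character vector")
}

#' Within- and between-group distance summary
#'
#' Summarizes a p-distance matrix over a haplotype-group partition, in the
#' layout of a within/between distance table: per group the mean and
#' maximum pairwise distance over all member pairs (undefined, not zero,
#' for singleton groups), and per group pair the mean over all
#' cross-group pairs.  Unassigned specimens are excluded.
#'
#' @param dm a `p_dist`.
#' @param partition a `group_partition` or named character vector mapping
#'   specimen id to group label ([unassigned_label()] for none).
#' @return an object of class `"group_dist_summary"`: list with `within`
#'   (data.frame `group`, `mean`, `max`, `n_pairs`, `defined`) and
#'   `between` (data.frame `group1`, `group2`, `mean`).
#' @export
group_distance_summary <- function(dm, partition) {
  assignment <- as_assignment(partition)
  assignment <- assignment[assignment != unassigned_label()]
  missing <- setdiff(names(assignment), dm$ids)
  if (length(missing))
    key_error(sprintf("partitioned id(s) absent from distance matrix: %s",
                      paste(missing, collapse = ", ")))
  groups <- sort(unique(assignment))
  members <- split(names(assignment), assignment)

  within <- do.call(rbind, lapply(groups, function(g) {
    ids <- members[[g]]
    if (length(ids) < 2L)
      return(data.frame(group = g, mean = NA_real_, max = NA_real_,
                        n_pairs = 0L, defined = FALSE))
    sub <- dm$d[ids, ids]
    vals <- sub[upper.tri(sub)]
    data.frame(group = g, mean = mean(vals), max = max(vals),
               n_pairs = length(vals), defined = TRUE)
  }))

  pairs <- if (length(groups) >= 2L) utils::combn(groups, 2L) else
    matrix(character(0), nrow = 2)
  between <- do.call(rbind, c(list(
    data.frame(group1 = character(0), group2 = character(0),
               mean = numeric(0))),
    lapply(seq_len(ncol(pairs)), function(k) {
      g1 <- pairs[1, k]; g2 <- pairs[2, k]
      vals <- dm$d[members[[g1]], members[[g2]], drop = FALSE]
      data.frame(group1 = g1, group2 = g2, mean = mean(vals))
    })))
  structure(list(within = within, between = between),
            class = "group_dist_summary")
}

#' @export
print.group_dist_summary <- function(x, ...) {
  cat(sprintf("Distance summary: %d groups, %d group pairs\n",
              nrow(x$within), nrow(x$between)))
  w <- x$within
  w$mean <- ifelse(w$defined, formatC(w$mean, format = "f", digits = 4), "n/c")
  w$max <- ifelse(w$defined, formatC(w$max, format = "f", digits = 4), "n/c")
  print(w[, c("group", "mean", "max", "n_pairs")], row.names = FALSE)
  invisible(x)
}

#' Extrema of the between-group mean distances
#'
#' @param summary a `group_dist_summary`.
#' @return list with `min_between`, `max_between` and the group pairs
#'   `argmin`, `argmax` attaining them.
#' @export
distance_range <- function(summary) {
  b <- summary$between
  if (nrow(b) < 1L) value_error("distance_range needs >= 2 groups")
  imin <- which.min(b$mean); imax <- which.max(b$mean)
  list(min_between = b$mean[imin],
       max_between = b$mean[imax],
       argmin = c(b$group1[imin], b$group2[imin]),
       argmax = c(b$group1[imax], b$group2[imax]))
}
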