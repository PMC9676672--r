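# Three-criterion haplotype-group delimitation, cross-marker resolution
# comparison, and OTU-to-reference matching.
#
# A haplotype group is a clade that (i) has bootstrap support at or above
# a floor, (ii) keeps its within-group pairwise distance at or below a
# ceiling, and (iii) is separated: the distance from any member to the
# nearest non-member exceeds the within-group distance.  Among nested
# qualifying clades the most inclusive one is kept; specimens in no
# qualifying clade stay unassigned.

#' Delimitation criteria
#'
#' Defaults implement the rule used to read haplotype groups off a COI
#' tree: bootstrap support >= 99, within-group distance not exceeding 6%,
#' and nearest-neighbor distance greater than the within-group distance.
#' The within-group distance enters the rule as the maximum pairwise
#' distance by default ("did not exceed" reads as a bound on every pair);
#' set `within_statistic = "mean"` for the reporting convention.
#'
#' @param min_support bootstrap floor, percent in `[0, 100]`.
#' @param max_within within-group distance ceiling, fraction in `[0, 1]`.
#' @param nn_rule enforce the nearest-neighbor separation criterion.
#' @param within_statistic `"max"` or `"mean"` pairwise distance.
#' @return a list of class `"delimitation_criteria"`.
#' @export
delimitation_criteria <- function(min_support = 99, max_within = 0.06,
                                  nn_rule = TRUE,
                                  within_statistic = c("max", "mean")) {
  within_statistic <- match.arg(within_statistic)
  if (max_within < 0 || max_within > 1)
    value_error("max_within must lie in [0, 1]")
  if (min_support < 0 || min_support > 100)
    value_error("min_support must lie in [0, 100]")
  structure(list(min_support = min_support, max_within = max_within,
                 nn_rule = nn_rule, within_statistic = within_statistic),
            class = "delimitation_criteria")
}

clade_stats <- function(ids, all_ids, d, within_statistic) {
  sub <- d[ids, ids]
  vals <- sub[upper.tri(sub)]
  within_max <- max(vals)
  within_mean <- mean(vals)
  others <- setdiff(all_ids, ids)
  nn <- if (length(others)) min(d[ids, others]) else Inf
  list(within_max = within_max, within_mean = within_mean,
       within = if (within_statistic == "max") within_max else within_mean,
       nn_distance = nn)
}

#' Delimit haplotype groups on a supported tree
#'
#' Candidate groups are the clades of `tree` (see [clades()]); a
#' candidate of two or more members qualifies when it meets all enabled
#' criteria.  Clades whose members are identical sequences (within
#' distance exactly 0) qualify regardless of support, since zero-length
#' edges carry no meaningful bootstrap signal.  Among nested qualifying
#' clades the most inclusive is kept.  Tips in no qualifying clade are
#' unassigned.  Groups are labelled `group_1`, `group_2`, ... in
#' decreasing size order (ties by first member id).
#'
#' @param tree a `phylo` with bootstrap supports in its node labels.
#' @param dm a `p_dist` covering every tip of `tree`.
#' @param criteria a [delimitation_criteria()].
#' @param outgroup optional tip id passed to [clades()].
#' @return an object of class `"group_partition"`: list with
#'   `assignment` (named character vector, tip id -> group label or
#'   [unassigned_label()]) and `provenance` (data.frame with per-group
#'   `support`, `within_max`, `within_mean`, `nn_distance`, `size`).
#' @export
delimit <- function(tree, dm, criteria = delimitation_criteria(),
                    outgroup = NULL) {
  tips <- tree$tip.label
  missing <- setdiff(tips, dm$ids)
  if (length(missing))
    key_error(sprintf("tree tip(s) absent from distance matrix: %s",
                      paste(missing, collapse = ", ")))
  d <- dm$d
  cand <- clades(tree, outgroup)
  sizes <- lengths(cand$tips)
  cand <- cand[sizes >= 2L, ]

  qualifying <- list()
  for (k in seq_len(nrow(cand))) {
    ids <- cand$tips[[k]]
    st <- clade_stats(ids, tips, d, criteria$within_statistic)
    support_ok <- (!is.na(cand$support[k]) &&
                     cand$support[k] >= criteria$min_support) ||
      st$within_max == 0
    if (!support_ok) next
    if (st$within > criteria$max_within) next
    if (criteria$nn_rule && !(st$nn_distance > st$within)) next
    qualifying[[length(qualifying) + 1L]] <-
      c(list(tips = ids, support = cand$support[k]), st)
  }

  selected <- list()
  if (length(qualifying)) {
    ord <- order(-vapply(qualifying, function(q) length(q$tips), integer(1)))
    for (q in qualifying[ord]) {
      overlap <- vapply(selected, function(s) length(intersect(s$tips, q$tips)),
                        integer(1))
      if (all(overlap == 0L)) {
        selected[[length(selected) + 1L]] <- q
      } else {
        nested <- any(overlap == length(q$tips))
        if (!nested)
          stop("internal error: overlapping non-nested qualifying clades")
        # nested inside an already selected (larger) clade: keep maximal
      }
    }
  }

  # deterministic labels: size desc, then first member id
  if (length(selected)) {
    key <- vapply(selected, function(s) min(s$tips), character(1))
    ord <- order(-vapply(selected, function(s) length(s$tips), integer(1)), key)
    selected <- selected[ord]
  }
  assignment <- stats::setNames(rep(unassigned_label(), length(tips)), tips)
  prov <- data.frame(group = character(0), support = numeric(0),
                     within_max = numeric(0), within_mean = numeric(0),
                     nn_distance = numeric(0), size = integer(0))
  for (i in seq_along(selected)) {
    s <- selected[[i]]
    lab <- sprintf("group_%d", i)
    assignment[s$tips] <- lab
    prov <- rbind(prov, data.frame(
      group = lab, support = s$support, within_max = s$within_max,
      within_mean = s$within_mean, nn_distance = s$nn_distance,
      size = length(s$tips)))
  }
  structure(list(assignment = assignment, provenance = prov),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  n_un <- sum(x$assignment == unassigned_label())
  cat(sprintf("Partition: %d specimens in %d groups (%d unassigned)\n",
              length(x$assignment), nrow(x$provenance), n_un))
  if (nrow(x$provenance)) print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' Compare a fine partition with a coarser labelling
#'
#' Reports how groups of a fine partition (e.g. COI haplotype groups)
#' collapse under a coarser labelling of the same specimens (e.g. classes
#' of identical 18S sequence, or OTU membership).
#'
#' @param fine a `group_partition` or named character vector (specimen id
#'   -> fine group; unassigned specimens are ignored).
#' @param coarse named character vector, specimen id -> coarse label.
#' @return an object of class `"resolution_report"`: list with
#'   `n_fine`, `n_coarse`, `n_collapsed` (fine groups sharing their
#'   coarse label with at least one other fine group) and `collapse`
#'   (named list, coarse label -> fine groups mapped under it).
#' @export
compare_partitions <- function(fine, coarse) {
  fine <- as_assignment(fine)
  fine <- fine[fine != unassigned_label()]
  shared <- intersect(names(fine), names(coarse))
  if (length(shared) == 0L)
    value_error("fine and coarse labellings share no specimen ids")
  fine <- fine[shared]
  coarse <- coarse[shared]
  collapse <- lapply(split(fine, coarse),
                     function(x) sort(unique(unname(x))))
  counts <- table(unlist(collapse))
  collapsed_groups <- names(counts)[vapply(
    names(counts),
    function(g) any(vapply(collapse,
                           function(s) g %in% s && length(s) > 1, logical(1))),
    logical(1))]
  structure(list(n_fine = length(unique(fine)),
                 n_coarse = length(unique(coarse)),
                 n_collapsed = length(collapsed_groups),
                 collapse = collapse),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf(
    "Resolution: %d fine groups under %d coarse labels; %d collapsed\n",
    x$n_fine, x$n_coarse, x$n_collapsed))
  for (lab in names(x$collapse))
    cat(sprintf("  %s <- {%s}\n", lab, paste(x$collapse[[lab]],
                                             collapse = ", ")))
  invisible(x)
}

#' Match OTU sequences to Sanger reference sequences
#'
#' Each OTU is aligned to every reference with a global end-free
#' (overlap) alignment — appropriate when metabarcode amplicons are
#' subfragments of the Sanger region — and percent identity is computed
#' over the aligned overlap (matches / aligned columns, internal gaps
#' counted).  The best-scoring reference is reported when its identity
#' reaches `min_identity`, otherwise the OTU is unmatched.
#'
#' @param otus,refs named character vectors of sequences (or
#'   `plectax_alignment`s; gaps are stripped before alignment).
#' @param min_identity identity threshold as a fraction (default 0.99,
#'   the usual OTU clustering radius).
#' @return data.frame with one row per OTU: `otu`, `ref` (`NA` when no
#'   reference reaches the threshold) and `identity` of the best match.
#' @export
match_otus <- function(otus, refs, min_identity = 0.99) {
  as_strings <- function(x) {
    s <- if (inherits(x, "plectax_alignment")) alignment_strings(x) else x
    gsub("-", "", s, fixed = TRUE)
  }
  otus <- as_strings(otus)
  refs <- as_strings(refs)
  if (length(refs) == 0L) value_error("empty reference set")
  if (length(otus) == 0L) value_error("empty OTU set")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  out <- data.frame(otu = names(otus), ref = NA_character_,
                    identity = NA_real_)
  for (i in seq_along(otus)) {
    best_id <- -Inf; best_ref <- NA_character_
    for (j in seq_along(refs)) {
      pa <- Biostrings::pairwiseAlignment(
        otus[[i]], refs[[j]], type = "overlap",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      aligned_cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
      ident <- Biostrings::nmatch(pa) / aligned_cols
      if (ident > best_id) {
        best_id <- ident
        best_ref <- names(refs)[j]
      }
    }
    out$identity[i] <- best_id
    if (best_id >= min_identity) out$ref[i] <- best_ref
  }
  out
}
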