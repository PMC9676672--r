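# Newick input/output for trees whose internal-node labels are bootstrap
# supports.  Trees are ape "phylo" objects; supports live in node.label
# and are normalized to percent on [0, 100] on read.

#' Read a Newick tree with internal-node support values
#'
#' Internal node labels are interpreted as numeric bootstrap supports and
#' normalized to percent.  With `support_scale = "auto"` the scale is
#' inferred: if every labelled value is <= 1 the labels are taken as
#' fractions and multiplied by 100, otherwise they are already percents.
#' Unlabelled internal nodes (commonly the root) keep an `NA` support.
#'
#' @param path path to a Newick file.
#' @param support_scale `"auto"`, `"percent"` or `"fraction"`.
#' @param strict if `TRUE` (default) a non-numeric, non-empty internal
#'   label is an error; if `FALSE` it becomes an `NA` support.
#' @return an ape `phylo` whose `node.label` holds numeric percent
#'   supports (as characters, `NA`/empty for absent).
#' @export
read_newick_with_support <- function(path,
                                     support_scale = c("auto", "percent",
                                                       "fraction"),
                                     strict = TRUE) {
  support_scale <- match.arg(support_scale)
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) format_error(
                     sprintf("not readable as Newick (%s): %s",
                             conditionMessage(e), path)))
  if (is.null(tree)) format_error(sprintf("no tree in file: %s", path))
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep("", tree$Nnode)
  absent <- is.na(labels) | labels == ""
  support <- suppressWarnings(as.numeric(labels))
  bad <- !absent & is.na(support)
  if (any(bad)) {
    if (strict)
      format_error(sprintf("non-numeric support label(s): %s",
                           paste(unique(labels[bad]), collapse = ", ")))
    support[bad] <- NA_real_
  }
  scale <- switch(support_scale,
                  percent  = "percent",
                  fraction = "fraction",
                  auto = if (any(support > 1, na.rm = TRUE)) "percent"
                         else "fraction")
  if (scale == "fraction") support <- support * 100
  if (any(support < 0 | support > 100, na.rm = TRUE))
    format_error("support values outside [0, 100] after scaling")
  tree$node.label <- ifelse(is.na(support), "", format_support(support))
  tree
}

# supports are printed with up to 3 decimals, trailing zeros trimmed
format_support <- function(x) {
  # %.3f always prints a decimal point, so stripping "(.)0+$" never eats
  # the zeros of an integer part like 100
  sub("\\.?0+$", "", sprintf("%.3f", x))
}

#' Numeric supports of a tree's internal nodes
#'
#' @param tree a `phylo` whose internal-node labels are supports.
#' @return numeric vector of length `tree$Nnode`, `NA` where absent.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s
}

#' Write a tree with percent supports as internal labels
#'
#' @param tree a `phylo` with supports in `node.label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick_with_support <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
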