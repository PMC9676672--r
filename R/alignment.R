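# Alignment container and FASTA input/output.
#
# An alignment is stored as a character matrix with one row per sequence
# (rownames are the sequence ids) and one column per position; residues
# are upper-case IUPAC nucleotide codes or the gap character "-".

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# IUPAC code -> set of compatible bases, used by the compatible-match
# ambiguity policy of p_distance_matrix()
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct an alignment from id/sequence pairs
#'
#' @param seqs named character vector of equal-length sequence strings,
#'   or a character matrix (rows = sequences) with rownames.
#' @param alphabet_policy `"strict"` rejects residues outside the IUPAC
#'   nucleotide alphabet (plus `-`); `"permissive"` maps them to `N` with
#'   a warning.
#' @return an object of class `"plectax_alignment"`: a character matrix of
#'   single residues, rows named by sequence id.
#' @export
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "AC-T"))
#' alignment_length(aln)
alignment <- function(seqs, alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (length(seqs) == 0L) format_error("alignment has no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      alignment_error(sprintf(
        "ragged alignment: sequence lengths %s",
        paste(unique(lens), collapse = ", ")))
    if (lens[1] < 1L) alignment_error("alignment length must be >= 1")
    m <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  ids <- rownames(m)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    format_error("all sequences must carry a non-empty id")
  if (anyDuplicated(ids))
    format_error(sprintf("duplicate sequence ids: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m[] <- toupper(m)
  bad <- !(m %in% IUPAC_CODES)
  if (any(bad)) {
    if (alphabet_policy == "strict")
      format_error(sprintf("non-IUPAC residues in alignment: %s",
                           paste(unique(m[bad]), collapse = ", ")))
    warning(sprintf("%d non-IUPAC residues replaced with N", sum(bad)),
            call. = FALSE)
    m[bad] <- "N"
  }
  structure(m, class = c("plectax_alignment", "matrix", "array"))
}

#' @rdname alignment
#' @param aln an alignment.
#' @export
alignment_length <- function(aln) ncol(aln)

#' @rdname alignment
#' @export
alignment_ids <- function(aln) rownames(aln)

#' Sequences of an alignment as strings
#' @param aln an alignment.
#' @return named character vector of sequence strings.
#' @export
alignment_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' @export
print.plectax_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d positions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' FASTA parsing is delegated to [Biostrings::readBStringSet()]; this
#' function enforces the alignment invariants (equal lengths, unique ids,
#' upper-case IUPAC residues).
#'
#' @param path path to a FASTA file of aligned sequences.
#' @inheritParams alignment
#' @return a `plectax_alignment`.
#' @export
read_alignment <- function(path, alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) format_error(
                   sprintf("not readable as FASTA (%s): %s",
                           conditionMessage(e), path)))
  if (length(ss) == 0L) format_error(sprintf("empty FASTA file: %s", path))
  seqs <- as.character(ss)
  # FASTA description lines: id is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  alignment(seqs, alphabet_policy)
}

#' Write an alignment to FASTA
#'
#' @param aln an alignment.
#' @param path output file path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  seqs <- alignment_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
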