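# Specimen and morphometric table input, plus accessors for the packaged
# transcriptions of the study's collection and measurement tables.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    format_error(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
}

#' Read a specimen collection table
#'
#' Expects a delimited table (tab or comma, auto-detected) with columns
#' `group`, `nid`, `species`, `site`, `location`, `marker`, `accession`.
#' A blank `group` cell or the footnote marker `"a"` denotes a specimen
#' not assigned to any haplotype group and is mapped to
#' [unassigned_label()].  `marker` and `accession` may hold several
#' whitespace-separated values; parsed versions are attached as the list
#' columns `markers` and `accessions`.
#'
#' @param path path to the table.
#' @return a data.frame with one row per specimen.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = detect_delim(path),
                          colClasses = "character", check.names = FALSE)
  require_columns(df, c("group", "nid", "species", "site", "location",
                        "marker", "accession"), path)
  if (anyDuplicated(df$nid))
    format_error(sprintf("%s: duplicate specimen id(s): %s", path,
                         paste(unique(df$nid[duplicated(df$nid)]),
                               collapse = ", ")))
  grp <- trimws(df$group)
  df$group <- ifelse(grp == "" | grp == "a", unassigned_label(), grp)
  df$markers <- I(strsplit(trimws(df$marker), "\\s+"))
  df$accessions <- I(strsplit(trimws(df$accession), "\\s+"))
  df
}

#' Read a morphometric measurement table
#'
#' Expects columns `nid`, `stage` (`F` female / `J` juvenile),
#' `tail_length`, `anal_body_width`, `amphid_width`, `neck_width`
#' (micrometres).  `NA` is permitted only for the amphid and neck fields.
#' Extra columns (e.g. a transcribed printed morphotype label) pass
#' through untouched.
#'
#' @param path path to the table.
#' @return a data.frame with measurement columns as numerics.
#' @export
read_morph_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, sep = detect_delim(path),
                          colClasses = "character", check.names = FALSE)
  require_columns(df, c("nid", "stage", "tail_length", "anal_body_width",
                        "amphid_width", "neck_width"), path)
  if (!all(df$stage %in% c("F", "J")))
    format_error(sprintf("%s: stage must be F or J", path))
  num_cols <- c("tail_length", "anal_body_width", "amphid_width", "neck_width")
  for (cl in num_cols) {
    raw <- trimws(df[[cl]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & !(raw %in% c("NA", "")))
    if (length(bad))
      format_error(sprintf("%s: non-numeric %s in row %d: '%s'",
                           path, cl, bad[1], raw[bad[1]]))
    df[[cl]] <- val
  }
  for (cl in c("tail_length", "anal_body_width")) {
    if (anyNA(df[[cl]]))
      format_error(sprintf("%s: %s may not be NA", path, cl))
    if (any(df[[cl]] <= 0))
      value_error(sprintf("%s: %s must be > 0", path, cl))
  }
  for (cl in c("amphid_width", "neck_width"))
    if (any(!is.na(df[[cl]]) & df[[cl]] <= 0))
      value_error(sprintf("%s: %s must be > 0 when present", path, cl))
  df
}

#' Packaged specimen collection table
#'
#' The study's full specimen table (haplotype group, specimen id, taxon,
#' site, location, sequenced markers, accession numbers), transcribed to
#' TSV and shipped with the package.
#'
#' @return a data.frame, see [read_specimen_table()].
#' @export
plectus_specimens <- function() {
  read_specimen_table(system.file("extdata", "table1_specimens.tsv",
                                  package = "plectax", mustWork = TRUE))
}

#' Packaged morphometric measurement table
#'
#' Voucher-image measurements of the Prairie Corridor specimens (tail
#' length, anal body width, amphid width, neck width, in micrometres),
#' together with the printed morphotype label and the printed derived
#' ratios (`cprime_printed`, `amphid_ratio_printed`) used for
#' cross-checking.
#'
#' @return a data.frame, see [read_morph_table()].
#' @export
plectus_morphometrics <- function() {
  read_morph_table(system.file("extdata", "table2_morphometrics.tsv",
                               package = "plectax", mustWork = TRUE))
}
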