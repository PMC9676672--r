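# Diagnostic morphometric ratios and morphotype classification.
#
# Two ratios separate the observed morphotypes: c' (tail length / anal
# body width; short-tailed < 3, long-tailed > 5) and the amphid aperture
# width relative to neck width (small-amphid forms average 0.14,
# large-amphid forms 0.26).

#' Morphotype classification thresholds
#'
#' @param short_max_cprime c' below this is the short-tailed morphotype.
#' @param long_min_cprime c' above this is the long-tailed morphotype.
#' @return a list of class `"morphotype_thresholds"`.
#' @export
morphotype_thresholds <- function(short_max_cprime = 3.0,
                                  long_min_cprime = 5.0) {
  if (short_max_cprime > long_min_cprime)
    value_error("short_max_cprime must not exceed long_min_cprime")
  structure(list(short_max_cprime = short_max_cprime,
                 long_min_cprime = long_min_cprime),
            class = "morphotype_thresholds")
}

#' Derive diagnostic ratios from a morphometric table
#'
#' Adds `c_prime` (tail length / anal body width) and `amphid_ratio`
#' (amphid width / neck width) columns, plus a `morphotype` call.
#' `rounding = "as-printed"` rounds half-up to the precision of the
#' printed tables (c' to 1 decimal, amphid ratio to 2); `"full"` keeps
#' full precision.  `NA` amphid or neck measurements propagate to an
#' `NA` ratio.
#'
#' @param morph a data.frame as returned by [read_morph_table()].
#' @param rounding `"full"` or `"as-printed"`.
#' @param thresholds a [morphotype_thresholds()].
#' @return `morph` with `c_prime`, `amphid_ratio` and `morphotype`
#'   columns added.
#' @export
derive_ratios <- function(morph, rounding = c("full", "as-printed"),
                          thresholds = morphotype_thresholds()) {
  rounding <- match.arg(rounding)
  if (any(morph$tail_length <= 0, na.rm = TRUE) ||
      any(morph$anal_body_width <= 0, na.rm = TRUE) ||
      anyNA(morph$tail_length) || anyNA(morph$anal_body_width))
    value_error("tail_length and anal_body_width must be positive and present")
  c_prime <- morph$tail_length / morph$anal_body_width
  amphid_ratio <- morph$amphid_width / morph$neck_width
  if (rounding == "as-printed") {
    c_prime <- round_half_up(c_prime, 1)
    amphid_ratio <- round_half_up(amphid_ratio, 2)
  }
  morph$c_prime <- c_prime
  morph$amphid_ratio <- amphid_ratio
  morph$morphotype <- classify_morphotype(c_prime, thresholds)
  morph
}

#' Classify specimens into tail morphotypes by their c' ratio
#'
#' @param c_prime numeric vector of c' ratios.
#' @param thresholds a [morphotype_thresholds()].
#' @return character vector: `"short_tail"` (c' below the short
#'   threshold), `"long_tail"` (above the long threshold),
#'   `"intermediate"` between them, `"undetermined"` when c' is `NA`.
#' @export
classify_morphotype <- function(c_prime,
                                thresholds = morphotype_thresholds()) {
  out <- rep("intermediate", length(c_prime))
  out[c_prime < thresholds$short_max_cprime] <- "short_tail"
  out[c_prime > thresholds$long_min_cprime] <- "long_tail"
  out[is.na(c_prime)] <- "undetermined"
  out
}

#' Per-group summary of measurements and ratios
#'
#' Mean, sample (n-1) standard deviation, range and non-NA count of each
#' measurement and derived ratio, per group — the "mean +/- sd (range)"
#' layout of comparative morphometric tables.  Groups with no records
#' are omitted with a warning.
#'
#' @param records a data.frame from [derive_ratios()].
#' @param group character vector of group labels, parallel to
#'   `records` rows (e.g. haplotype group or morphotype).
#' @param measurements columns to summarize.
#' @return data.frame with columns `group`, `measurement`, `mean`, `sd`,
#'   `min`, `max`, `n`.
#' @export
morph_group_summary <- function(records, group,
                                measurements = c("tail_length",
                                                 "anal_body_width",
                                                 "amphid_width",
                                                 "neck_width",
                                                 "c_prime",
                                                 "amphid_ratio")) {
  stopifnot(length(group) == nrow(records))
  measurements <- intersect(measurements, names(records))
  out <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    rows <- records[group == g, , drop = FALSE]
    do.call(rbind, lapply(measurements, function(cl) {
      x <- rows[[cl]][!is.na(rows[[cl]])]
      if (length(x) == 0L)
        return(data.frame(group = g, measurement = cl, mean = NA_real_,
                          sd = NA_real_, min = NA_real_, max = NA_real_,
                          n = 0L))
      data.frame(group = g, measurement = cl, mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
                 min = min(x), max = max(x), n = length(x))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Discrepancies between printed and recomputed ratios
#'
#' Recomputes the derived ratios at full precision and lists rows where
#' a printed value differs from the recomputed one by more than `tol`
#' (printed tables occasionally disagree with their own inputs; such
#' rows are reported rather than silently failed).
#'
#' @param morph a data.frame with measurement columns plus printed-value
#'   columns `cprime_printed` and/or `amphid_ratio_printed`.
#' @param tol maximum tolerated |printed - recomputed|; the default 0.05
#'   is half an ulp at 1-decimal printing.
#' @return data.frame with one row per discrepant cell: `nid`, `ratio`,
#'   `printed`, `recomputed`.
#' @export
morph_discrepancies <- function(morph, tol = 0.05) {
  rec <- derive_ratios(morph, rounding = "full")
  out <- data.frame(nid = character(0), ratio = character(0),
                    printed = numeric(0), recomputed = numeric(0))
  check <- function(printed_col, ratio_name, recomputed) {
    if (!printed_col %in% names(morph)) return()
    printed <- suppressWarnings(as.numeric(morph[[printed_col]]))
    bad <- which(!is.na(printed) & !is.na(recomputed) &
                   abs(printed - recomputed) > tol + 1e-9)
    if (length(bad))
      out <<- rbind(out, data.frame(nid = morph$nid[bad], ratio = ratio_name,
                                    printed = printed[bad],
                                    recomputed = recomputed[bad]))
  }
  check("cprime_printed", "c_prime", rec$c_prime)
  check("amphid_ratio_printed", "amphid_ratio", rec$amphid_ratio)
  out
}
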