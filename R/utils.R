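# internal helpers shared across modules

#' @keywords internal
#' @noRd
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "plectax_error")))
}

format_error    <- function(msg) abort(msg, "plectax_format_error")
alignment_error <- function(msg) abort(msg, "plectax_alignment_error")
value_error     <- function(msg) abort(msg, "plectax_value_error")
key_error       <- function(msg) abort(msg, "plectax_key_error")

#' Round half away from zero at a fixed number of decimals
#'
#' Base [round()] rounds half to even ("banker's rounding"); printed tables
#' in the taxonomic literature conventionally round half up.  A small
#' relative epsilon absorbs binary floating-point representation error
#' (e.g. `0.245 * 100` evaluating just below `24.5`).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.245, 2.35), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Sentinel label for specimens not assigned to any haplotype group
#'
#' @return the string used throughout the package for unassigned specimens.
#' @export
unassigned_label <- function() "unassigned"

# run an expression with a temporary RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
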