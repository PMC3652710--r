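#' @keywords internal
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards,
# so every simulation operation is a pure function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' the printed ratio tables), unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.4375, 2)  # 0.44
#' round_half_up(0.655, 2)   # 0.66
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

stop_param <- function(...) stop(..., call. = FALSE)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param(sprintf("'%s' must be a single proportion in [0, 1]", name))
  }
  invisible(x)
}
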