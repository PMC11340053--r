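#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used throughout the display
#' layer (base [round()] rounds half to even, which does not reproduce printed
#' survey tables such as a rank-order priority of 73.71 displayed as 74).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(73.71, 0) # 74
#' round_half_up(0.875, 2) # 0.88
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code with a fixed RNG seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

stop_schema <- function(msg) {
  rlang::abort(msg, class = "eb_schema_error")
}

stop_integrity <- function(msg) {
  rlang::abort(msg, class = "eb_integrity_error")
}

stop_domain <- function(msg) {
  rlang::abort(msg, class = "eb_domain_error")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s table is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
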