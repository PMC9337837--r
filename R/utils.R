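`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shortest round-trip decimal formatting
#'
#' Formats doubles with the fewest significant digits that still parse
#' back to the identical binary value, so that written files are
#' byte-stable under rewrite and numerically lossless under re-read.
#'
#' @param x numeric vector.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
fmt_num <- function(x) {
  stopifnot(is.numeric(x))
  out <- character(length(x))
  todo <- is.finite(x)
  out[!todo] <- as.character(x[!todo])
  for (d in 1:17) {
    if (!any(todo)) break
    s <- trimws(formatC(x[todo], digits = d, format = "g", width = 1L))
    ok <- suppressWarnings(as.numeric(s)) == x[todo]
    ok[is.na(ok)] <- FALSE
    ii <- which(todo)
    out[ii[ok]] <- s[ok]
    todo[ii[ok]] <- FALSE
  }
  if (any(todo)) out[todo] <- sprintf("%.17g", x[todo])
  out
}

# Deterministic 31-bit sub-seed from a base seed and an integer salt.
# Keeps derived seeds strictly below 2^31 regardless of the base.
derive_seed <- function(base, salt) {
  v <- (abs(as.numeric(base)) * 131 + abs(as.numeric(salt)) * 7 + 1) %% 2147483629
  as.integer(v) + 1L
}
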