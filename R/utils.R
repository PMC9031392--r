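clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: keeps dim attributes

`%||%` <- function(a, b) if (is.null(a)) b else a

# product of two polynomials given as ascending coefficient vectors
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# evaluate ascending-coefficient polynomial by Horner's rule
polyval_asc <- function(coefs, x) {
  out <- rep(coefs[length(coefs)], length(x))
  for (j in rev(seq_len(length(coefs) - 1L))) out <- out * x + coefs[j]
  out
}

stop_phb <- function(msg, ...) {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  stop(msg, call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
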