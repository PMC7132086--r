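# Round half away from zero. base::round() rounds half to even, which would
# silently change derived iteration counts at .5 ties.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

# Pad a matrix with a constant one-pixel border.
pad1 <- function(m, value = 0) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(value, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  p
}
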