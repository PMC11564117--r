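# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# All stochastic entry points funnel through this so that a scene or a
# pipeline run is a pure function of its config.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == round(x)

# Sample an image at continuous (row, col) positions by bilinear
# interpolation. Pixel (i, j) has its center at coordinate (i, j), 1-based;
# positions outside [1, nrow] x [1, ncol] return NA.
bilinear_sample <- function(image, rows, cols) {
  nr <- nrow(image); nc <- ncol(image)
  out <- rep(NA_real_, length(rows))
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  if (!any(ok)) return(out)
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- image[cbind(r0, c0)]
  v10 <- image[cbind(r0 + 1, c0)]
  v01 <- image[cbind(r0, c0 + 1)]
  v11 <- image[cbind(r0 + 1, c0 + 1)]
  # incremental form: exactly v00 on constant patches, and a global additive
  # offset shifts every sample by exactly that offset
  out[ok] <- v00 + fr * (v10 - v00) + fc * (v01 - v00) +
    fr * fc * (v11 - v10 - v01 + v00)
  out
}
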