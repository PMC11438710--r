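#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.25 -> 0.3 at 1 dp and
#' -0.25 -> -0.3), the convention used throughout printed report tables here.
#' Base [round()] uses round-half-to-even and is not suitable for reproducing
#' table output.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(0.947, 1)   # 0.9
#' roundHalfUp(36.25, 1)   # 36.3
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored as 36.249999... (binary
  # representation of a decimal 36.25) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# fixed-dp text at half-away-from-zero rounding; keeps "-0.0" out of output
formatFixed <- function(x, digits = 1L) {
  r <- roundHalfUp(x, digits)
  r[r == 0] <- 0
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), r))
}

# run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators never consume ambient randomness
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# small deterministic checksum for provenance logging (polynomial hash over
# UTF-8 bytes, modulus below 2^31 so all arithmetic stays exact in doubles)
contentChecksum <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n")) %% 256
  h <- 17
  m <- 2147483629
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
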