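# Minimal unscrambled Sobol low-discrepancy sequence (dimensions <= 3),
# gray-code construction with Joe-Kuo direction numbers.  Only the first
# three dimensions are needed (one per Windkessel parameter), so the
# direction-number table is tiny:
#   dim 1: van der Corput base 2
#   dim 2: polynomial x + 1          (s = 1, a = 0, m = 1)
#   dim 3: polynomial x^2 + x + 1    (s = 2, a = 1, m = 1, 3)

.SOBOL_BITS <- 30L

.sobol_directions <- function(dim) {
  tab <- list(
    list(s = 0L, a = 0L, m = integer(0)),   # dim 1 handled specially
    list(s = 1L, a = 0L, m = c(1L)),
    list(s = 2L, a = 1L, m = c(1L, 3L))
  )
  bits <- .SOBOL_BITS
  V <- matrix(0, nrow = bits, ncol = dim)
  for (d in seq_len(dim)) {
    if (d == 1L) {
      m <- rep(1L, bits)
    } else {
      p <- tab[[d]]
      s <- p$s
      m <- integer(bits)
      m[seq_len(s)] <- p$m
      if (bits > s) {
        a_bits <- as.integer(intToBits(p$a))[seq_len(max(s - 1L, 1L))]
        for (j in (s + 1L):bits) {
          val <- bitwXor(m[j - s], bitwShiftL(m[j - s], s))
          if (s > 1L) {
            for (k in seq_len(s - 1L)) {
              if (a_bits[s - k] == 1L) {
                val <- bitwXor(val, bitwShiftL(m[j - k], k))
              }
            }
          }
          m[j] <- val
        }
      }
    }
    V[, d] <- bitwShiftL(m[seq_len(bits)], bits - seq_len(bits))
  }
  V
}

#' Unscrambled Sobol sequence in the unit hypercube
#'
#' Deterministic low-discrepancy points used to spread the initial genetic
#' algorithm population over the discretised parameter box.  The sequence
#' starts at the origin (index 0); `skip` drops leading points.
#'
#' @param n number of points.
#' @param dim dimension, at most 3.
#' @param skip number of leading points to drop (default 0).
#' @return an `n x dim` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim = 3L, skip = 0L) {
  n <- as.integer(n); dim <- as.integer(dim); skip <- as.integer(skip)
  stopifnot(n >= 1L, dim >= 1L, dim <= 3L, skip >= 0L)
  V <- .sobol_directions(dim)
  total <- n + skip
  pts <- matrix(0, nrow = total, ncol = dim)
  x <- integer(dim)
  for (i in seq_len(total - 1L)) {
    # gray code: flip the direction of the lowest zero bit of i-1
    c_bit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) {
      ii <- bitwShiftR(ii, 1L)
      c_bit <- c_bit + 1L
    }
    x <- bitwXor(x, V[c_bit, ])
    pts[i + 1L, ] <- x
  }
  pts <- pts / 2^.SOBOL_BITS
  pts[(skip + 1L):total, , drop = FALSE]
}
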