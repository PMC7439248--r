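# Exact non-negative big integers as numeric limb vectors, little-endian,
# base 2^24. A limb times a small multiplier (< 2^29) stays below 2^53, so
# all arithmetic is exact in doubles. Used for the ring and distance
# invariants, whose exactness the prime-product encoding depends on; the
# much larger refinement scores are handled by the compiled code in src/.

BIG_BASE <- 2^24

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  limbs
}

big_is_zero <- function(a) length(a) == 1L && a[1L] == 0

big_trim <- function(a) {
  n <- length(a)
  while (n > 1L && a[n] == 0) n <- n - 1L
  a[seq_len(n)]
}

# a * m for small non-negative integer m (< 2^29)
big_mul_small <- function(a, m) {
  stopifnot(m >= 0, m < 2^29)
  if (m == 0 || big_is_zero(a)) return(0)
  carry <- 0
  out <- numeric(length(a) + 2L)
  for (i in seq_along(a)) {
    v <- a[i] * m + carry
    out[i] <- v %% BIG_BASE
    carry <- v %/% BIG_BASE
  }
  i <- length(a)
  while (carry > 0) {
    i <- i + 1L
    if (i > length(out)) out <- c(out, 0)
    out[i] <- carry %% BIG_BASE
    carry <- carry %/% BIG_BASE
  }
  big_trim(out)
}

big_add_small <- function(a, m) {
  stopifnot(m >= 0, m < 2^52)
  carry <- m
  out <- a
  i <- 1L
  while (carry > 0) {
    if (i > length(out)) out <- c(out, 0)
    v <- out[i] + carry %% BIG_BASE
    carry <- carry %/% BIG_BASE
    out[i] <- v %% BIG_BASE
    carry <- carry + v %/% BIG_BASE
    i <- i + 1L
  }
  big_trim(out)
}

# -1, 0, 1 as a <, ==, > b
big_cmp <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

# Fixed-width hex key: lexicographic order of equally-padded keys equals
# numeric order. `width` is the number of limbs to pad to.
big_hex <- function(a, width = length(a)) {
  a <- big_trim(a)
  stopifnot(width >= length(a))
  limbs <- c(a, numeric(width - length(a)))
  paste(sprintf("%06x", rev(limbs)), collapse = "")
}

big_to_num <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * BIG_BASE + a[i]
  v  # exact only below 2^53
}

big_dec <- function(a) {
  if (big_is_zero(a)) return("0")
  digits <- character(0)
  cur <- big_trim(a)
  while (!big_is_zero(cur)) {
    rem <- 0
    quo <- numeric(length(cur))
    for (i in rev(seq_along(cur))) {
      v <- rem * BIG_BASE + cur[i]
      quo[i] <- v %/% 1e6
      rem <- v %% 1e6
    }
    cur <- big_trim(quo)
    digits <- c(
      if (big_is_zero(cur)) sub("^0+(.)", "\\1", sprintf("%06.0f", rem))
      else sprintf("%06.0f", rem),
      digits
    )
  }
  paste(digits, collapse = "")
}

# Factorize a big natural over the first `n_primes` primes; returns exponent
# vector. Errors if a residual cofactor remains (never happens for values
# built as products of those primes).
big_factor_small_primes <- function(a, n_primes) {
  primes <- nth_primes(n_primes)
  expo <- integer(n_primes)
  cur <- big_trim(a)
  for (k in seq_len(n_primes)) {
    p <- primes[k]
    repeat {
      # divide by p, track remainder
      rem <- 0
      quo <- numeric(length(cur))
      for (i in rev(seq_along(cur))) {
        v <- rem * BIG_BASE + cur[i]
        quo[i] <- v %/% p
        rem <- v %% p
      }
      if (rem != 0) break
      cur <- big_trim(quo)
      expo[k] <- expo[k] + 1L
    }
  }
  if (!(length(cur) == 1L && cur[1L] == 1)) {
    stop("value has prime factors beyond the first ", n_primes, " primes")
  }
  expo
}
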