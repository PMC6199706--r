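# Independent oracles used to validate the package's computations. These
# deliberately use different algorithms from the implementation paths they
# check.

# Does `s` contain any exact direct repeat of length >= min_len with
# non-overlapping copies? Diagonal run-length scan over all offsets.
brute_force_has_repeat <- function(s, min_len) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  for (d in seq_len(n - 1L)) {
    eq <- chars[seq_len(n - d)] == chars[(d + 1L):n]
    r <- rle(eq)
    run_len <- r$lengths[r$values]
    if (any(pmin(run_len, d) >= min_len)) return(TRUE)
  }
  FALSE
}

# All maximal exact direct repeats >= min_len: list of (start1, start2, len),
# 0-based, copies clipped to be non-overlapping.
brute_force_exact_repeats <- function(s, min_len) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  for (d in seq_len(n - 1L)) {
    eq <- chars[seq_len(n - d)] == chars[(d + 1L):n]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      len <- min(r$lengths[k], d)
      if (len >= min_len)
        out[[length(out) + 1L]] <- c(start1 = pos[k] - 1L,
                                     start2 = pos[k] - 1L + d, len = len)
    }
  }
  out
}

# Exact upper-tail binomial P(X >= a) by direct term summation with
# Pascal-triangle binomial coefficients (independent of pbinom).
exact_binom_tail <- function(a, n, p) {
  if (a <= 0) return(1)
  # Pascal triangle row n
  row <- 1
  for (i in seq_len(n)) row <- c(row, 0) + c(0, row)
  sum(row[(a + 1L):(n + 1L)] * p^(a:n) * (1 - p)^(n - (a:n)))
}

# Regularized upper incomplete gamma Q(a, x) via series / continued
# fraction (Lentz), giving the chi-square survival function
# Q(df/2, x/2). Independent of pchisq.
gammq_oracle <- function(a, x) {
  if (x < 0 || a <= 0) stop("bad args")
  if (x == 0) return(1)
  gln <- lgamma(a)
  if (x < a + 1) {                      # series for P, return 1 - P
    ap <- a; s <- 1 / a; del <- s
    for (i in 1:1000) {
      ap <- ap + 1
      del <- del * x / ap
      s <- s + del
      if (abs(del) < abs(s) * 1e-15) break
    }
    return(1 - s * exp(-x + a * log(x) - gln))
  }
  # continued fraction for Q
  tiny <- 1e-300
  b <- x + 1 - a; c <- 1 / tiny; d <- 1 / b; h <- d
  for (i in 1:1000) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b; if (abs(d) < tiny) d <- tiny
    c <- b + an / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < 1e-15) break
  }
  exp(-x + a * log(x) - gln) * h
}

chisq_sf_oracle <- function(chi2, df) gammq_oracle(df / 2, chi2 / 2)

# Decimal string addition and doubling: an addition-based bignum oracle for
# powers (4^n = "1" doubled 2n times), independent of the multiply-by-4
# implementation.
bigadd_str <- function(a, b) {
  da <- rev(as.integer(strsplit(a, "", fixed = TRUE)[[1]]))
  db <- rev(as.integer(strsplit(b, "", fixed = TRUE)[[1]]))
  n <- max(length(da), length(db))
  da <- c(da, rep(0L, n - length(da)))
  db <- c(db, rep(0L, n - length(db)))
  s <- da + db; carry <- 0L
  for (i in seq_len(n)) {
    v <- s[i] + carry; s[i] <- v %% 10L; carry <- v %/% 10L
  }
  while (carry > 0L) { s <- c(s, carry %% 10L); carry <- carry %/% 10L }
  paste(rev(s), collapse = "")
}

pow4_oracle <- function(n) {
  x <- "1"
  for (i in seq_len(2L * n)) x <- bigadd_str(x, x)
  x
}

# random DNA string helper for property tests
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
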