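# Internal numeric helpers shared across modules.

# Sum `vals` into bins 1..n given by integer bin ids `idx`.
accumulate_by_id <- function(idx, vals, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(vals, idx, reorder = TRUE)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# Decode 1-based linear indices k of the ordered pairs (i < j) over 1..nn,
# enumerated (1,2),(1,3),...,(1,nn),(2,3),...  Inverse of the triangular
# offset off(i) = (i-1)*nn - i*(i-1)/2; the analytic root is corrected for
# floating-point error by at most one step in each direction.
decode_pair_index <- function(k, nn) {
  k0 <- k - 1
  off <- function(i) (i - 1) * nn - i * (i - 1) / 2
  i <- floor(((2 * nn - 1) - sqrt((2 * nn - 1)^2 - 8 * k0)) / 2) + 1
  i <- pmax(1, pmin(i, nn - 1))
  hi <- off(i) > k0
  i[hi] <- i[hi] - 1L
  lo <- (i + 1 <= nn - 1) & (off(i + 1) <= k0)
  i[lo] <- i[lo] + 1L
  j <- k0 - off(i) + i + 1
  cbind(as.integer(i), as.integer(j))
}

# Uniformly sample m distinct unordered non-loop pairs from `ids`.
sample_distinct_pairs <- function(ids, m) {
  nn <- length(ids)
  total <- nn * (nn - 1) / 2
  if (m > total) {
    stop("requested ", m, " edges but only ", total, " distinct pairs exist",
         call. = FALSE)
  }
  if (m == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  ij <- decode_pair_index(sample.int(total, m), nn)
  u <- ids[ij[, 1L]]
  v <- ids[ij[, 2L]]
  cbind(pmin(u, v), pmax(u, v))
}

# Canonical (u < v), duplicate-free edge matrix.
canonical_edges <- function(u, v) {
  a <- pmin(u, v)
  b <- pmax(u, v)
  keep <- !duplicated(a * 2^26 + b) & a != b
  cbind(as.integer(a[keep]), as.integer(b[keep]))
}

# sample() without the length-1 surprise.
resample <- function(x, size) {
  x[sample.int(length(x), size)]
}

# Gaussian truncated below at zero, by inverse-CDF on the admissible tail.
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd <= 0) {
    return(rep(max(mean, 0), n))
  }
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
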