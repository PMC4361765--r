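# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Two-pass Pearson correlation from the definition.
pearson_bruteforce <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Weighted geometric mean by direct product, no log transform.
geomean_bruteforce <- function(values, weights) {
  w <- weights / sum(weights)
  out <- 1
  for (i in seq_along(values)) out <- out * values[i]^w[i]
  out
}

# Scalar Schaefer forward simulation, written independently of
# project_pairs (explicit loop, no matrix code).
schaefer_bruteforce <- function(r, K, b0, catches) {
  B <- b0 * K
  out <- B
  for (ct in catches) {
    B <- B + r * B * (1 - B / K) - ct
    out <- c(out, B)
  }
  out
}
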