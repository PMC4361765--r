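# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stock RNG seed derived from (run seed, stock id), so
# per-stock results do not depend on assessment order. Kept below 2^31 - 1.
stock_seed <- function(seed, stock_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(stock_id))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

# MD5 of an arbitrary R object via its serialized bytes (used for config
# hashes and determinism checks on in-memory results).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps the stream stable across R >= 3.5
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Scalar-or-vector range validation with field naming.
check_range <- function(x, field, lower, upper, allow_na = FALSE) {
  bad <- !is.na(x) & (x < lower | x > upper)
  if (any(bad)) {
    stopf("'%s' must lie in [%g, %g] (got %s)", field, lower, upper,
          paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", "))
  }
  if (!allow_na && any(is.na(x))) stopf("'%s' contains NA", field)
  invisible(x)
}
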