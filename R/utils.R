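# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps every stochastic operation in the
# package reproducible without clobbering the session RNG.
local_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a run seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483647)
}

# Weighted population mean and SD (weights assumed normalized).
weighted_mean_w <- function(x, w) sum(w * x)

weighted_sd_pop <- function(x, w) {
  m <- sum(w * x)
  sqrt(sum(w * (x - m)^2))
}

# Weighted Pearson correlation with population normalization.
weighted_cor <- function(x, y, w) {
  mx <- sum(w * x)
  my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  cov / (weighted_sd_pop(x, w) * weighted_sd_pop(y, w))
}
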