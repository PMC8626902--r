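# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All randomness in the package funnels through
# this so that a single integer seed makes a run reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from a master seed, kept within 32-bit
# integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(partition = 11L, cohort = 101L, noise = 211L,
               expression = 307L, methylation = 401L, peaks = 503L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# 0-based half-open interval overlap (>= 1 shared base).
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

# Convert 0-based half-open coordinates to a GRanges (1-based closed).
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = getOption("increg.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}
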