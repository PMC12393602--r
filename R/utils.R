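# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a per-stage substream seed from a master seed; kept < 2^31.
substream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) + as.integer(offset)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Strip a leading "chr" prefix; chromosome tokens are kept as characters.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

is_autosome <- function(chrom) norm_chrom(chrom) %in% as.character(1:22)

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# IRanges over 0-based half-open [start, end): stored as 1-based closed
# [start + 1, end] so that width() == end - start.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# Tiny FNV-1a hash of a character scalar -> 8 hex digits (config stamping).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
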