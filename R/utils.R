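# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are deterministic without clobbering
# the session stream.
with_seed <- function(seed, expr) {
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
  expr
}

# Per-stage seeds derived from one global seed; offsets keep stages
# independently re-runnable. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# Phred quality -> error probability.
phred_to_error <- function(q) {
  if (any(q < 0)) stopf("Phred qualities must be >= 0")
  10^(-q / 10)
}

TRANSITION_PAIRS <- list(c("C", "T"), c("G", "A"))

is_transition_site <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
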