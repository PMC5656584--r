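# Seed plumbing.  All user-facing stochastic functions accept `seed`; when
# non-NULL the global RNG state is saved, reseeded, and restored on exit, so
# seeded calls are pure.  Sub-streams are derived with a Lehmer step so that
# one master seed drives independent stages (partitioning, GA init, noise).

local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# Derived seeds stay in [1, 2^31 - 2] (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  for (k in seq_len(stream)) x <- (x * 48271) %% m
  as.integer(ifelse(x == 0, 1, x))
}
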