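# internal helpers shared across modules

.acuteqeeg_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# counter-based per-subject seed derivation (31-bit, Lehmer-style step)
.derive_seed <- function(master, index) {
  (as.numeric(master) * 48271 + as.numeric(index)) %% 2147483647
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

# md5 of a deparsed R object, used to stamp pipeline artifacts
.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
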