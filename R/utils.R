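# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
rc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "kpcarc_error", "error", "condition")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# One-letter residue label in author numbering, e.g. "R131"; falls back to
# the three-letter code when the residue is non-standard.
residue_one_letter <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  bad <- is.na(out) | out == "X"
  out[bad] <- resname[bad]
  out
}
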