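# Internal helpers shared across modules.

# Derive a reproducible child seed from a global seed and a generator name.
# Keeps all seeds in the 32-bit signed range.
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L + 1)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate an expression matrix: numeric, dimnames present and unique.
check_expr <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated sample ids", arg))
  }
  invisible(x)
}

sorted_unique <- function(x) sort(unique(as.character(x)))
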