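# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed and a stage label.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 48271 + h * 16807 + index * 69621) %% 2147483647L)
}

# Evaluate an expression under a local RNG state so callers' streams are
# untouched.
with_seed <- function(seed, expr) {
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
  force(expr)
}

assert_columns <- function(df, cols, where = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        where, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "predchar_schema_error"
    )
  }
  invisible(df)
}

elc_components <- function() c("bioclimatic", "edaphic", "geophysic")
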