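# internal helpers shared across modules

# Deterministic per-unit seed derivation: mixes a global seed with one or
# more small indices into a value in [1, 2^31 - 2] so that every simulated
# window / population / stage gets an independent, reproducible RNG stream.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed %% m)
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) * 2654435769) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

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

stop_bad_config <- function(msg) {
  abort(msg, class = "selscape_config_error")
}

stop_domain <- function(msg) {
  abort(msg, class = "selscape_domain_error")
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")),
      class = "selscape_schema_error"
    )
  }
  invisible(df)
}
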