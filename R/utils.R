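# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic entry points take an
# explicit seed and route through here, so no function mutates global RNG
# state as a side effect.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

stop_if_not_positive <- function(x, what, strict = TRUE) {
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (!is.numeric(x) || anyNA(x) || bad) {
    stop(what, if (strict) " must be strictly positive" else " must be non-negative",
         call. = FALSE)
  }
  invisible(x)
}

#' @importFrom utils packageVersion
pkg_version_string <- function() {
  as.character(utils::packageVersion("dremseq"))
}
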