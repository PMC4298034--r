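# internal validation helpers; all user-facing errors carry a dcmodel error class
# so the CLI can map them onto exit codes (usage vs numerical/degenerate).

stop_invalid <- function(msg, ...) {
  rlang::abort(msg, class = c("dc_error_invalid_parameter", "dc_error"), ...)
}

stop_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = c("dc_error_degenerate", "dc_error"), ...)
}

stop_no_solution <- function(msg, ...) {
  rlang::abort(msg, class = c("dc_error_no_solution", "dc_error"), ...)
}

check_probability <- function(x, what, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_invalid(sprintf("`%s` must be numeric in [0, 1].", what))
  }
  if (!is.null(len) && length(x) != len) {
    stop_invalid(sprintf("`%s` must have length %d.", what, len))
  }
  invisible(x)
}

check_count <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(as.integer(min(x, .Machine$integer.max)))
}

# set the RNG state locally when a seed is given, leaving the caller's
# stream untouched; with seed = NULL draws come from the global stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_invalid("`seed` must be a single integer or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

GENOTYPE_LABELS <- c("DD", "DC", "CC")
PAIR_LABELS <- c("R-R", "R-L", "L-L")
PARENT_LABELS <- c("RxR", "RxL", "LxL")
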