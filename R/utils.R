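#' @keywords internal
"_PACKAGE"

# direction vocabulary shared by every module
.DIRECTIONS <- c("up", "down", "unspecified")
.CALL_DIRECTIONS <- c("up", "down", "unchanged")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_ds <- function(msg, class) {
  stop(structure(
    class = c(class, "dystroscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(ok, msg, class = "dystroscore_input_error") {
  if (!isTRUE(ok)) abort_ds(msg, class)
  invisible(TRUE)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# .Random.seed afterwards so generators never leak global random state.
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite integer")
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

trimmed_nonempty <- function(x) {
  x <- trimws(as.character(x))
  nzchar(x)
}

#' Normalize a direction token vector
#'
#' @param x character vector of direction labels.
#' @param allowed permitted vocabulary.
#' @return `x`, validated.
#' @keywords internal
check_directions <- function(x, allowed = .DIRECTIONS) {
  bad <- setdiff(unique(x), allowed)
  assert_that(length(bad) == 0L,
              sprintf("invalid direction token(s): %s (allowed: %s)",
                      paste(bad, collapse = ", "),
                      paste(allowed, collapse = ", ")))
  x
}
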