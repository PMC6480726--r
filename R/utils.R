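# Internal validation and RNG helpers.

stop_lfnmr <- function(..., class = "lfnmr_error") {
  stop(errorCondition(paste0(...), class = c(class, "lfnmr_error")))
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_lfnmr(name, " must be a single non-missing number",
               class = "lfnmr_validation_error")
  if (finite && !is.finite(x))
    stop_lfnmr(name, " must be finite", class = "lfnmr_validation_error")
  if (positive && x <= 0)
    stop_lfnmr(name, " must be > 0", class = "lfnmr_validation_error")
  if (nonnegative && x < 0)
    stop_lfnmr(name, " must be >= 0", class = "lfnmr_validation_error")
  invisible(x)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
# A NULL seed leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (keeps each stage of a
# pipeline independently reproducible). Values stay below 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
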