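# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic "commercial" rounding used for report output and batch-size
#' schedules, in place of [base::round()]'s round-half-to-even rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.305, 2)  # 0.31, where round() gives 0.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Locale-independent id ordering; ties everywhere are broken by smallest id
# so that runs replay identically across platforms.
order_ids <- function(ids, key = NULL) {
  if (is.null(key)) order(ids, method = "radix")
  else order(key, ids, method = "radix")
}

sort_ids <- function(ids) ids[order_ids(ids)]

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic sub-seed derivation (kept below 2^31 - 1).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 7919 + 1) %% 2147483647)
}

# sample() without the length-1 numeric surprise.
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

stop_iterscreen <- function(subclass, msg, call. = FALSE) {
  cond <- structure(
    class = c(subclass, "iterscreen_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg, subclass = "iterscreen_validation_error") {
  if (!isTRUE(ok)) stop_iterscreen(subclass, msg)
  invisible(TRUE)
}
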