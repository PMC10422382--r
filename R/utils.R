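#' Round half away from zero
#'
#' Commercial rounding: `.5` always rounds up (for positive input), unlike
#' [base::round()]'s round-half-even. Used for the stratified split
#' arithmetic, where per-class test counts are `round_half_up(fraction *
#' total)`.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(147.6, 62.6, 0.5, 1.5))  # 148 63 1 2
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One global seed fans out to per-stage seeds through a fixed affine map so
# each pipeline stage is reproducible in isolation.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  stages <- c(fixtures = 1L, split = 2L, train = 3L, extract = 4L,
              select = 5L, evaluate = 6L)
  off <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.double(seed) * 7L + off * 1000003L) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Short stable fingerprint of an R object (configs, weight sets).
obj_hash <- function(x) {
  raw <- as.double(serialize(x, connection = NULL, version = 2))
  w <- (seq_along(raw) - 1) %% 9973 + 1
  h1 <- sum(raw * w) %% 2147483647
  h2 <- sum(raw * rev(w)) %% 2147483647
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

log_msg <- function(...) {
  message(sprintf("[octaco %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}
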