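#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois rnorm rlnorm rnbinom rgamma runif dnorm
#'   model.matrix p.adjust lm coef quantile setNames rmultinom sd var
#' @importFrom utils write.table read.table head
NULL

# Derive a reproducible child seed (< 2^31) from a root seed and a stream
# name, so independent pipeline stages get independent, re-runnable streams.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > max) {
    stop2(name, " must be a single number in [0, ", max, "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop2(name, " must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}
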