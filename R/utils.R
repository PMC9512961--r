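#' @keywords internal
"_PACKAGE"

# Canonical station order used for requirement sequencing and dispatch.
STATIONS <- c("ED", "CT", "OR", "ICU", "WARD")

BODY_REGIONS <- c("head", "face", "neck", "thorax", "abdomen", "spine",
                  "upper-extremity", "lower-extremity", "external")

TRIAGE_LEVELS <- c("RED", "YELLOW", "GREEN", "DEAD")

#' Deterministically split a master seed into per-module sub-seeds
#'
#' One master seed drives a whole run; each stochastic module (scenario
#' generation, prehospital evacuation, replicate draws) receives its own
#' sub-seed so that modules can be re-run in isolation and replicates are
#' independent.  Sub-seeds are drawn from a generator seeded with the master
#' seed and kept below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Distributes `n` integer units over categories in proportion to `weights`,
#' flooring each quota and assigning the remaining units in order of the
#' largest fractional remainders.  Ties are broken by position (earlier
#' categories win), which callers exploit for the RED > YELLOW > GREEN > DEAD
#' priority order.
#'
#' @param weights non-negative numeric vector with positive sum.
#' @param n total count to apportion.
#' @return integer vector summing exactly to `n`, same names as `weights`.
#' @export
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  quota <- weights / sum(weights) * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order(): ties resolved by index, i.e. by category position
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  out <- as.integer(base)
  names(out) <- names(weights)
  out
}

# Step-function lookup: largest value whose breakpoint time <= t, else `before`.
step_lookup <- function(times, values, t, before = 0L) {
  idx <- findInterval(t, times)
  ifelse(idx == 0L, before, values[pmax(idx, 1L)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(...) stop(sprintf(...), call. = FALSE)
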