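#' Run code with a locally seeded RNG
#'
#' All randomness in the package flows through named integer seeds so that
#' identical configuration yields identical output. The global RNG state is
#' restored afterwards.
#'
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Modal value with lowest-index tie break
#' @noRd
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(list(value = NA_integer_, tie = FALSE))
  tab <- table(x)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(value = min(winners), tie = length(winners) > 1L)
}

#' Derive a child seed from a parent seed and a label
#'
#' Keeps independent random streams (behaviour, population, splits,
#' permutations) reproducible from one top-level seed. Result stays below
#' 2^31 - 1.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 104729L)
}
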