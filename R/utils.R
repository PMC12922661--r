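# Internal helpers shared across modules.

#' Derive a reproducible stage seed from a global seed
#'
#' Every stochastic stage of the pipeline takes its own seed derived from one
#' global seed and a stage label, so stages can be re-run independently while
#' the whole pipeline stays reproducible.
#'
#' @param seed Global integer seed.
#' @param label Character stage label (e.g. `"cohort"`, `"recovery"`).
#' @param k Optional extra integer offset (e.g. a participant index).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  # simple LCG-style mix kept inside 2^31 via double arithmetic
  v <- (as.double(seed) * 69069 + h * 2654435.0 + k * 97) %% 2147483647
  as.integer(floor(v))
}

# logistic sigmoid
sigm <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) stop(msg, call. = FALSE)
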