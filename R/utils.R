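#' Derive a child random seed from a master seed and a stream label
#'
#' All stochastic functions in the package take an explicit integer seed.
#' Multi-stage simulations split one master seed into named sub-streams with
#' this helper, so that adding a stage never perturbs the draws of earlier
#' stages.  The scheme is a small multiplicative hash of the label folded
#' into the master seed, reduced modulo 2^31 - 1 (R seeds are 32-bit).
#'
#' @param seed master integer seed
#' @param label character scalar naming the stream (e.g. "fragmentize/tumor_1")
#' @return an integer seed in `[1, 2^31 - 2]`, deterministic in `(seed, label)`
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_umeseq <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_umeseq(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}
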