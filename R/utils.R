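#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pchisq pnorm qchisq rbinom rnorm runif setNames
#' @importFrom dplyr %>%
NULL

# internal logger: messages are suppressible with suppressMessages()
mx_log <- function(...) inform(paste0("[metaxes] ", sprintf(...)))

# round to a number of significant figures with ties away from zero
# (report presentation convention: 0.05/8 = 0.00625 prints as 0.0063);
# raw values are always retained alongside
signif2 <- function(x, digits = 2) {
  ifelse(x == 0, 0, {
    m <- floor(log10(abs(x)))
    f <- 10^(digits - 1 - m)
    sign(x) * floor(abs(x) * f + 0.5) / f
  })
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", what))
  }
  invisible(x)
}

stopifnot_count <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    abort(sprintf("`%s` must be a positive integer", what))
  }
  invisible(x)
}

# deterministic sub-seed derivation: keeps every stage's stream independent
# while staying reproducible from one user-facing seed (< 2^31)
derive_seed <- function(seed, tag) {
  h <- digest::digest(list(seed = as.integer(seed), tag = tag), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
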