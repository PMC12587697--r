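#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif rpois predict median quantile sd var
#'   cor coef lm lm.fit plogis qlogis dist
#' @importFrom rlang %||% abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# logistic function; kept as a named helper so the generating equations read
# like the printed model
sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# binary cross-entropy per observation; probabilities are clipped away from
# {0,1} only to keep the loss finite
bce <- function(y_prob, y, eps = 1e-12) {
  p <- clip(y_prob, eps, 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# derive a child seed from a base seed and a label, staying within 32-bit
# integer range
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}
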