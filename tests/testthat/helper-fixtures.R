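# Small shared fixtures, built in code at test time.

# the ground-truth graph of the simulated system (also shipped as the
# packaged expert edge list)
ground_truth_dag <- function() {
  causal_dag(tibble::tibble(
    from = c("X0", "X2", "X4", "Z", "X8", "X0", "X2", "X4", "T", "X3", "M",
             "T"),
    to   = c("T", "T", "T", "T", "Z", "Y", "Y", "Y", "M", "M", "Y", "Y")),
    provenance = "expert")
}

tiny_titan_config <- function(...) {
  titan_config(hidden = 16, layers = 1, heads = 2, epochs = 3,
               batch_size = 64, lr = 3e-3, profile = "reduced", ...)
}

# brute-force Shapley enumeration for a linear model evaluated with excluded
# features fixed at their background means (independent oracle for
# linear_shap)
shapley_enumeration <- function(beta, intercept, means, x) {
  p <- length(beta)
  f_of <- function(subset) {
    xe <- means
    xe[subset] <- x[subset]
    intercept + sum(beta * xe)
  }
  vapply(seq_len(p), function(j) {
    rest <- setdiff(seq_len(p), j)
    total <- 0
    for (k in 0:length(rest)) {
      subsets <- if (k == 0) list(integer()) else
        utils::combn(rest, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) {
        total <- total + w * (f_of(c(S, j)) - f_of(S))
      }
    }
    total
  }, numeric(1))
}

# all-pairs Mann-Whitney probability with ties counted half (independent
# oracle for auc_roc)
auc_bruteforce <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}
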