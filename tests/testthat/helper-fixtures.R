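# shared fixtures, all built in code

# two-variable chain Cmp -> x (coef b1) -> y (coef b2)
chain_truth <- function(b1 = 0.8, b2 = 0.5, noise = "gaussian") {
  ground_truth_sem(c("Cmp", "x", "y"),
                   data.frame(source = c("Cmp", "x"), target = c("x", "y"),
                              coefficient = c(b1, b2)),
                   noise = noise)
}

# random recursive path model over p variables with edge probability prob;
# coefficients in [-0.8, 0.8] away from 0, unit disturbance variances
random_truth <- function(p, seed, prob = 0.5) {
  set.seed(seed)
  vars <- c("Cmp", paste0("v", seq_len(p - 1)))
  src <- c(); tgt <- c()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (j > p) next
    if (stats::runif(1) < prob) { src <- c(src, vars[i]); tgt <- c(tgt, vars[j]) }
  }
  coefs <- stats::runif(length(src), 0.3, 0.8) * sample(c(-1, 1), length(src), TRUE)
  ground_truth_sem(vars,
                   if (length(src)) data.frame(source = src, target = tgt,
                                               coefficient = coefs),
                   noise = "gaussian")
}

# small deterministic transaction fixture: 10 samples, compost in 5,
# item B=high in 4, overlap 3
fixture_transactions <- function() {
  tx <- list(
    c("compost", "B=high"), c("compost", "B=high"), c("compost", "B=high"),
    c("compost", "B=low"), c("compost", "B=low"),
    c("B=high"), c("B=low"), c("B=low"), c("B=low"), c("B=low"))
  structure(tx, class = "transactions")
}

# brute-force rule metrics from raw transactions
brute_rule <- function(tx, a, b) {
  n <- length(tx)
  ina <- vapply(tx, function(t) a %in% t, TRUE)
  inb <- vapply(tx, function(t) b %in% t, TRUE)
  s <- mean(ina & inb)
  list(support = s, confidence = s / mean(ina), lift = (s / mean(ina)) / mean(inb))
}
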