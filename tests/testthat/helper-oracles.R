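# independent loop-based implementation of the accuracy metric suite
brute_metrics <- function(cm) {
  n <- nrow(cm); N <- sum(cm)
  oa <- 0
  for (i in seq_len(n)) oa <- oa + cm[i, i]
  oa <- oa / N
  P <- R <- F1 <- numeric(n)
  for (i in seq_len(n)) {
    pred_tot <- 0; ref_tot <- 0
    for (j in seq_len(n)) {
      pred_tot <- pred_tot + cm[j, i]
      ref_tot <- ref_tot + cm[i, j]
    }
    P[i] <- if (pred_tot > 0) cm[i, i] / pred_tot else 0
    R[i] <- if (ref_tot > 0) cm[i, i] / ref_tot else 0
    F1[i] <- if (P[i] + R[i] > 0) 2 * P[i] * R[i] / (P[i] + R[i]) else 0
  }
  pc <- 0
  for (i in seq_len(n)) pc <- pc + sum(cm[i, ]) * sum(cm[, i])
  pc <- pc / N^2
  list(oa = oa, P = P, R = R, F1 = F1, pc = pc,
       kappa = (oa - pc) / (1 - pc))
}

# maximum absolute deviation between the package metrics and the brute-force
# oracle over n_mat random confusion matrices
metrics_oracle_maxdiff <- function(n_mat = 1000, seed = 123) {
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_mat)) {
    n <- sample(2:17, 1)
    cm <- matrix(stats::rpois(n * n, lambda = sample(c(1, 5, 40), 1)), n, n)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- suppressWarnings(classification_metrics(cm))
    want <- brute_metrics(cm)
    # chance agreement of exactly 1 leaves kappa 0/0 in the oracle; the
    # package defines that degenerate case explicitly, so skip its kappa
    kd <- if (abs(1 - want$pc) < 1e-9) 0 else abs(got$kappa - want$kappa)
    worst <- max(worst,
                 abs(got$oa - want$oa), abs(got$pc - want$pc), kd,
                 max(abs(got$per_class$precision - want$P)),
                 max(abs(got$per_class$recall - want$R)),
                 max(abs(got$per_class$f1 - want$F1)))
  }
  worst
}
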