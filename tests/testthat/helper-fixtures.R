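# Shared fixtures and independent oracles for the suite.

# quick two-group table of log-normal concentrations, one block
rand_table <- function(n_a = 8, n_b = 10, p = 6, seed = 1,
                       block = "serum") {
  set.seed(seed)
  v <- matrix(rlnorm(p * (n_a + n_b)), n_a + n_b, p,
              dimnames = list(NULL, paste0(block, "__v", seq_len(p))))
  metabolite_table(v, rep(c("COPD", "OSAS"), c(n_a, n_b)))
}

# exhaustive pair-counting AUC (independent of the rank-based implementation)
auc_pairs <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# brute-force Kennard-Stone: enumerate to find the max-distance pair, then
# grow greedily by max-min distance with lowest-index tie-break
ks_brute <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  best <- c(1L, 2L)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (D[i, j] > D[best[1], best[2]]) best <- c(i, j)
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- vapply(cand, function(c) min(D[c, sel]), numeric(1))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# variables planted in the recovery simulations (fixed across the suite)
planted_five <- function(effect = 1.5) {
  setNames(rep(effect, 5),
           c("EBC__v3", "serum__v5", "serum__v20", "urine__v7",
             "urine__v20"))
}
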