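# Independent oracles used across tests. These deliberately take different
# computational routes than the package implementations they check.

# Branch length of the root-spanning survival subtree, computed by an
# edge-wise route: an edge belongs to the subtree iff a present leaf
# descends from its child node. (The implementation unions root-to-tip
# paths instead.)
oracle_branch_length <- function(tree, present) {
  tips <- match(present, tree$tip.label)
  ntip <- ape::Ntip(tree)
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  keep <- vapply(seq_len(nrow(tree$edge)), function(e) {
    any(tips_under(tree$edge[e, 2]) %in% tips)
  }, logical(1))
  sum(tree$edge.length[keep])
}

# Brute-force one-sample t statistic and two-sided p, written from the
# textbook formula rather than stats::t.test.
oracle_one_sample_t <- function(x, mu) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Beta-binomial sampler written independently of gen_allele_counts (fixed
# total coverage, explicit mixture draw) for estimator cross-checks.
oracle_betabinom_ar_mean <- function(ar_true, coverage, rho, n, seed) {
  set.seed(seed)
  p <- ar_true / (1 + ar_true)
  s <- (1 - rho) / rho
  ps <- if (rho > 0) rbeta(n, p * s, (1 - p) * s) else rep(p, n)
  xi <- rbinom(n, coverage, ps)
  mean(xi / (coverage - xi))
}
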