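# Shared fixtures: everything is generated in code at test time.

toy_counts <- function() {
  m <- matrix(c(10, 20, 30, 40,
                100, 200, 150, 120,
                9, 9, 9, 50,
                5, 5, 5, 5,
                60, 55, 70, 65,
                1, 2, 1, 3), nrow = 6, byrow = TRUE)
  rownames(m) <- paste0("G", 1:6)
  colnames(m) <- paste0("S", 1:4)
  m
}

toy_samples <- function(classes, reps = 3) {
  data.frame(
    sample_id = paste(rep(classes, each = reps), seq_len(reps), sep = "_"),
    class = rep(classes, each = reps),
    replicate = rep(seq_len(reps), times = length(classes)),
    stringsAsFactors = FALSE)
}

# Small two-class simulated dataset for DE-level tests.
quick_sim <- function(seed, planted = NULL, n_genes = 600,
                      classes = c("negative", "PROTAC"), reps = 3) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, classes = classes,
                    replicates_per_class = reps, planted_effects = planted)
  simulate_counts(cfg)
}

# Independent brute-force BH step-up oracle (sorted p, p[i]*m/i, cumulative
# minimum from the largest p, capped at 1).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exhaustive hypergeometric tail oracle: enumerate every possible query
# draw of the same size from the universe and count overlaps >= k.
ora_oracle <- function(universe, set, query) {
  draws <- combn(universe, length(query))
  k <- length(intersect(query, set))
  mean(apply(draws, 2, function(d) length(intersect(d, set)) >= k))
}
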