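# Shared in-code fixtures. Everything is generated programmatically;
# nothing is read from disk except files the tests themselves write.

# A small two-group simulated study used by several test files.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_group = c("6m" = 6L, "28m" = 6L),
                        n_genes = 400L, frac_de_24m = 0, frac_de_28m = 0.1,
                        n_coupled = 10L,
                        function_decline = c("6m" = 0, "28m" = -8),
                        seed = 314L)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# Hand-written functional records for CFAB tests: reference animals with
# controlled determinant values.
make_records <- function(rotarod, grip = rep(100, length(rotarod)),
                         cling = rep(10^1.8, length(rotarod)),
                         treadmill = rep(25, length(rotarod)),
                         vwr = rep(5, length(rotarod)),
                         ids = sprintf("a%02d", seq_along(rotarod)),
                         age = rep("6m", length(rotarod))) {
  data.frame(animal_id = ids, age_group = age,
             rotarod_s = rotarod, grip_force = grip,
             inverted_cling_s = cling, treadmill_speed = treadmill,
             vwr = vwr, stringsAsFactors = FALSE)
}

# Independent brute-force BH oracle: padj_i = min_{j: p_j >= p_i over the
# step-up path} p_(j) m / j, literally per definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper-tail oracle: P[X >= b] by summing the
# pmf written out with choose().
hyper_brute <- function(b, B, N, n) {
  ks <- max(0, n - (N - B)):min(B, n)
  pmf <- choose(B, ks) * choose(N - B, n - ks) / choose(N, n)
  sum(pmf[ks >= b])
}
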