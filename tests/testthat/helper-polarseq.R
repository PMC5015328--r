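# Shared fixtures and independent oracles for the test suite.

# One moderately sized simulated dataset with planted classes, analysed
# once and reused across tests (the "standard dataset").
.std_cache <- new.env(parent = emptyenv())
standard_dataset <- function() {
  if (is.null(.std_cache$ds)) {
    sim <- simulate_counts(simulation_config(n_genes = 5000, seed = 101))
    s <- size_factors(sim$counts)
    q <- normalize_counts(sim$counts, s)
    disp <- estimate_dispersions(sim$counts, s, sim$design)
    de <- lrt_time_effect(sim$counts, s, sim$design, disp)
    profiles <- side_profiles(q, sim$design)
    .std_cache$ds <- list(sim = sim, s = s, q = q, disp = disp, de = de,
                          profiles = profiles)
  }
  .std_cache$ds
}

make_profiles <- function(oral, physa, time_points = c(0, 8, 24, 72)) {
  if (is.null(dim(oral))) oral <- matrix(oral, nrow = 1)
  if (is.null(dim(physa))) physa <- matrix(physa, nrow = 1)
  rownames(oral) <- rownames(physa) <- sprintf("g%03d", seq_len(nrow(oral)))
  structure(list(oral = oral, physa = physa, time_points = time_points),
            class = "expression_profiles")
}

# Lin's concordance, evaluated directly from its definition
brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)
  2 * sxy / denom
}

# trend rules re-applied literally, one comparison at a time
brute_trend <- function(a, fold) {
  up <- TRUE
  down <- TRUE
  for (t in seq_along(a)[-1]) {
    if (!(a[t] / a[1] >= fold)) up <- FALSE
    if (!(a[1] / a[t] >= fold)) down <- FALSE
  }
  if (up) "always_up" else if (down) "always_down" else "other"
}

brute_interval <- function(a, fold) {
  out <- character(length(a) - 1)
  for (t in seq_along(out)) {
    r <- a[t + 1] / a[t]
    out[t] <- if (r >= fold) "up" else if (r <= 1 / fold) "down" else "flat"
  }
  out
}

# upper-tail hypergeometric probability by exhaustive enumeration
brute_hyper <- function(k, K, N, n) {
  tot <- choose(N, n)
  acc <- 0
  for (j in k:min(n, K)) acc <- acc + choose(K, j) * choose(N - K, n - j)
  acc / tot
}

# AUC of scores ranking `positive` below `negative` (ascending separation)
auc_ascending <- function(scores, positive, negative) {
  sc <- c(scores[positive], scores[negative])
  lab <- rep(c(TRUE, FALSE), c(sum(positive), sum(negative)))
  r <- rank(sc)
  n_neg <- sum(!lab)
  n_pos <- sum(lab)
  (sum(r[!lab]) - n_neg * (n_neg + 1) / 2) / (n_neg * n_pos)
}

rand_index <- function(a, b) {
  n <- length(a)
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  (sum(sa == sb) - n) / (n * (n - 1))
}
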