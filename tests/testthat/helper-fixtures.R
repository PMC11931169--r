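# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small template bank shared by cheap tests
tiny_bank <- function() memo("tiny_bank", template_bank(6, seed = 11))

# a quickly trained model for tests that only need a plausible scorer
small_model <- function() memo("small_model", {
  tr <- labeled_events(1500, tiny_bank(),
                       fractions = c(neural = 1, type1 = 0, type2 = 0),
                       seed = 21)
  spike_autoencoder(tr$segments, epochs = 8, seed = 7)
})

# full study-scale model (20 epochs, 5000 clean spikes) keyed by seed;
# shared between the acceptance blocks
study_model <- function(seed) memo(paste0("study_model_", seed), {
  tpls <- template_bank(20, seed = seed)
  tr <- labeled_events(5000, tpls,
                       fractions = c(neural = 1, type1 = 0, type2 = 0),
                       seed = seed * 31 + 1)
  list(model = spike_autoencoder(tr$segments, epochs = 20, seed = seed),
       templates = tpls)
})

# labeled evaluation run at study scale: unseen template bank, default
# composition; returns scores split by class plus overall accuracy
study_eval <- function(seed, n = 5000) memo(paste0("study_eval_", seed), {
  fit <- study_model(seed)
  ev_bank <- template_bank(20, seed = seed + 500)
  ev <- labeled_events(n, ev_bank, seed = seed * 31 + 2)
  sc <- predict(fit$model, ev$segments)
  list(scores = sc, labels = ev$labels,
       accuracy = classification_accuracy(ev$labels,
                                          classify_events(sc, 1.5)))
})

# brute-force oracles -------------------------------------------------------

msle_loop <- function(x, xhat) {
  s <- 0
  for (i in seq_along(x))
    s <- s + (log(abs(xhat[i]) + 1) - log(abs(x[i]) + 1))^2
  s / length(x)
}

silhouette_brute <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    if (sum(own) == 1) return(0)  # singleton convention
    (b - a) / max(a, b)
  }, numeric(1))
}

# optimal one-to-one matching count within tol (O(n*m) interval DP)
optimal_match_count <- function(gt, st, tol) {
  n <- length(gt); m <- length(st)
  dp <- matrix(0L, n + 1, m + 1)
  for (i in n:1) for (j in m:1) {
    best <- max(dp[i + 1, j], dp[i, j + 1])
    if (abs(gt[i] - st[j]) <= tol) best <- max(best, 1L + dp[i + 1, j + 1])
    dp[i, j] <- best
  }
  dp[1, 1]
}

isi_pairwise_brute <- function(times, window) {
  n <- length(times)
  if (n < 2) return(0)
  v <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (times[j] - times[i] < window) v <- v + 1L
  v / n
}
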