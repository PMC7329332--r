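# Independent brute-force oracles used across the suite.

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = no edge)
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# weight matrix -> edge-length matrix (1/w, Inf where no edge)
weights_to_lengths <- function(w) {
  len <- 1 / w
  len[w == 0] <- Inf
  diag(len) <- 0
  len
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      grow(c(prefix, lab), max(maxlab, lab))
    }
  }
  grow(integer(0), 0)
  out
}

# Newman weighted modularity of a partition
modularity_of <- function(w, membership) {
  m2 <- sum(w)
  k <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(k, k) / m2) * same) / m2
}

# random connected-ish weighted graph fixture
random_weight_matrix <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 1)
    }
  }
  w
}

# small deterministic synthetic calcium trace with known events
fixture_trace_with_events <- function(n_events = 20, snr = 10, seed = 1,
                                      fs = 500, duration = 600) {
  train <- gen_event_train(rate = n_events / duration * 1.6,
                           total_duration = duration, min_gap = 3,
                           duration_range = c(0.3, 2), seed = seed)
  suppressWarnings(
    gen_calcium_trace(train, fs = fs,
                      transient = list(rise_tau = 0.05, decay_tau = 0.4,
                                       amplitude = 1),
                      noise_sd = 1 / snr, seed = seed + 100))
}
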