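# Shared fixtures, built in code. Small genome for unit tests; the
# acceptance tests build the full 12 x 1 Mb desk world themselves.

tiny_genome <- function(n = 3, len = 1.2e5) genome_model(rep(len, n))

# memoized small layout (computed once per test run)
.fixture_env <- new.env()
tiny_layout <- function() {
  if (is.null(.fixture_env$lay))
    .fixture_env$lay <- make_probe_layout(tiny_genome(), 500, seed = 7)
  .fixture_env$lay
}

# Independent brute-force segmentation oracle: enumerate every breakpoint
# placement for n <= 12 and return the minimal penalized cost for each
# penalty. Deliberately shares no code with segment_chromosome().
brute_force_best <- function(x, penalties) {
  n <- length(x)
  stopifnot(n >= 1, n <= 12)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n)
    S[i, j] <- sum((x[i:j] - mean(x[i:j]))^2)
  best <- rep(Inf, length(penalties))
  n_masks <- if (n == 1) 1L else 2L^(n - 1L)
  bits <- if (n >= 2) 2^(0:(n - 2)) else numeric(0)
  for (mask in 0:(n_masks - 1L)) {
    ends <- c(which(bitwAnd(mask, bits) > 0), n)
    firsts <- c(1L, utils::head(ends, -1) + 1L)
    sse <- sum(S[cbind(firsts, ends)])
    best <- pmin(best, sse + penalties * length(ends))
  }
  best
}

# dp objective value of a segmentation
dp_objective <- function(seg, penalty) sum(seg$sse) + penalty * nrow(seg)

# one normalized scan over the tiny layout with planted events
tiny_processed_scan <- function(truth = NULL, sample = "S1", seed = 21,
                                noise_sd = 0.15) {
  lay <- tiny_layout()
  sc <- simulate_scan(lay, truth, sample = sample, noise_sd = noise_sd,
                      spatial_amp = 0.1, dye_bias_strength = 0.2,
                      seed = seed)
  qspline_normalize(spatial_correct(sc, lay))
}
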