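# Shared fixtures and independent oracles, built in code at test time.

# A MitoSignalSet of pure sinusoids on an rows x cols lattice.
# freqsMHz / phases are recycled over mitochondria.
makeSineSet <- function(rows = 3, cols = 3, N = 256, dt = 0.5,
                        freqsMHz = 20, phases = 0, noiseSd = 0,
                        baseline = 10, seed = 1) {
  M <- rows * cols
  freqsMHz <- rep_len(freqsMHz, M)
  phases <- rep_len(phases, M)
  tt <- (seq_len(N) - 1) * dt
  sig <- t(vapply(seq_len(M), function(m) {
    baseline + sin(2 * pi * freqsMHz[m] / 1000 * tt + phases[m])
  }, numeric(N)))
  if (noiseSd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    sig <- sig + matrix(rnorm(M * N, 0, noiseSd), M, N)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  MitoSignalSet(sig, dt = dt,
                gridRow = rep(seq_len(rows), each = cols),
                gridCol = rep(seq_len(cols), times = rows))
}

# Brute-force Watts-Strogatz clustering by explicit triangle enumeration:
# for each vertex, loop over all neighbour pairs and count realized links.
bruteLocalClustering <- function(adj) {
  M <- nrow(adj)
  vapply(seq_len(M), function(m) {
    nb <- which(adj[m, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (adj[nb[i], nb[j]] != 0) links <- links + 1L
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# Direct (non-FFT) Morlet CWT oracle: the transform is evaluated as an
# explicit O(N^2) sum over naively computed DFT components -- the same
# mathematical definition as the Fourier-domain implementation but with
# no fft() anywhere.
naiveCWT <- function(x, dt, scales, omega0 = 6) {
  N <- length(x)
  x <- x - mean(x)
  n <- 0:(N - 1)
  # naive DFT
  xhat <- vapply(n, function(k) sum(x * exp(-2i * pi * k * n / N)),
                 complex(1))
  k <- 0:(N - 1)
  omega <- ifelse(k <= N / 2, 2 * pi * k / (N * dt),
                  -2 * pi * (N - k) / (N * dt))
  W <- matrix(0 + 0i, length(scales), N)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psihat <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      ifelse(omega > 0, exp(-((s * omega - omega0)^2) / 2), 0)
    for (tt in seq_len(N)) {
      W[j, tt] <- sum(xhat * psihat * exp(2i * pi * k * (tt - 1) / N)) / N
    }
  }
  Mod(W)^2
}

# Random simple graph adjacency (for oracle comparisons).
randomAdjacency <- function(M, p) {
  A <- matrix(FALSE, M, M)
  A[upper.tri(A)] <- runif(M * (M - 1) / 2) < p
  A | t(A)
}
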