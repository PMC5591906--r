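# Shared fixtures: all randomness goes through explicit seeds so every
# test is reproducible in isolation.

random_sequence <- function(nx, ny, nt, seed = 1, pixel_scale = 255) {
  set.seed(seed)
  n <- nx * ny * nt
  dmri_sequence(array(complex(real = rnorm(n), imaginary = rnorm(n)),
                      c(nx, ny, nt)),
                pixel_scale = pixel_scale)
}

random_complex_matrix <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)), nr, nc)
}

# Planted low-rank + sparse problem: A0 a product of Gaussian factors,
# E0 with uniformly random support and +/- unit entries.
planted_rpca <- function(n = 100, rank = 5, sparsity = 0.05, seed = 1) {
  set.seed(seed)
  A0 <- matrix(rnorm(n * rank), n, rank) %*% t(matrix(rnorm(n * rank), n, rank))
  E0 <- matrix(0, n, n)
  idx <- sample(n * n, round(sparsity * n * n))
  E0[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
  list(X = (A0 + E0) + 0i, A0 = A0, E0 = E0, support = idx)
}

rel_frob <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# numerical rank at a relative threshold
mat_rank <- function(m, rtol = 1e-8) {
  d <- svd(m, nu = 0, nv = 0)$d
  sum(d > rtol * d[1])
}
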