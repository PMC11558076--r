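# shared fixture builders; everything is generated in code at test time

# simple trace over an n-locus 1 Mb panel from a coordinate matrix
make_trace <- function(coords, cell = "c1", chrom = "chr1", copy = "0",
                       bin_bp = 1e6) {
  n <- nrow(coords)
  locus_trace(cell, chrom, copy, (seq_len(n) - 1L) * bin_bp,
              seq_len(n) * bin_bp, coords)
}

# free random-walk chain, reproducible
walk_chain <- function(n, step_sd = 0.4, seed = 1) {
  set.seed(seed)
  apply(matrix(rnorm(n * 3, sd = step_sd), n, 3), 2, cumsum)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q * sign(diag(qr.R(qr_)))[col(Q)]
}

# brute-force orthogonal Procrustes oracle: many random orthogonal starts,
# each refined locally over an Euler-angle parameterization (both
# determinant signs), independent of the SVD route
oracle_procrustes_rmsd <- function(A, B, n_starts = 200) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  euler <- function(th) {
    cz <- cos(th[1]); sz <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  }
  obj <- function(th, refl) {
    R <- euler(th)
    if (refl) R[, 3] <- -R[, 3]
    sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  }
  best <- Inf
  for (refl in c(FALSE, TRUE)) {
    for (s in seq_len(n_starts)) {
      th0 <- runif(3, -pi, pi)
      fit <- optim(th0, obj, refl = refl, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 2000))
      best <- min(best, fit$value)
    }
  }
  best
}

# the desk-scale benchmark bundle shared by the acceptance tests; generated
# once per test run
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_bundle <- function() {
  if (!exists("bundle", .benchmark_cache)) {
    cfg <- synth_config(seed = 101L)
    .benchmark_cache$bundle <- generate_multimodal(cfg)
    .benchmark_cache$masked <- mask_traces(.benchmark_cache$bundle$traces,
                                           rates = c(0.5, 0.6, 0.7, 0.8),
                                           seed = 102L)
  }
  list(bundle = .benchmark_cache$bundle, masked = .benchmark_cache$masked)
}
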