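# small matrices with controlled observed/missing structure
mask_pairs <- function(K, pairs) {
  for (p in pairs) {
    K[p[1], p[2]] <- NA
    K[p[2], p[1]] <- NA
  }
  K
}

test_that("the informative Hi-C range maximises short-range rank agreement", {
  set.seed(31)
  n <- 30
  sep <- abs(row(diag(n)) - col(diag(n)))
  # sampled contacts track proximity up to separation 10, pure noise beyond:
  # rank agreement climbs while informative strata accumulate, then dilutes
  K <- exp(-sep / 4)
  noise <- sep > 10
  K[noise] <- runif(sum(noise))
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  H <- matrix(rpois(n * n, 60 * exp(-sep / 4)), n)
  H[lower.tri(H)] <- t(H)[lower.tri(H)]

  # brute-force all candidate ranges with an independent loop
  brute <- sapply(1:(n - 1), function(v) {
    sel <- upper.tri(K) & sep <= v
    if (sd(H[sel]) == 0 || sd(K[sel]) == 0) return(NA_real_)
    suppressWarnings(cor(H[sel], K[sel], method = "spearman"))
  })
  k <- select_k(H, K)
  expect_equal(k, which.max(brute))
  expect_true(k >= 6 && k <= 14)

  # noiseless monotone relation ties at 1 from the first stratum with
  # variation onward; the smallest such range wins
  H2 <- exp(-sep / 4) * 100
  K2 <- exp(-sep / 4)
  expect_equal(select_k(H2, K2), 2L)

  # anti-correlated data still returns the argmax of the (negative) profile
  K3 <- sep / max(sep)
  expect_equal(select_k(H, K3), which.max(sapply(1:(n - 1), function(v) {
    sel <- upper.tri(K3) & sep <= v
    suppressWarnings(cor(H[sel], K3[sel], method = "spearman"))
  })))

  expect_error(select_k(matrix(NA_real_, 3, 3), matrix(NA_real_, 3, 3)),
               "comparable")
})

test_that("the weight bound schedule switches off beyond the informative range", {
  expect_equal(wbound_schedule(5, 10), 0.4)
  expect_equal(wbound_schedule(11, 10), 0)
  expect_equal(wbound_schedule(1:12, 10, w = 0.4),
               c(rep(0.4, 10), 0, 0))
  expect_equal(wbound_schedule(3, 10, w = 0), 0)
})

test_that("stratum normalisation splits observed and missing parts to unit sums", {
  K <- matrix(NA_real_, 4, 4)
  # separation-1 entries: (1,2)=0.2 obs, (2,3)=0.6 obs, (3,4) missing
  K[1, 2] <- K[2, 1] <- 0.2
  K[2, 3] <- K[3, 2] <- 0.6
  Knf <- matrix(0.5, 4, 4)
  Knf[1, 2] <- Knf[2, 1] <- 1
  Knf[2, 3] <- Knf[3, 2] <- 3
  st <- normalize_stratum(K, Knf, NULL, v = 1)
  expect_equal(st$p_fish[st$observed], c(0.25, 0.75))
  expect_equal(sum(st$p_fish), 1)
  expect_equal(st$p_nf_obs[st$observed], c(0.25, 0.75))
  expect_equal(st$s_fish_obs, 0.8)
  expect_equal(st$s_nf_obs, 4)
  # missing part: single entry gets full mass
  expect_equal(st$p_nf_miss[!st$observed], 1)

  # all observed: missing sums are zero and missing profiles empty
  Kc <- matrix(0.5, 4, 4)
  st2 <- normalize_stratum(Kc, Knf, NULL, v = 1)
  expect_true(all(st2$observed))
  expect_equal(st2$s_nf_miss, 0)
  expect_false(st2$degenerate)
})

test_that("closed-form stratum weights match a fine grid search in both modes", {
  set.seed(32)
  grid_obj <- function(x, y, z, a) sum((a * x + (1 - a) * y - z)^2)
  for (case in 1:100) {
    npairs <- sample(3:12, 1)
    x <- runif(npairs); y <- runif(npairs); z <- runif(npairs)
    wb <- sample(c(0, 0.2, 0.4), 1)
    st <- list(observed = rep(TRUE, npairs), p_fish = z, p_nf_obs = y,
               p_nh_obs = x)
    fw <- fit_weights(st, w_bound = wb, mode = 1L)
    # constraints hold exactly: b is 1 - a by construction
    expect_identical(fw$b, 1 - fw$a)
    expect_gte(fw$a, wb)
    expect_gte(fw$b, 0)
    grid <- seq(wb, 1, by = 1e-3)
    best <- min(vapply(grid, grid_obj, numeric(1), x = x, y = y, z = z))
    expect_lte(grid_obj(x, y, z, fw$a), best + 1e-9)

    # modes 2-3: nonnegative single-weight least squares
    fw2 <- fit_weights(st, mode = 2L)
    expect_identical(fw2$a, 0)
    expect_gte(fw2$b, 0)
    gridb <- seq(0, 3, by = 1e-3)
    bestb <- min(vapply(gridb, function(b) sum((b * y - z)^2), numeric(1)))
    expect_lte(sum((fw2$b * y - z)^2), bestb + 1e-9)
  }
})

test_that("weight fitting hits its exact special cases", {
  z <- c(0.2, 0.3, 0.5)
  st <- list(observed = rep(TRUE, 3), p_fish = z, p_nf_obs = z,
             p_nh_obs = c(0.9, 0.05, 0.05))
  fw <- fit_weights(st, w_bound = 0, mode = 1L)
  expect_equal(fw$a, 0)
  expect_equal(fw$b, 1)

  st2 <- list(observed = rep(TRUE, 3), p_fish = z, p_nf_obs = c(1, 0, 0) - c(1, 0, 0) + c(0.9, 0.05, 0.05),
              p_nh_obs = z)
  fw2 <- fit_weights(st2, w_bound = 0.4, mode = 1L)
  expect_equal(fw2$a, 1, tolerance = 1e-6)

  # degenerate stratum: sentinel weights, flagged
  st3 <- list(observed = logical(3), p_fish = numeric(3),
              p_nf_obs = numeric(3), p_nh_obs = numeric(3))
  fw3 <- fit_weights(st3, w_bound = 0.4, mode = 1L)
  expect_true(fw3$flag)
  expect_equal(fw3$a, 0.4)
  expect_equal(fw3$b, 0.6)
  expect_equal(fit_weights(st3, mode = 3L)$b, 1)
})

test_that("observed entries survive imputation bit-identical and output is proper", {
  set.seed(33)
  X <- walk_chain(12, seed = 33)
  tr <- make_trace(X)
  D <- pairwise_distances(tr)
  sig <- estimate_sigma(D)
  K <- proximity(D, sig)
  Km <- mask_pairs(K, list(c(1, 5), c(2, 7), c(3, 4), c(9, 12), c(6, 11)))
  Knf <- proximity(pairwise_distances(make_trace(walk_chain(12, seed = 34))),
                   sig)
  out <- impute_scores(Km, Knf, mode = 3L)
  obs <- is.finite(Km) & row(Km) != col(Km)
  expect_identical(out$K[obs], Km[obs])     # Eq-20 observed branch, exact
  expect_true(all(is.finite(out$K)))
  expect_true(all(out$K >= 0 & out$K <= 1))
  expect_equal(out$K, t(out$K))

  # no missing entries: the matrix comes back unchanged off-diagonal
  out2 <- impute_scores(K, Knf, mode = 3L)
  expect_identical(out2$K[obs], K[obs])
})

test_that("stratum-total arithmetic follows the rescaling identity", {
  # observed sum 0.8 and proportion-of-observed 0.8 give imputed total 0.2
  s_obs <- 0.8; prop <- 0.8
  expect_equal(s_obs / prop - s_obs, 0.2)

  # engineered matrix reproducing those sums at separation 1:
  # neighbour mass 0.8 observed / 0.2 missing -> prop = 0.8
  n <- 5
  K <- matrix(NA_real_, n, n); diag(K) <- 1
  K[1, 2] <- K[2, 1] <- 0.5; K[2, 3] <- K[3, 2] <- 0.3
  K[3, 4] <- K[4, 3] <- NA; K[4, 5] <- K[5, 4] <- NA
  Knf <- matrix(0, n, n)
  Knf[1, 2] <- Knf[2, 1] <- 0.4; Knf[2, 3] <- Knf[3, 2] <- 0.4
  Knf[3, 4] <- Knf[4, 3] <- 0.1; Knf[4, 5] <- Knf[5, 4] <- 0.1
  out <- impute_scores(K, Knf, mode = 3L)
  # b = 1 here (neighbour profile proportional to observed), imputed total 0.2
  # split evenly over the two missing pairs by the neighbour profile
  expect_equal(out$K[3, 4] + out$K[4, 5], 0.2, tolerance = 1e-8)
  expect_equal(out$K[3, 4], out$K[4, 5])
})

test_that("a single truthful neighbour restores the masked stratum profile", {
  # noiseless toy: neighbour equals the pre-mask truth
  set.seed(34)
  X <- walk_chain(8, seed = 35)
  truth <- proximity(pairwise_distances(make_trace(X)), 1)
  Km <- mask_pairs(truth, list(c(1, 2), c(3, 4), c(2, 6), c(5, 8)))
  out <- impute_scores(Km, truth, mode = 3L)
  miss <- !is.finite(Km) & upper.tri(Km)
  # relative profile restored, scaled by the stratum-total estimate
  for (v in unique(abs(row(Km) - col(Km))[miss])) {
    sel <- miss & abs(row(Km) - col(Km)) == v
    if (sum(sel) >= 2) {
      ratio <- out$K[sel] / truth[sel]
      expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-8)
    }
  }
})

test_that("mode 1 with an all-zero Hi-C matrix reduces to mode 2 at zero bound", {
  set.seed(36)
  X <- walk_chain(10, seed = 36)
  truth <- proximity(pairwise_distances(make_trace(X)), 1)
  Km <- mask_pairs(truth, list(c(1, 3), c(2, 8), c(4, 9), c(5, 6)))
  Knf <- proximity(pairwise_distances(make_trace(walk_chain(10, seed = 37))), 1)
  H0 <- matrix(0, 10, 10)
  m1 <- impute_scores(Km, Knf, H0, mode = 1L, w_bound = 0, k = 5L)
  m2 <- impute_scores(Km, Knf, mode = 2L)
  expect_equal(m1$K, m2$K, tolerance = 1e-10)
})

test_that("mode 1 blends Hi-C with the bound enforced per stratum", {
  set.seed(37)
  X <- walk_chain(10, seed = 38)
  truth <- proximity(pairwise_distances(make_trace(X)), 1)
  Km <- mask_pairs(truth, list(c(1, 3), c(2, 8), c(4, 9), c(5, 6)))
  Knf <- truth
  H <- 50 * proximity(pairwise_distances(make_trace(walk_chain(10, seed = 39))), 1)
  out <- impute_scores(Km, Knf, H, mode = 1L, w_bound = 0.4, k = 4L)
  w <- out$weights
  expect_true(all(w$a[w$v <= 4] >= 0.4 - 1e-12))
  expect_true(all(w$a[w$v > 4] >= 0))
  expect_true(all(abs(w$a + w$b - 1) < 1e-12))
  expect_error(impute_scores(Km, Knf, NULL, mode = 1L), "mode 1")
})
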