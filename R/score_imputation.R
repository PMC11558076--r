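#' Choose the Hi-C-informative genomic distance
#'
#' For each candidate separation `v` in `1..v_max`, computes the Spearman rank
#' correlation between the Hi-C contacts and the FISH proximity scores over
#' all locus pairs with bin separation at most `v` that are present in both
#' matrices, and returns the `v` maximising it (smallest `v` on ties). Beyond
#' this range single-cell Hi-C contacts carry little signal, so the Hi-C
#' mixing weight is released there (see [wbound_schedule()]).
#'
#' @param H Contact matrix (merged Hi-C).
#' @param K Proximity matrix (FISH), `NA` for missing pairs.
#' @param v_max Largest separation to consider (defaults to N - 1).
#' @return Integer separation `k`.
#' @export
select_k <- function(H, K, v_max = nrow(K) - 1L) {
  n <- nrow(K)
  sep <- abs(row(K) - col(K))
  ut <- upper.tri(K)
  rho <- rep(NA_real_, v_max)
  for (v in seq_len(v_max)) {
    sel <- ut & sep <= v & is.finite(H) & is.finite(K)
    if (sum(sel) >= 2L && stats::sd(H[sel]) > 0 && stats::sd(K[sel]) > 0)
      rho[v] <- stats::cor(H[sel], K[sel], method = "spearman")
  }
  if (all(is.na(rho))) stop("no comparable pairs between H and K")
  which.max(rho)  # first index attaining the maximum
}

#' Hi-C weight bound schedule over genomic distance
#'
#' The lower bound on the Hi-C weight `a` is `w` for separations up to `k`
#' (where Hi-C is informative) and 0 beyond.
#'
#' @param v Bin separation.
#' @param k Informative range from [select_k()].
#' @param w Bound inside the informative range (default 0.4).
#' @return `w` if `v <= k`, else 0. Vectorised over `v`.
#' @export
wbound_schedule <- function(v, k, w = 0.4) {
  stopifnot(w >= 0, w <= 1)
  ifelse(v <= k, w, 0)
}

# index pairs (i, i+v) of the v-th superdiagonal, 1-based
.stratum_idx <- function(n, v) {
  i <- seq_len(n - v)
  cbind(i, i + v)
}

#' Normalise one genomic-distance stratum
#'
#' Splits the locus pairs at bin separation `v` into observed (finite in the
#' cell's own FISH matrix) and missing, accumulates the stratum sums of each
#' source, and rescales each (source, part) group to sum to one. Groups with a
#' zero sum yield all-zero profiles and are flagged.
#'
#' @param K_fish The cell's own proximity matrix (`NA` = missing pair).
#' @param K_nf Merged neighbour-FISH proximity matrix.
#' @param H_nh Merged neighbour-Hi-C contact matrix, or `NULL` (modes 2-3).
#' @param v Bin separation of the stratum.
#' @return List with the pair indices (`idx`, `observed` mask), normalised
#'   profiles `p_fish`, `p_nf_obs`, `p_nf_miss`, `p_nh_obs`, `p_nh_miss`, and
#'   the sums `s_fish_obs`, `s_nf_obs`, `s_nf_miss`, `s_nh_obs`, `s_nh_miss`,
#'   plus `degenerate` flags.
#' @export
normalize_stratum <- function(K_fish, K_nf, H_nh = NULL, v) {
  idx <- .stratum_idx(nrow(K_fish), v)
  kf <- K_fish[idx]
  obs <- is.finite(kf)
  # entries uncovered by every neighbour carry the part's mean neighbour
  # signal: with few loci a stratum can lack coverage at single entries, and
  # a hard zero there would understate the imputed proximity
  norm_part <- function(vals, mask) {
    fin <- is.finite(vals)
    fill <- if (any(fin & mask)) mean(vals[fin & mask]) else 0
    vals <- ifelse(fin, vals, fill)
    s <- sum(vals[mask])
    p <- numeric(length(vals))
    if (s > 0) p[mask] <- vals[mask] / s
    list(p = p, s = s)
  }
  nf <- K_nf[idx]
  nf_o <- norm_part(nf, obs); nf_m <- norm_part(nf, !obs)
  if (!is.null(H_nh)) {
    nh <- H_nh[idx]
    nh_o <- norm_part(nh, obs); nh_m <- norm_part(nh, !obs)
  } else {
    nh_o <- nh_m <- list(p = numeric(nrow(idx)), s = 0)
  }
  s_fish <- sum(kf[obs])
  p_fish <- numeric(nrow(idx))
  if (s_fish > 0) p_fish[obs] <- kf[obs] / s_fish
  list(idx = idx, observed = obs, v = v,
       p_fish = p_fish,
       p_nf_obs = nf_o$p, p_nf_miss = nf_m$p,
       p_nh_obs = nh_o$p, p_nh_miss = nh_m$p,
       s_fish_obs = s_fish,
       s_nf_obs = nf_o$s, s_nf_miss = nf_m$s,
       s_nh_obs = nh_o$s, s_nh_miss = nh_m$s,
       degenerate = !any(obs) || s_fish == 0)
}

#' Fit the stratum mixing weights
#'
#' Mode 1 minimises `sum_observed (a P_nH + b P_nF - P_FISH)^2` subject to
#' `a >= w_bound`, `b >= 0`, `a + b = 1`. With `b = 1 - a` this is a bounded
#' 1-D quadratic with a closed-form minimiser, clamped into
#' `[w_bound, 1]` — identical optimum to an iterative constrained solver, but
#' deterministic. Modes 2-3 fix `a = 0` and solve the nonnegative 1-D least
#' squares for `b` alone.
#'
#' @param stratum Output of [normalize_stratum()].
#' @param w_bound Lower bound on the Hi-C weight `a` (mode 1).
#' @param mode 1 (FISH + Hi-C) or 2/3 (FISH only).
#' @return List with `a`, `b`, and `flag` (`TRUE` when the stratum had no
#'   observed pairs and sentinel weights were used: `a = w_bound`,
#'   `b = 1 - w_bound` in mode 1; `b = 1` otherwise).
#' @export
fit_weights <- function(stratum, w_bound = 0.4, mode = 1L) {
  obs <- stratum$observed
  if (!any(obs)) {
    return(if (mode == 1L) list(a = w_bound, b = 1 - w_bound, flag = TRUE)
           else list(a = 0, b = 1, flag = TRUE))
  }
  z <- stratum$p_fish[obs]
  y <- stratum$p_nf_obs[obs]
  if (mode == 1L) {
    x <- stratum$p_nh_obs[obs]
    d <- x - y
    denom <- sum(d * d)
    a <- if (denom > 0) sum(d * (z - y)) / denom else w_bound
    a <- min(max(a, w_bound), 1)
    list(a = a, b = 1 - a, flag = FALSE)
  } else {
    denom <- sum(y * y)
    b <- if (denom > 0) max(0, sum(y * z) / denom) else 1
    list(a = 0, b = b, flag = FALSE)
  }
}

#' Impute the missing entries of a proximity matrix
#'
#' Per genomic-distance stratum `v`, fits the mixing weights on the observed
#' pairs ([fit_weights()]), forms the imputed normalised profile
#' `a P_nH + b P_nF` (mode 1) or `b P_nF` (modes 2-3) on the missing pairs,
#' estimates the stratum total of the missing part from the
#' proportion-of-observed of the neighbour sources, and rescales. Observed
#' entries are returned bit-identical; imputed entries are clipped to
#' `[0, 1]`; the diagonal is set to 1.
#'
#' Degenerate strata with no observed pairs use sentinel weights, and their
#' missing-part total is estimated from the cell's global ratio of observed
#' FISH signal to neighbour-FISH signal so the rescaling stays finite.
#'
#' @param K_fish The cell's proximity matrix (`NA` = missing).
#' @param K_nf Merged neighbour-FISH matrix ([merge_fish_neighbors()]).
#' @param H_nh Merged neighbour-Hi-C matrix, mode 1 only.
#' @param mode Imputation mode: 1 (FISH + Hi-C + RNA), 2 (FISH + RNA),
#'   3 (FISH only). Modes 2 and 3 differ upstream (how neighbours are found),
#'   not here.
#' @param w_bound Hi-C weight bound inside the informative range.
#' @param k Informative Hi-C range; `NULL` means [select_k()] on
#'   (`H_nh`, `K_fish`).
#' @return List with `K` (complete matrix) and `weights`, a data.frame of
#'   `(v, a, b, n_obs, n_miss, flag)` per stratum.
#' @export
impute_scores <- function(K_fish, K_nf, H_nh = NULL, mode = 3L,
                          w_bound = 0.4, k = NULL) {
  mode <- as.integer(mode)
  if (mode == 1L && is.null(H_nh))
    stop("mode 1 requires a merged neighbour Hi-C matrix")
  if (mode != 1L) H_nh <- NULL
  n <- nrow(K_fish)
  if (mode == 1L && is.null(k)) k <- select_k(H_nh, K_fish)

  # global observed/neighbour ratio, for strata with no observed anchor
  obs_all <- is.finite(K_fish) & upper.tri(K_fish)
  nf_at_obs <- sum(K_nf[obs_all & is.finite(K_nf)])
  global_ratio <- if (nf_at_obs > 0) sum(K_fish[obs_all]) / nf_at_obs else 1

  K_out <- K_fish
  wt <- vector("list", n - 1L)
  for (v in seq_len(n - 1L)) {
    st <- normalize_stratum(K_fish, K_nf, H_nh, v)
    wb <- if (mode == 1L) wbound_schedule(v, k, w_bound) else 0
    fw <- fit_weights(st, wb, mode)
    miss <- !st$observed
    wt[[v]] <- data.frame(v = v, a = fw$a, b = fw$b,
                          n_obs = sum(st$observed), n_miss = sum(miss),
                          flag = fw$flag)
    if (!any(miss)) next

    p_imp <- if (mode == 1L)
      fw$a * st$p_nh_miss[miss] + fw$b * st$p_nf_miss[miss]
    else
      fw$b * st$p_nf_miss[miss]

    nf_tot <- st$s_nf_obs + st$s_nf_miss
    prop_nf <- if (nf_tot > 0) st$s_nf_obs / nf_tot else NA_real_
    if (mode == 1L) {
      nh_tot <- st$s_nh_obs + st$s_nh_miss
      prop_nh <- if (nh_tot > 0) st$s_nh_obs / nh_tot else NA_real_
      # each weight paired with its own modality's observed fraction
      prop <- fw$a * prop_nh + fw$b * prop_nf
      if (!is.finite(prop)) prop <- prop_nf
    } else {
      prop <- prop_nf
    }

    if (st$degenerate || !is.finite(prop) || prop <= 0) {
      s_imp <- global_ratio * st$s_nf_miss
    } else {
      s_imp <- st$s_fish_obs / prop - st$s_fish_obs
    }
    vals <- pmin(pmax(p_imp * s_imp, 0), 1)
    ij <- st$idx[miss, , drop = FALSE]
    K_out[ij] <- vals
    K_out[ij[, c(2L, 1L), drop = FALSE]] <- vals
  }
  diag(K_out) <- 1
  attr(K_out, "sigma") <- attr(K_fish, "sigma")
  list(K = K_out, weights = do.call(rbind, wt))
}
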