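#' Insulation profile of a proximity matrix
#'
#' The matrix is partitioned into consecutive fixed-size windows. For each
#' boundary between adjacent windows, `intra` is the mean off-diagonal
#' proximity within the two windows and `inter` the mean proximity between
#' them; the boundary score is `(intra - inter) / (intra + inter)`. Two fully
#' separated domains score 1; a featureless matrix scores 0. Missing entries
#' are ignored in the means.
#'
#' @param K Proximity matrix, `N >= 2 * window`.
#' @param window Window size in bins.
#' @return data.frame with `boundary` (bin index of the first bin of the
#'   right window), `intra`, `inter`, `score` (`NA` when `intra + inter = 0`),
#'   and `is_peak` (strict local maximum of the score profile).
#' @export
insulation_profile <- function(K, window) {
  n <- nrow(K)
  if (n < 2L * window) stop("matrix too small for the window size")
  nwin <- n %/% window
  starts <- (seq_len(nwin) - 1L) * window + 1L
  blocks <- lapply(starts, function(s) s:(s + window - 1L))
  fin_mean <- function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }
  res <- lapply(seq_len(nwin - 1L), function(b) {
    w1 <- blocks[[b]]; w2 <- blocks[[b + 1L]]
    within <- c(K[w1, w1][upper.tri(K[w1, w1])],
                K[w2, w2][upper.tri(K[w2, w2])])
    intra <- fin_mean(within)
    inter <- fin_mean(K[w1, w2])
    tot <- intra + inter
    score <- if (is.finite(tot) && tot != 0) (intra - inter) / tot else NA_real_
    data.frame(boundary = starts[b + 1L], intra = intra, inter = inter,
               score = score)
  })
  out <- do.call(rbind, res)
  s <- out$score
  out$is_peak <- vapply(seq_along(s), function(i) {
    isTRUE(s[i] > ifelse(i > 1L, s[i - 1L], -Inf)) &&
      isTRUE(s[i] > ifelse(i < length(s), s[i + 1L], -Inf))
  }, logical(1L))
  out
}

#' A/B compartment assignment from a proximity matrix
#'
#' The expected proximity at each bin separation is fitted by linear
#' regression of `log(mean K)` on `log(v)`; the observed matrix is divided by
#' the expected, a Pearson correlation matrix of the normalised matrix is
#' computed, and bins are split by the sign of its first principal component.
#' The sign is oriented so bin 1 is labelled `+` (biological A/B orientation
#' via gene density is out of scope).
#'
#' @param K Complete proximity matrix.
#' @return data.frame with `bin`, `pc1`, `compartment` (`"+"`/`"-"`).
#' @export
compartments <- function(K) {
  n <- nrow(K)
  sep <- abs(row(K) - col(K))
  mean_v <- vapply(seq_len(n - 1L), function(v) {
    x <- K[sep == v]
    mean(x[is.finite(x)])
  }, numeric(1L))
  ok <- is.finite(mean_v) & mean_v > 0
  if (sum(ok) < 2L) stop("not enough strata to fit an expected curve")
  cf <- stats::coef(stats::lm(log(mean_v[ok]) ~ log(which(ok))))
  expd <- matrix(1, n, n)
  pos <- sep > 0
  expd[pos] <- exp(cf[[1L]] + cf[[2L]] * log(sep[pos]))
  normd <- K / expd
  if (stats::sd(normd[upper.tri(normd)], na.rm = TRUE) < 1e-10)
    stop("degenerate (constant) matrix; compartments undefined")
  C <- suppressWarnings(stats::cor(normd, use = "pairwise.complete.obs"))
  if (any(!is.finite(C))) stop("correlation matrix has undefined entries")
  pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1L]
  if (pc1[1L] < 0) pc1 <- -pc1
  data.frame(bin = seq_len(n), pc1 = pc1,
             compartment = ifelse(pc1 >= 0, "+", "-"))
}

#' Contact-decay feature vector of a single matrix
#'
#' Fraction of the total signal found at each bin separation; the vector sums
#' to one (all-zero matrices return a zero vector with attribute
#' `zero_total`).
#'
#' @param M Contact or proximity matrix (missing entries count as 0).
#' @return Numeric vector of length `N - 1` over separations `1..N-1`.
#' @export
decay_features <- function(M) {
  n <- nrow(M)
  sep <- abs(row(M) - col(M))
  ut <- upper.tri(M)
  v <- vapply(seq_len(n - 1L), function(s) {
    x <- M[ut & sep == s]
    sum(x[is.finite(x)])
  }, numeric(1L))
  tot <- sum(v)
  if (tot == 0) {
    attr(v, "zero_total") <- TRUE
    return(v)
  }
  v / tot
}

#' Highly variable locus pairs across cells
#'
#' Coefficient of variation (sd / mean across cells) per upper-triangle locus
#' pair; the top fraction `q` by CV is selected. Constant pairs have CV 0 and
#' are never selected.
#'
#' @param mats Named list of matrices over the same loci.
#' @param q Fraction of pairs to keep (default top 20%).
#' @return Integer matrix of selected `(i, j)` pairs with a `cv` column.
#' @export
cv_features <- function(mats, q = 0.2) {
  ut <- which(upper.tri(mats[[1L]]), arr.ind = TRUE)
  vals <- vapply(mats, function(m) m[ut], numeric(nrow(ut)))
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  keep <- cv > 0
  ord <- order(cv, decreasing = TRUE)
  ord <- ord[seq_len(min(ceiling(q * nrow(ut)), sum(keep)))]
  cbind(i = ut[ord, 1L], j = ut[ord, 2L], cv = cv[ord])
}

#' PCA embedding of per-cell proximity matrices
#'
#' Upper triangles are flattened (missing entries set to 0 — a documented
#' caveat: at high missing rates this encodes the mask, which is exactly why
#' imputation improves clustering), normalised per cell, and reduced by PCA.
#'
#' @param mats Named list of matrices over the same loci.
#' @param dim Embedding dimensionality.
#' @param normalize Divide each cell's feature vector by its total, treating
#'   the proximity profile compositionally (the cell-to-cell pattern, not the
#'   overall signal level, is what distinguishes cell types; the level is a
#'   nuisance dominated by detection and estimation noise).
#' @return Cells x dim score matrix.
#' @export
pca_features <- function(mats, dim = 30L, normalize = TRUE) {
  ut <- upper.tri(mats[[1L]])
  feat <- t(vapply(mats, function(m) {
    x <- m[ut]
    x[!is.finite(x)] <- 0
    if (normalize && sum(x) > 0) x <- x / sum(x)
    x
  }, numeric(sum(ut))))
  ncomp <- min(dim, nrow(feat) - 1L, ncol(feat))
  emb <- stats::prcomp(feat, rank. = ncomp, center = TRUE)$x
  rownames(emb) <- names(mats)
  emb
}

#' Mean adjusted Rand index of repeated k-means
#'
#' Runs k-means `repetitions` times with seeded restarts and averages the
#' adjusted Rand index against the reference labels.
#'
#' @param features Cells x features matrix.
#' @param true_labels Reference labels, one per row.
#' @param k Number of clusters.
#' @param repetitions Number of k-means repetitions (default 4).
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @return Mean ARI; per-repetition values in attribute `per_rep`.
#' @export
kmeans_ari <- function(features, true_labels, k, repetitions = 4L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(features)) stop("more clusters than cells")
  ari <- vapply(seq_len(repetitions), function(r) {
    set.seed(seed + r)
    cl <- stats::kmeans(features, centers = k, nstart = 10L)$cluster
    mclust::adjustedRandIndex(cl, true_labels)
  }, numeric(1L))
  structure(mean(ari), per_rep = ari)
}

# pair span in bp, from bin start positions
.pair_span <- function(starts, i, j) abs(starts[j] - starts[i])

#' Call chromatin loops from a population of traces
#'
#' For every locus pair within a genomic span of `span_min` to `span_max`,
#' the spatial distances observed across cells are compared with the pooled
#' distances of the pair's local genomic neighbourhood (offsets within
#' `flank_bp`, the pair itself excluded) by a one-sided Welch t-test
#' (loop = closer than its neighbourhood). p-values are Benjamini-Hochberg
#' adjusted; candidates with `q <= fdr` are grouped into 8-connected clusters
#' of adjacent bin pairs and the lowest-q member of each cluster is the
#' summit.
#'
#' @param traces Named list of [locus_trace] of one cell type, same panel.
#' @param fdr FDR cutoff (default 0.1).
#' @param span_min,span_max Genomic span limits in bp.
#' @param flank_bp Half-width of the local neighbourhood in bp.
#' @return data.frame of tested pairs: `i`, `j` (bin indices), `start1`,
#'   `start2`, `t`, `p`, `q`, `candidate`, `cluster` (`NA` for
#'   non-candidates), `is_summit`.
#' @export
call_loops <- function(traces, fdr = 0.1, span_min = 1e5, span_max = 1e6,
                       flank_bp = 2.5e5) {
  if (length(traces) < 2L) stop("loop calling needs at least 2 cells")
  n <- nrow(traces[[1L]]$coords)
  starts <- traces[[1L]]$loci$start
  dist_list <- lapply(traces, pairwise_distances)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  span <- .pair_span(starts, ut[, 1L], ut[, 2L])
  keep <- span >= span_min & span <= span_max
  cand <- ut[keep, , drop = FALSE]
  if (!nrow(cand)) return(.empty_loops())
  # distances per pair across cells (all pairs: the neighbourhood sample may
  # reach outside the tested span range): pairs x cells
  D <- vapply(dist_list, function(d) d[ut], numeric(nrow(ut)))
  row_of <- matrix(0L, n, n)
  row_of[ut] <- seq_len(nrow(ut))
  bin_flank <- floor(flank_bp / stats::median(diff(starts)))
  offs <- expand.grid(di = -bin_flank:bin_flank, dj = -bin_flank:bin_flank)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]

  res <- lapply(seq_len(nrow(cand)), function(r) {
    a <- D[row_of[cand[r, 1L], cand[r, 2L]], ]
    a <- a[is.finite(a)]
    ni <- cand[r, 1L] + offs$di
    nj <- cand[r, 2L] + offs$dj
    ok <- ni >= 1L & nj <= n & ni < nj
    rows <- row_of[cbind(ni[ok], nj[ok])]
    rows <- rows[rows > 0L]
    b <- as.vector(D[rows, , drop = FALSE])
    b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(c(t = NA_real_, p = NA_real_))
    tt <- stats::t.test(a, b, alternative = "less")
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(i = cand[, 1L], j = cand[, 2L],
                    start1 = starts[cand[, 1L]], start2 = starts[cand[, 2L]],
                    t = res[, "t"], p = res[, "p"])
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$candidate <- !is.na(out$q) & out$q <= fdr
  out$cluster <- NA_integer_
  out$is_summit <- FALSE
  if (any(out$candidate)) {
    cl <- .cluster_pairs(out$i[out$candidate], out$j[out$candidate])
    out$cluster[out$candidate] <- cl
    for (g in unique(cl)) {
      rows <- which(out$candidate)[cl == g]
      out$is_summit[rows[which.min(out$q[rows])]] <- TRUE
    }
  }
  out
}

.empty_loops <- function() {
  data.frame(i = integer(), j = integer(), start1 = integer(),
             start2 = integer(), t = numeric(), p = numeric(), q = numeric(),
             candidate = logical(), cluster = integer(), is_summit = logical())
}

# 8-connected components of candidate bin pairs in (i, j) space
.cluster_pairs <- function(i, j) {
  n <- length(i)
  if (n == 1L) return(1L)
  adj <- abs(outer(i, i, `-`)) <= 1L & abs(outer(j, j, `-`)) <= 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Loop strength as centre-to-neighbourhood fold change
#'
#' Ratio of the central proximity to the mean proximity of the surrounding
#' `(2 flank + 1)^2` window (centre excluded), ignoring missing entries.
#'
#' @param K Proximity matrix.
#' @param i,j Loop anchor bin indices.
#' @param flank Flank half-width in bins (e.g. 250 kb worth).
#' @return Fold change, `NA` when the centre is missing or the flank carries
#'   no finite value.
#' @export
loop_fold_change <- function(K, i, j, flank) {
  n <- nrow(K)
  if (i - flank < 1L || j + flank > n || j - flank < 1L || i + flank > n)
    stop("loop flank extends beyond the matrix")
  centre <- K[i, j]
  if (!is.finite(centre)) return(NA_real_)
  win <- K[(i - flank):(i + flank), (j - flank):(j + flank)]
  win[flank + 1L, flank + 1L] <- NA_real_
  m <- mean(win[is.finite(win)])
  if (!is.finite(m) || m == 0) return(NA_real_)
  centre / m
}

#' Pairs with cell-type-specific proximity
#'
#' Minimal differential test: for each locus pair in the loop span range, a
#' two-sided Welch t-test of the spatial distances between the two cell
#' types, Benjamini-Hochberg adjusted across pairs.
#'
#' @param traces_by_type Named list of two (or more; first two are compared)
#'   lists of [locus_trace], each with at least 2 cells.
#' @param fdr FDR cutoff.
#' @param span_min,span_max Genomic span limits in bp.
#' @return data.frame `i`, `j`, `t`, `p`, `q`, `significant`.
#' @export
differential_loops <- function(traces_by_type, fdr = 0.1,
                               span_min = 1e5, span_max = 1e6) {
  if (length(traces_by_type) < 2L) stop("need at least 2 cell types")
  t1 <- traces_by_type[[1L]]; t2 <- traces_by_type[[2L]]
  if (length(t1) < 2L || length(t2) < 2L)
    stop("each cell type needs at least 2 cells")
  n <- nrow(t1[[1L]]$coords)
  starts <- t1[[1L]]$loci$start
  D1 <- lapply(t1, pairwise_distances)
  D2 <- lapply(t2, pairwise_distances)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  span <- .pair_span(starts, ut[, 1L], ut[, 2L])
  cand <- ut[span >= span_min & span <= span_max, , drop = FALSE]
  res <- apply(cand, 1L, function(ij) {
    a <- vapply(D1, function(d) d[ij[1L], ij[2L]], numeric(1L))
    b <- vapply(D2, function(d) d[ij[1L], ij[2L]], numeric(1L))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(c(t = NA_real_, p = NA_real_))
    tt <- stats::t.test(a, b)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  out <- data.frame(i = cand[, 1L], j = cand[, 2L],
                    t = res["t", ], p = res["p", ])
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q <= fdr
  out
}
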