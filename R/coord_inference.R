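#' Scale proximity scores to Poisson pseudo-counts
#'
#' Proximity scores in `[0, 1]` are scaled by `c` and rounded half-away-from-
#' zero, giving the integer "contact counts" that act as the Poisson random
#' variable during coordinate inference.
#'
#' @param K Proximity matrix, finite entries in `[0, 1]`.
#' @param c Integer scale (default 100).
#' @return Integer matrix `round(c * K)`.
#' @export
scale_to_counts <- function(K, c = 100L) {
  if (any(!is.finite(K))) stop("K must be complete before scaling")
  floor(c * K + 0.5)
}

# model pieces shared by objective and gradient --------------------------------

#' Build the Poisson coordinate-inference model
#'
#' Pairs entering the likelihood are all locus pairs with at least one
#' undetected endpoint: anchoring each free locus against the detected ones is
#' what makes the problem identifiable.
#'
#' @param trace A [locus_trace] with at least 2 detected loci.
#' @param K_imputed Complete proximity matrix for the trace.
#' @param sigma Kernel bandwidth (micrometres).
#' @param c Count scale, see [scale_to_counts()].
#' @return A list of class `poisson_model`: `counts`, `sigma`, `scale`,
#'   `anchors` (detected coordinates), `free` (undetected locus indices),
#'   `pairs` (index pairs in the likelihood).
#' @export
poisson_model <- function(trace, K_imputed, sigma, c = 100L) {
  free <- which(!trace$detected)
  n <- nrow(trace$coords)
  counts <- scale_to_counts(K_imputed, c)
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  touch <- ut[, 1L] %in% free | ut[, 2L] %in% free
  structure(list(counts = counts, sigma = sigma, scale = c,
                 anchors = trace$coords, free = free,
                 pairs = ut[touch, , drop = FALSE]),
            class = "poisson_model")
}

# assemble full coordinate matrix from the free-parameter vector
.fill_coords <- function(par, model) {
  X <- model$anchors
  X[model$free, ] <- matrix(par, ncol = 3L)
  X
}

#' Negative Poisson log-likelihood of free coordinates
#'
#' `sum over pairs of [lambda - k log lambda]` with
#' `lambda = c * exp(-d^2 / sigma^2)`; the constant `log k!` term is dropped
#' (it does not move the optimum). `lambda` is floored at `1e-10` inside the
#' logarithm so widely separated pairs stay finite.
#'
#' @param par Numeric vector of free coordinates (length `3 * n_free`,
#'   column-major x/y/z).
#' @param model A [poisson_model()].
#' @return Scalar objective value.
#' @export
neg_log_likelihood <- function(par, model) {
  if (any(!is.finite(par))) stop("non-finite coordinates")
  X <- .fill_coords(par, model)
  i <- model$pairs[, 1L]; j <- model$pairs[, 2L]
  d2 <- rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2)
  lam <- model$scale * exp(-d2 / model$sigma^2)
  k <- model$counts[model$pairs]
  sum(lam - k * log(pmax(lam, 1e-10)))
}

#' @rdname neg_log_likelihood
#' @details `neg_log_likelihood_grad` is the analytic gradient:
#'   `d/dX_i = sum_j (2 / sigma^2) (k_ij - lambda_ij) (X_i - X_j)` over pairs
#'   involving `i` (the `k/lambda` ratio cancels, so it is finite everywhere).
#' @export
neg_log_likelihood_grad <- function(par, model) {
  X <- .fill_coords(par, model)
  i <- model$pairs[, 1L]; j <- model$pairs[, 2L]
  diff <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  d2 <- rowSums(diff^2)
  lam <- model$scale * exp(-d2 / model$sigma^2)
  k <- model$counts[model$pairs]
  w <- (2 / model$sigma^2) * (k - lam)
  G <- matrix(0, nrow(X), 3L)
  for (ax in 1:3) {
    g <- w * diff[, ax]
    G[, ax] <- G[, ax] +
      tabulate2(i, g, nrow(X)) - tabulate2(j, g, nrow(X))
  }
  as.vector(G[model$free, , drop = FALSE])
}

# sum values by integer group (rowsum wrapper returning a dense vector)
tabulate2 <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Linear-interpolation baseline for undetected loci
#'
#' Each undetected locus is placed on the segment between its flanking
#' detected loci, weighted by genomic position; runs with no detected flank on
#' one side copy the nearest detected coordinate.
#'
#' @param trace A [locus_trace] with at least one detected locus.
#' @return A completed [locus_trace]; attribute `imputed` marks the filled
#'   loci.
#' @export
linear_interpolate <- function(trace) {
  det <- which(trace$detected)
  if (!length(det)) stop("no detected loci to interpolate from")
  X <- trace$coords
  g <- trace$loci$start
  for (ax in 1:3) {
    X[, ax] <- stats::approx(g[det], X[det, ax], xout = g,
                             rule = 2)$y
  }
  out <- trace
  out$coords <- X
  out$detected <- rep(TRUE, nrow(X))
  attr(out, "imputed") <- !trace$detected
  out
}

#' Infer 3D coordinates of undetected loci
#'
#' Free variables are the coordinates of the undetected loci only; detected
#' loci never move. Starting from the [linear_interpolate()] solution, the
#' negative Poisson log-likelihood is minimised by bounded L-BFGS-B with the
#' analytic gradient; box bounds are the detected-coordinate bounding box
#' expanded by 50% of its width on each side per axis.
#'
#' @param trace A [locus_trace].
#' @param K_imputed Complete proximity matrix (from [impute_scores()]).
#' @param sigma Kernel bandwidth used to build `K_imputed`.
#' @param c Count scale.
#' @param max_iter Iteration cap for the optimiser.
#' @param pgtol Projected-gradient tolerance.
#' @return Completed [locus_trace] with attribute `imputed`; traces with
#'   fewer than 2 detected loci are returned unchanged with a warning.
#' @export
infer_coordinates <- function(trace, K_imputed, sigma, c = 100L,
                              max_iter = 500L, pgtol = 1e-6) {
  if (sum(trace$detected) < 2L) {
    warning("fewer than 2 detected loci; trace returned unchanged",
            call. = FALSE)
    return(trace)
  }
  if (all(trace$detected)) {
    out <- trace
    attr(out, "imputed") <- rep(FALSE, nrow(trace$coords))
    return(out)
  }
  model <- poisson_model(trace, K_imputed, sigma, c)
  init <- linear_interpolate(trace)
  par0 <- as.vector(init$coords[model$free, , drop = FALSE])

  anch <- trace$coords[trace$detected, , drop = FALSE]
  lo <- apply(anch, 2L, min); hi <- apply(anch, 2L, max)
  width <- pmax(hi - lo, sigma)          # degenerate flat boxes get room
  lower <- rep(lo - 0.5 * width, each = length(model$free))
  upper <- rep(hi + 0.5 * width, each = length(model$free))
  par0 <- pmin(pmax(par0, lower), upper)

  fit <- stats::optim(par0, neg_log_likelihood, neg_log_likelihood_grad,
                      model = model, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, pgtol = pgtol))
  out <- trace
  out$coords[model$free, ] <- matrix(fit$par, ncol = 3L)
  out$detected <- rep(TRUE, nrow(out$coords))
  attr(out, "imputed") <- !trace$detected
  attr(out, "objective") <- fit$value
  out
}
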