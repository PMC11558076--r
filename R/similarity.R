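#' Orthogonal Procrustes alignment of two coordinate sets
#'
#' Finds the orthogonal matrix `R` (reflections permitted) and translation
#' that superpose point set `B` onto point set `A` by minimising the Frobenius
#' norm of the residual. The translation is the centroid offset; the rotation
#' comes from the singular value decomposition of the cross-covariance of the
#' centred sets. The aligned copy is `B* = (B - centroid(B)) R + centroid(A)`.
#'
#' @param A,B Numeric n x 3 matrices of matched points, all finite, n >= 3.
#' @param indices Optional locus indices recorded in the result (bookkeeping
#'   for overlap-restricted alignments).
#' @return An object of class `procrustes_alignment` with elements `rotation`
#'   (3 x 3 orthogonal), `translation` (`centroid(A) - centroid(B)`),
#'   `centroid_a`, `centroid_b`, `overlap_indices`, and `rmsd` of the aligned
#'   residual.
#' @examples
#' A <- matrix(rnorm(15), 5, 3)
#' th <- pi / 3
#' Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' fit <- procrustes_align(A, A %*% Rz + 1)
#' fit$rmsd  # ~0
#' @export
procrustes_align <- function(A, B, indices = seq_len(nrow(A))) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L)
    stop("A and B must be matched n x 3 coordinate sets")
  if (nrow(A) < 3L) stop("at least 3 matched points are required")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("coordinates must be finite")
  fit <- .procrustes(A, B)
  structure(c(fit, list(overlap_indices = indices)),
            class = "procrustes_alignment")
}

# SVD core, no n >= 3 gate (rmsd's 2-point analytic case is well-defined)
.procrustes <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  s <- svd(crossprod(Bc, Ac))
  R <- s$u %*% t(s$v)
  Bstar <- Bc %*% R
  list(rotation = R, translation = ca - cb, centroid_a = ca, centroid_b = cb,
       rmsd = sqrt(mean(rowSums((Ac - Bstar)^2))))
}

#' Apply a Procrustes alignment to a coordinate set
#'
#' @param alignment A `procrustes_alignment`.
#' @param B Coordinates to transform (n x 3).
#' @return The superposed coordinates `(B - centroid(B)) R + centroid(A)`.
#' @export
apply_alignment <- function(alignment, B) {
  sweep(sweep(as.matrix(B), 2L, alignment$centroid_b) %*% alignment$rotation,
        2L, alignment$centroid_a, `+`)
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat(sprintf("<procrustes_alignment> %d points, residual RMSD %.4g um\n",
              length(x$overlap_indices), x$rmsd))
  invisible(x)
}

#' Procrustes-aligned RMSD between two chromosome structures
#'
#' Root-mean-square deviation after optimal orthogonal superposition,
#' restricted to loci detected in both traces. Pairs whose both-detected
#' overlap falls below `min_overlap` loci are treated as incomparable and
#' return `NA`: a handful of shared points can always be superposed almost
#' exactly, so small overlaps would otherwise fake near-zero RMSD.
#'
#' @param A,B [locus_trace] objects over the same locus panel, or plain n x 3
#'   coordinate matrices (rows with `NA` count as undetected).
#' @param min_overlap Minimum number of both-detected loci.
#' @return RMSD in micrometres, or `NA_real_` when undefined.
#' @export
rmsd <- function(A, B, min_overlap = 10L) {
  ca <- if (inherits(A, "locus_trace")) A$coords else as.matrix(A)
  cb <- if (inherits(B, "locus_trace")) B$coords else as.matrix(B)
  if (nrow(ca) != nrow(cb))
    stop("traces have incompatible locus counts")
  ok <- apply(is.finite(ca), 1L, all) & apply(is.finite(cb), 1L, all)
  if (sum(ok) < max(2L, min_overlap)) return(NA_real_)
  .procrustes(ca[ok, , drop = FALSE], cb[ok, , drop = FALSE])$rmsd
}

#' Pairwise RMSD matrix over a set of traces
#'
#' @param traces Named list of [locus_trace] over the same panel.
#' @param min_overlap Passed to [rmsd()].
#' @return Symmetric matrix with `NA` diagonal and `NA` for incomparable
#'   pairs, dimnames taken from `traces`.
#' @export
rmsd_matrix <- function(traces, min_overlap = 10L) {
  n <- length(traces)
  m <- matrix(NA_real_, n, n, dimnames = list(names(traces), names(traces)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- rmsd(traces[[i]], traces[[j]], min_overlap)
    }
  }
  m
}

#' Mean square error between two proximity matrices
#'
#' Mean of squared entry differences over upper-triangle pairs finite in both
#' matrices (the denominator is the count of such pairs, `n(n-1)/2` when both
#' matrices are complete).
#'
#' @param KA,KB Proximity matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
proximity_mse <- function(KA, KB) {
  if (!identical(dim(KA), dim(KB))) stop("matrices differ in shape")
  ut <- upper.tri(KA)
  ok <- ut & is.finite(KA) & is.finite(KB)
  if (!any(ok)) stop("no pairs comparable in both matrices")
  mean((KA[ok] - KB[ok])^2)
}
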