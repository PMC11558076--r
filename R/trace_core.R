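#' Construct a chromatin trace for one chromosome copy
#'
#' A locus trace holds the ordered loci of a single chromosome copy in one
#' cell: genomic intervals (0-based half-open, BED convention) and 3D spatial
#' coordinates in micrometres. Loci with no detected signal carry `NA`
#' coordinates and `FALSE` in the detection mask; arithmetic never sees
#' sentinel values.
#'
#' @param cell_id Cell identifier (scalar character).
#' @param chrom Chromosome name.
#' @param copy_id Homolog label, e.g. `"0"`/`"1"`.
#' @param start,end Integer vectors of genomic interval bounds (bp), strictly
#'   increasing by `start`.
#' @param coords Numeric N x 3 matrix of (x, y, z) positions in micrometres;
#'   a row is either all-finite (detected) or all-`NA` (undetected). Rows with
#'   any missing component are treated as undetected.
#' @return An object of class `locus_trace`.
#' @examples
#' tr <- locus_trace("c1", "chr1", "0", c(0, 5e4), c(5e4, 1e5),
#'                   rbind(c(0, 0, 0), c(1, 1, 1)))
#' missing_rate(tr)
#' @export
locus_trace <- function(cell_id, chrom, copy_id, start, end, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L) stop("a locus trace needs at least 2 loci")
  if (length(start) != n || length(end) != n)
    stop("interval vectors and coordinate rows disagree in length")
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (is.unsorted(start, strictly = TRUE))
    stop("loci must be strictly increasing by genomic_start")
  detected <- apply(is.finite(coords), 1L, all)
  coords[!detected, ] <- NA_real_
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(cell_id = as.character(cell_id), chrom = as.character(chrom),
         copy_id = as.character(copy_id),
         loci = data.frame(start = as.integer(start), end = as.integer(end)),
         coords = coords, detected = detected),
    class = "locus_trace")
}

#' @export
print.locus_trace <- function(x, ...) {
  cat(sprintf("<locus_trace> cell %s, %s copy %s: %d loci, missing rate %.2f\n",
              x$cell_id, x$chrom, x$copy_id, nrow(x$coords), missing_rate(x)))
  invisible(x)
}

trace_id <- function(trace) {
  paste(trace$cell_id, trace$chrom, trace$copy_id, sep = "|")
}

#' Fraction of undetected loci in a trace
#'
#' @param trace A [locus_trace].
#' @return Fraction of loci with no detected coordinates, in `[0, 1]`.
#' @export
missing_rate <- function(trace) {
  stopifnot(inherits(trace, "locus_trace"))
  mean(!trace$detected)
}

#' Read chromatin traces from a tab-separated table
#'
#' Expects the columns `cell_id chrom copy_id locus_index genomic_start
#' genomic_end x y z`. An empty or `NaN` coordinate field marks the locus as
#' undetected. One [locus_trace] is built per `(cell_id, chrom, copy_id)`
#' combination; loci arriving out of genomic order are sorted with a warning.
#'
#' @param path Path to the TSV file.
#' @return Named list of [locus_trace] objects, keyed `cell|chrom|copy`.
#' @seealso [write_traces()] for the inverse; the pair round-trips losslessly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = list(cell_id = "character",
                                            chrom = "character",
                                            copy_id = "character"),
                          na.strings = c("", "NA", "NaN"))
  need <- c("cell_id", "chrom", "copy_id", "locus_index",
            "genomic_start", "genomic_end", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trace table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(is.na(df$cell_id) | is.na(df$genomic_start) | is.na(df$genomic_end))
  if (length(bad))
    stop("malformed trace row at line ", bad[1L] + 1L,
         " (missing identifier or interval)")
  key <- paste(df$cell_id, df$chrom, df$copy_id, sep = "|")
  groups <- split(seq_len(nrow(df)), key)

  # all copies of one chromosome must target the same probe panel
  grp_chrom <- vapply(strsplit(names(groups), "|", fixed = TRUE), `[`,
                      character(1L), 2L)
  nl <- tapply(lengths(groups), grp_chrom, function(x) length(unique(x)))
  if (any(nl > 1L))
    stop("inconsistent locus count across copies of the same chromosome")

  out <- lapply(groups, function(idx) {
    g <- df[idx, ]
    if (is.unsorted(g$genomic_start, strictly = TRUE)) {
      warning("loci out of genomic order in trace ", key[idx[1L]],
              "; sorting", call. = FALSE)
      g <- g[order(g$genomic_start), ]
    }
    locus_trace(g$cell_id[1L], g$chrom[1L], g$copy_id[1L],
                g$genomic_start, g$genomic_end,
                cbind(g$x, g$y, g$z))
  })
  out[order(names(out))]
}

#' Write chromatin traces to a tab-separated table
#'
#' @param traces List of [locus_trace] objects.
#' @param path Output path.
#' @param imputed_flags Optional named list (same names as `traces`) of logical
#'   vectors; when given, a provenance column `imputed` (0/1 per locus) is
#'   written.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, imputed_flags = NULL) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    n <- nrow(tr$coords)
    d <- data.frame(cell_id = tr$cell_id, chrom = tr$chrom,
                    copy_id = tr$copy_id, locus_index = seq_len(n) - 1L,
                    genomic_start = tr$loci$start, genomic_end = tr$loci$end,
                    x = tr$coords[, 1L], y = tr$coords[, 2L],
                    z = tr$coords[, 3L])
    if (!is.null(imputed_flags))
      d$imputed <- as.integer(imputed_flags[[names(traces)[i]]])
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Keep the better-detected homolog per cell and chromosome
#'
#' For each `(cell, chrom)` group the chromosome copy with the lowest missing
#' rate is retained (ties broken by lexicographically smallest `copy_id`);
#' retained copies whose missing rate still exceeds `max_missing` are dropped.
#'
#' @param traces Named list of [locus_trace].
#' @param max_missing Maximum tolerated missing rate for a kept copy.
#' @return Filtered named list.
#' @export
select_homolog <- function(traces, max_missing = 0.8) {
  if (!length(traces)) return(traces)
  grp <- vapply(traces, function(t) paste(t$cell_id, t$chrom, sep = "|"),
                character(1L))
  keep <- unlist(lapply(split(seq_along(traces), grp), function(idx) {
    rates <- vapply(traces[idx], missing_rate, numeric(1L))
    copies <- vapply(traces[idx], function(t) t$copy_id, character(1L))
    idx[order(rates, copies)][1L]
  }), use.names = FALSE)
  kept <- traces[sort(keep)]
  kept[vapply(kept, missing_rate, numeric(1L)) <= max_missing]
}

#' Drop traces with a missing rate above a threshold
#'
#' The inequality is strict: a trace at exactly the threshold is kept.
#'
#' @param traces Named list of [locus_trace].
#' @param threshold Missing-rate cutoff.
#' @return Filtered named list.
#' @export
drop_cells_by_missing <- function(traces, threshold = 0.8) {
  traces[vapply(traces, missing_rate, numeric(1L)) <= threshold]
}

#' Pairwise spatial distance matrix of a trace
#'
#' Euclidean distances between all locus pairs, in micrometres. Any pair
#' touching an undetected locus is `NA`.
#'
#' @param trace A [locus_trace].
#' @return Symmetric N x N numeric matrix with zero diagonal on detected loci.
#' @export
pairwise_distances <- function(trace) {
  stopifnot(inherits(trace, "locus_trace"))
  d <- as.matrix(stats::dist(trace$coords))
  dimnames(d) <- NULL
  d[!trace$detected, ] <- NA_real_
  d[, !trace$detected] <- NA_real_
  diag(d)[!trace$detected] <- NA_real_
  d
}

#' Estimate the proximity-kernel bandwidth
#'
#' The bandwidth sigma is the median (50th percentile) of all finite
#' off-diagonal upper-triangle distances, pooled over every matrix supplied.
#' Pooling scope (one cell versus a cell-type-by-chromosome pool) is the
#' caller's choice; the default is to pool everything given.
#'
#' @param distances A distance matrix or a list of them.
#' @return Scalar sigma in micrometres.
#' @export
estimate_sigma <- function(distances) {
  if (is.matrix(distances)) distances <- list(distances)
  vals <- unlist(lapply(distances, function(d) d[upper.tri(d)]))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite distances to estimate sigma from")
  s <- stats::median(vals)
  if (s <= 0) stop("sigma estimate is not positive")
  s
}

#' Transform distances into proximity scores
#'
#' Gaussian-kernel transform of a spatial distance matrix into `[0, 1]`:
#' `K = exp(-D^2 / sigma^2)`, or `K = 2^(-D^2 / sigma^2)` when
#' `half_decay = TRUE` so that a pair exactly `sigma` apart scores 0.5.
#' Missing distances propagate.
#'
#' @param D Distance matrix (from [pairwise_distances()]).
#' @param sigma Bandwidth in micrometres, positive.
#' @param half_decay Use base-2 decay instead of base-e.
#' @return Proximity matrix with attribute `sigma`.
#' @export
proximity <- function(D, sigma, half_decay = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive scalar")
  base <- if (half_decay) log(2) else 1
  K <- exp(-base * (D * D) / (sigma * sigma))
  attr(K, "sigma") <- sigma
  K
}

#' Read genomic bins from a 3-column BED file
#'
#' @param path BED path (chrom, start, end; 0-based half-open).
#' @return A data.frame with columns `chrom`, `start`, `end`, sorted and
#'   checked for overlaps.
#' @export
read_bins <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  b <- b[order(b$chrom, b$start), ]
  rownames(b) <- NULL
  same <- b$chrom[-1L] == b$chrom[-nrow(b)]
  if (any(same & b$start[-1L] < b$end[-nrow(b)]))
    stop("bins overlap")
  b
}

#' Write or read a dense matrix in the package's TSV dialect
#'
#' Dense tab-separated values with `L<index>` row/column headers; `NA` encodes
#' a missing entry.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` returns
#'   `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  dimnames(m) <- list(paste0("L", seq_len(nrow(m)) - 1L),
                      paste0("L", seq_len(ncol(m)) - 1L))
  utils::write.table(m, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  dimnames(m) <- NULL
  m
}
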