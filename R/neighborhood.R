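#' Cluster cells from RNA counts
#'
#' Standard single-cell recipe: total-count normalisation to the median
#' library size, `log(1 + x)`, PCA, a k-nearest-neighbour graph, and Louvain
#' community detection at a fixed seed. Precomputed labels, when supplied,
#' are returned verbatim and nothing is recomputed.
#'
#' @param expr Cells x genes nonnegative count matrix with unique rownames
#'   (cell ids).
#' @param n_components Number of principal components (reduced with a warning
#'   when fewer cells are available).
#' @param seed Integer seed for the community detection.
#' @param knn Neighbourhood size of the cell graph.
#' @param resolution Louvain resolution.
#' @param labels Optional precomputed labels (named by cell or in row order);
#'   returned unchanged.
#' @return Factor of cluster labels, named by cell id.
#' @export
cluster_rna <- function(expr, n_components = 30L, seed = 1L, knn = 15L,
                        resolution = 1, labels = NULL) {
  if (!is.null(labels)) {
    lab <- as.factor(labels)
    if (is.null(names(lab)) && !is.null(rownames(expr)))
      names(lab) <- rownames(expr)
    return(lab)
  }
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression counts must be nonnegative")
  n <- nrow(expr)
  if (n < 2L) stop("need at least 2 cells to cluster")
  lib <- rowSums(expr)
  lib[lib == 0] <- 1
  x <- log1p(expr / lib * stats::median(lib))
  ncomp <- min(n_components, n - 1L, ncol(x))
  if (ncomp < n_components)
    warning("reducing PCA dimensionality to ", ncomp, call. = FALSE)
  pcs <- stats::prcomp(x, rank. = ncomp, center = TRUE, scale. = FALSE)$x
  g <- .knn_graph(pcs, min(knn, n - 1L))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  lab <- factor(igraph::membership(comm))
  names(lab) <- rownames(expr)
  lab
}

# undirected kNN graph on rows of an embedding
.knn_graph <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, order(d[i, ])[seq_len(k)])
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Build the RMSD neighbor graph over FISH traces
#'
#' For each trace, candidate neighbours are the other traces of the same RNA
#' cluster and chromosome whose RMSD to it is defined; the `m` candidates with
#' smallest RMSD become its neighbour list (all of them when fewer than `m`
#' exist). Lists never contain the trace itself and never cross cluster
#' boundaries.
#'
#' @param traces Named list of [locus_trace].
#' @param labels Cluster label per trace (named by trace id, or by cell id, or
#'   in order). A single shared label reproduces the label-free mode.
#' @param m Neighbourhood size.
#' @param min_overlap Overlap gate passed to [rmsd()].
#' @return A named list (class `neighbor_graph`); each element is a data.frame
#'   with columns `id` and `similarity` (RMSD, ascending).
#' @export
fish_neighbor_graph <- function(traces, labels, m = 100L, min_overlap = 10L) {
  lab <- .match_labels(traces, labels)
  ids <- names(traces)
  chrom <- vapply(traces, function(t) t$chrom, character(1L))
  out <- stats::setNames(vector("list", length(traces)), ids)
  for (grp in split(seq_along(traces), paste(lab, chrom))) {
    rm <- rmsd_matrix(traces[grp], min_overlap)
    for (a in seq_along(grp)) {
      v <- stats::setNames(rm[a, ], colnames(rm))
      v <- v[is.finite(v)]
      v <- sort(v)[seq_len(min(m, length(v)))]
      out[[grp[a]]] <- data.frame(id = names(v), similarity = unname(v),
                                  stringsAsFactors = FALSE)
    }
  }
  structure(out, class = "neighbor_graph")
}

.match_labels <- function(traces, labels) {
  if (length(labels) == 1L) labels <- rep(labels, length(traces))
  if (!is.null(names(labels))) {
    ids <- names(traces)
    cells <- vapply(traces, function(t) t$cell_id, character(1L))
    key <- if (all(ids %in% names(labels))) ids else cells
    if (!all(key %in% names(labels)))
      stop("labels do not cover all traces")
    labels <- labels[key]
  }
  if (length(labels) != length(traces))
    stop("one label per trace is required")
  as.character(labels)
}

#' @export
print.neighbor_graph <- function(x, ...) {
  sizes <- vapply(x, nrow, integer(1L))
  cat(sprintf("<neighbor_graph> %d items, neighbour counts %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Merge proximity matrices over FISH neighbours
#'
#' Entrywise mean over the neighbours that carry a finite value at each entry
#' (measurement semantics: absent is missing, not zero). An entry is missing
#' in the merge only when it is missing in every neighbour. The trace's own
#' matrix never enters its average.
#'
#' @param graph A `neighbor_graph` from [fish_neighbor_graph()].
#' @param K Named list of proximity matrices, one per trace id.
#' @return Named list of merged matrices (`K_neighbor-FISH`); traces with an
#'   empty neighbour list get an all-`NA` matrix with attribute
#'   `empty_neighborhood = TRUE`.
#' @export
merge_fish_neighbors <- function(graph, K) {
  shape <- dim(K[[1L]])
  lapply(stats::setNames(names(graph), names(graph)), function(id) {
    nb <- graph[[id]]$id
    if (!length(nb)) {
      m <- matrix(NA_real_, shape[1L], shape[2L])
      attr(m, "empty_neighborhood") <- TRUE
      return(m)
    }
    acc <- matrix(0, shape[1L], shape[2L])
    cnt <- matrix(0L, shape[1L], shape[2L])
    for (j in nb) {
      kj <- K[[j]]
      ok <- is.finite(kj)
      acc[ok] <- acc[ok] + kj[ok]
      cnt <- cnt + ok
    }
    out <- acc / cnt
    out[cnt == 0L] <- NA_real_
    out
  })
}

#' Embed single-cell Hi-C contact matrices
#'
#' Features are `log(1 + count)` of the upper-triangle entries within a bin
#' separation of `d_max` (informative short-range contacts), reduced by PCA.
#'
#' @param contacts Named list of symmetric contact count matrices on shared
#'   bins.
#' @param dim Embedding dimensionality (reduced with a warning when more than
#'   the number of cells allows).
#' @param d_max Maximum bin separation entering the feature vector.
#' @return Cells x dim embedding matrix; all-zero cells are flagged in the
#'   attribute `zero_cells`.
#' @export
hic_embed <- function(contacts, dim = 30L, d_max = 30L) {
  n <- nrow(contacts[[1L]])
  sep <- abs(row(diag(n)) - col(diag(n)))
  sel <- upper.tri(diag(n)) & sep <= d_max
  feat <- t(vapply(contacts, function(h) log1p(h[sel]), numeric(sum(sel))))
  zero <- rowSums(feat) == 0
  ncomp <- min(dim, nrow(feat) - 1L, ncol(feat))
  if (ncomp < dim)
    warning("reducing Hi-C embedding dimensionality to ", ncomp, call. = FALSE)
  emb <- stats::prcomp(feat, rank. = ncomp, center = TRUE)$x
  rownames(emb) <- names(contacts)
  attr(emb, "zero_cells") <- names(contacts)[zero]
  emb
}

#' Nearest-neighbour graph in Hi-C embedding space
#'
#' @param embedding Cells x dim matrix from [hic_embed()], rownames = cell ids.
#' @param m Neighbourhood size; capped at the number of other cells.
#' @return A `neighbor_graph`: per cell, the `m` Euclidean nearest other
#'   cells, closest first.
#' @export
hic_neighbor_graph <- function(embedding, m = 10L) {
  n <- nrow(embedding)
  ids <- rownames(embedding)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  out <- lapply(seq_len(n), function(i) {
    o <- order(d[i, ])[seq_len(min(m, n - 1L))]
    data.frame(id = ids[o], similarity = d[i, o], stringsAsFactors = FALSE)
  })
  structure(stats::setNames(out, ids), class = "neighbor_graph")
}

#' Merge contact matrices over Hi-C neighbours
#'
#' Entrywise mean with count semantics: an absent contact is a zero, so every
#' entry of the merge is defined. A cell with no neighbours gets its own
#' matrix back with a warning.
#'
#' @param graph A `neighbor_graph` from [hic_neighbor_graph()].
#' @param contacts Named list of contact matrices.
#' @return Named list of merged matrices (`H_neighbor-scHi-C`).
#' @export
merge_hic_neighbors <- function(graph, contacts) {
  lapply(stats::setNames(names(graph), names(graph)), function(id) {
    nb <- graph[[id]]$id
    if (!length(nb)) {
      warning("cell ", id, " has no Hi-C neighbours; using its own matrix",
              call. = FALSE)
      return(contacts[[id]])
    }
    Reduce(`+`, contacts[nb]) / length(nb)
  })
}

#' Read a cell pairing table
#'
#' Tab-separated file with header `fish_cell_id hic_cell_id` (the pairing is
#' computed by an external cross-modal integration step and consumed here).
#'
#' @param path TSV path.
#' @return data.frame with character columns `fish_cell_id`, `hic_cell_id`.
#' @export
read_pairing <- function(path) {
  p <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("fish_cell_id", "hic_cell_id") %in% names(p)))
    stop("pairing table needs columns fish_cell_id and hic_cell_id")
  p
}

#' Join merged Hi-C matrices onto FISH cells through the pairing table
#'
#' @param pairing data.frame with `fish_cell_id`, `hic_cell_id` (one row per
#'   FISH cell; duplicates are an error).
#' @param fish_cells Character vector of FISH cell ids to resolve.
#' @param H_merged Named list of merged Hi-C matrices keyed by Hi-C cell id.
#' @return Named list over `fish_cells`; entries are merged Hi-C matrices, or
#'   `NULL` for unpaired cells (which fall back to FISH-only imputation, with
#'   a warning).
#' @export
attach_pairing <- function(pairing, fish_cells, H_merged) {
  if (anyDuplicated(pairing$fish_cell_id))
    stop("duplicate fish_cell_id rows in pairing table")
  dangling <- setdiff(pairing$hic_cell_id, names(H_merged))
  if (length(dangling))
    stop("pairing references unknown Hi-C cells: ",
         paste(utils::head(dangling, 3L), collapse = ", "))
  idx <- match(fish_cells, pairing$fish_cell_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " FISH cell(s) unpaired; they fall back to ",
            "FISH-only imputation", call. = FALSE)
  out <- lapply(idx, function(i) {
    if (is.na(i)) NULL else H_merged[[pairing$hic_cell_id[i]]]
  })
  stats::setNames(out, fish_cells)
}

#' Read per-cell Hi-C contact lists
#'
#' Each cell is a triplet TSV `bin_i bin_j count` (0-based bin indices,
#' header optional) over a shared bins table; matrices are symmetrised.
#'
#' @param paths Named character vector of triplet files (names = cell ids).
#' @param bins data.frame from [read_bins()] giving the bin count.
#' @return Named list of symmetric N x N count matrices.
#' @export
read_contacts <- function(paths, bins) {
  n <- nrow(bins)
  lapply(paths, function(p) {
    tri <- utils::read.table(p, header = .has_header(p))
    names(tri) <- c("bin_i", "bin_j", "count")
    m <- matrix(0, n, n)
    i <- tri$bin_i + 1L; j <- tri$bin_j + 1L
    if (any(i > n | j > n | i < 1L | j < 1L))
      stop("contact bin index out of range in ", p)
    m[cbind(i, j)] <- m[cbind(i, j)] + tri$count
    m[cbind(j, i)] <- m[cbind(i, j)]
    m
  })
}

.has_header <- function(path) {
  first <- readLines(path, n = 1L)
  grepl("bin_i", first, fixed = TRUE)
}
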