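#' Configuration of the synthetic multimodal generator
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: two cell types of 100 cells each over a 60-locus, 1 Mb
#' panel, with compartment-block structure strong enough that RNA clustering
#' and Hi-C/FISH agreement are unambiguous.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type FISH cells per type.
#' @param hic_cells_per_type Hi-C cells per type.
#' @param n_loci Loci per chromosome panel.
#' @param bin_bp Genomic bin size in bp.
#' @param chrom Chromosome name.
#' @param step_sd Polymer step standard deviation per axis (micrometres).
#' @param confinement AR(1) coefficient of the confined walk (1 = free walk).
#' @param block_size Compartment block length in loci.
#' @param block_shrink Factor pulling loci toward their compartment centroid
#'   (smaller = stronger compartmentalisation).
#' @param flip_blocks Number of compartment blocks that switch state in each
#'   cell type beyond the first: related subtypes share most of their
#'   compartment structure and differ in localized regions.
#' @param jitter_sd Per-cell, per-locus coordinate noise (micrometres).
#' @param dropout Baseline probability that a locus goes undetected.
#' @param locus_bias Optional per-locus dropout multiplier profile (length
#'   `n_loci`), mimicking probes with high cell-absence rates; `NULL` for
#'   uniform dropout.
#' @param n_genes,n_markers RNA panel size and markers per type.
#' @param rna_mean,rna_fold,rna_size Negative-binomial baseline mean, marker
#'   fold change, and dispersion size.
#' @param hic_depth Expected Poisson count at proximity 1.
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_types = 2L, cells_per_type = 100L,
                         hic_cells_per_type = 100L, n_loci = 60L,
                         bin_bp = 1e6, chrom = "chr1",
                         step_sd = 0.8, confinement = 0.75,
                         block_size = 10L, block_shrink = 0.5,
                         flip_blocks = 2L,
                         jitter_sd = 0.3, dropout = 0.1, locus_bias = NULL,
                         n_genes = 50L, n_markers = 10L, rna_mean = 5,
                         rna_fold = 8, rna_size = 10, hic_depth = 5,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_types >= 1L, cells_per_type >= 1L, n_loci >= 4L,
            dropout >= 0, dropout <= 1, block_shrink > 0, block_shrink <= 1,
            is.numeric(seed))
  structure(cfg, class = "synth_config")
}

# random 3x3 rotation (special orthogonal) via QR of a Gaussian matrix
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q * sign(diag(qr.R(qr_)))[col(Q)]
}

# confined AR(1) random-walk chain shared by all cell types
.base_chain <- function(cfg) {
  n <- cfg$n_loci
  X <- matrix(0, n, 3L)
  sd_loc <- cfg$step_sd / sqrt(1 - cfg$confinement^2 + 1e-12)
  X[1L, ] <- stats::rnorm(3L, sd = sd_loc)
  for (i in 2:n)
    X[i, ] <- cfg$confinement * X[i - 1L, ] +
      stats::rnorm(3L, sd = cfg$step_sd)
  X
}

# type backbone: the shared chain under a type-specific compartment-block
# attraction (cell types of one organism share most 3D organisation;
# differences are localised block switches)
.type_backbone <- function(cfg, base, type) {
  n <- cfg$n_loci
  X <- base
  blocks <- ((seq_len(n) - 1L) %/% cfg$block_size)
  nb <- max(blocks) + 1L
  # shared alternating A/B baseline; each further type switches a small set
  # of blocks (related subtypes share most compartments, differences are
  # localized)
  comp <- blocks %% 2L
  if (type > 1L && cfg$flip_blocks > 0L) {
    fl <- (((type - 2L) * cfg$flip_blocks + seq_len(cfg$flip_blocks) - 1L)
           %% nb)
    comp[blocks %in% fl] <- 1L - comp[blocks %in% fl]
  }
  for (lab in unique(comp)) {
    sel <- comp == lab
    ctr <- colMeans(X[sel, , drop = FALSE])
    X[sel, ] <- sweep(sweep(X[sel, , drop = FALSE], 2L, ctr) *
                        cfg$block_shrink, 2L, ctr, `+`)
  }
  attr(X, "compartment") <- comp
  X
}

.jittered_copy <- function(backbone, jitter_sd) {
  n <- nrow(backbone)
  X <- backbone + matrix(stats::rnorm(3L * n, sd = jitter_sd), n, 3L)
  X %*% .random_rotation() +
    matrix(stats::rnorm(3L), n, 3L, byrow = TRUE)
}

#' Generate a synthetic multimodal dataset bundle
#'
#' Per cell type, a confined random-walk backbone with a type-specific
#' compartment-block pattern; per FISH cell, a jittered, randomly oriented
#' copy of the backbone with uniform (optionally locus-biased) dropout; per
#' Hi-C cell, Poisson contact counts with rate proportional to the Gaussian
#' proximity of an independent jitter of the same backbone; RNA counts are
#' negative-binomial with type-specific marker genes; the pairing table links
#' each FISH cell to a same-type Hi-C cell.
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_bundle` with `truth` (complete traces),
#'   `traces` (post-dropout), `labels` (type per FISH cell), `rna` (cells x
#'   genes counts), `contacts` (per Hi-C cell), `hic_labels`, `pairing`,
#'   `bins`, `config`.
#' @export
generate_multimodal <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_loci
  starts <- as.integer((seq_len(n) - 1L) * cfg$bin_bp)
  ends <- as.integer(starts + cfg$bin_bp)
  bins <- data.frame(chrom = cfg$chrom, start = starts, end = ends)
  bias <- if (is.null(cfg$locus_bias)) rep(1, n) else cfg$locus_bias

  truth <- list(); traces <- list(); labels <- character(0)
  contacts <- list(); hic_labels <- character(0)
  pairing <- NULL
  rna_rows <- list()

  marker_sets <- lapply(seq_len(cfg$n_types), function(t)
    ((t - 1L) * cfg$n_markers + 1L):(t * cfg$n_markers))

  base <- .base_chain(cfg)
  for (t in seq_len(cfg$n_types)) {
    backbone <- .type_backbone(cfg, base, t)
    type_lab <- paste0("type", t)

    for (i in seq_len(cfg$cells_per_type)) {
      cell <- sprintf("F%d_%03d", t, i)
      X <- .jittered_copy(backbone, cfg$jitter_sd)
      tr_true <- locus_trace(cell, cfg$chrom, "0", starts, ends, X)
      p_drop <- pmin(cfg$dropout * bias, 0.95)
      drop <- stats::runif(n) < p_drop
      Xobs <- X; Xobs[drop, ] <- NA_real_
      truth[[trace_id(tr_true)]] <- tr_true
      traces[[trace_id(tr_true)]] <-
        locus_trace(cell, cfg$chrom, "0", starts, ends, Xobs)
      labels[cell] <- type_lab

      mu <- rep(cfg$rna_mean, cfg$n_genes)
      mu[marker_sets[[t]]] <- cfg$rna_mean * cfg$rna_fold
      rna_rows[[cell]] <- stats::rnbinom(cfg$n_genes, mu = mu,
                                         size = cfg$rna_size)
    }

    for (i in seq_len(cfg$hic_cells_per_type)) {
      cell <- sprintf("H%d_%03d", t, i)
      Xh <- .jittered_copy(backbone, cfg$jitter_sd)
      D <- as.matrix(stats::dist(Xh))
      sig <- stats::median(D[upper.tri(D)])
      K <- exp(-(D * D) / (sig * sig))
      lam <- cfg$hic_depth * K
      H <- matrix(0, n, n)
      ut <- upper.tri(H)
      H[ut] <- stats::rpois(sum(ut), lam[ut])
      H <- H + t(H)
      contacts[[cell]] <- H
      hic_labels[cell] <- type_lab
    }

    pairing <- rbind(pairing, data.frame(
      fish_cell_id = sprintf("F%d_%03d", t, seq_len(cfg$cells_per_type)),
      hic_cell_id = sprintf("H%d_%03d", t,
                            ((seq_len(cfg$cells_per_type) - 1L) %%
                               cfg$hic_cells_per_type) + 1L)))
  }

  rna <- do.call(rbind, rna_rows)
  colnames(rna) <- sprintf("gene%03d", seq_len(cfg$n_genes))
  structure(list(truth = truth, traces = traces, labels = labels,
                 rna = rna, contacts = contacts, hic_labels = hic_labels,
                 pairing = pairing, bins = bins, config = cfg),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synth_bundle> %d FISH traces (%d types, %d loci), ",
                     "%d Hi-C cells, %d genes\n"),
              length(x$traces), x$config$n_types, x$config$n_loci,
              length(x$contacts), ncol(x$rna)))
  invisible(x)
}

#' Mask detected loci to target missing rates
#'
#' The simulation protocol for benchmarking: traces whose missing rate is
#' already at or above `pre_filter` are excluded; each remaining trace is
#' copied once per target rate with additional detected loci masked uniformly
#' at random (without replacement) until the overall missing fraction reaches
#' the target (nearest achievable count). Ground truth is the unmasked input;
#' masking never resurrects a locus. Deterministic under `seed`.
#'
#' @param traces Named list of [locus_trace].
#' @param rates Target overall missing rates.
#' @param pre_filter Only traces with missing rate strictly below this enter.
#' @param seed Integer seed.
#' @return List with `truth` (the retained input traces) and `masked`, a
#'   named list over `rate_<r>` of masked trace lists.
#' @export
mask_traces <- function(traces, rates = c(0.5, 0.6, 0.7, 0.8),
                        pre_filter = 0.3, seed = 1L) {
  keep <- vapply(traces, missing_rate, numeric(1L)) < pre_filter
  kept <- traces[keep]
  set.seed(seed)
  masked <- lapply(rates, function(r) {
    lapply(kept, function(tr) {
      n <- nrow(tr$coords)
      target <- round(r * n)
      cur <- sum(!tr$detected)
      if (target < cur) {
        warning("target rate ", r, " below current missing rate of trace ",
                trace_id(tr), "; skipping", call. = FALSE)
        return(tr)
      }
      extra <- sample(which(tr$detected), target - cur)
      out <- tr
      out$coords[extra, ] <- NA_real_
      out$detected[extra] <- FALSE
      out
    })
  })
  names(masked) <- paste0("rate_", rates)
  list(truth = kept, masked = masked)
}

#' Write a synthetic bundle to disk in the package's text formats
#'
#' Traces as the trace TSV dialect, bins as 3-column BED, RNA as a dense CSV,
#' contacts as per-cell `bin_i bin_j count` triplet TSVs, the pairing and
#' labels as TSVs, plus a `manifest.tsv` listing every emitted file with the
#' generator seed.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "contacts"), showWarnings = FALSE)
  paths <- c(traces = file.path(dir, "traces.tsv"),
             truth = file.path(dir, "truth.tsv"),
             bins = file.path(dir, "bins.bed"),
             rna = file.path(dir, "rna.csv"),
             labels = file.path(dir, "labels.tsv"),
             pairing = file.path(dir, "pairing.tsv"))
  write_traces(bundle$traces, paths["traces"])
  write_traces(bundle$truth, paths["truth"])
  utils::write.table(bundle$bins, paths["bins"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(bundle$rna, paths["rna"])
  utils::write.table(data.frame(cell_id = names(bundle$labels),
                                label = unname(bundle$labels)),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$pairing, paths["pairing"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cpaths <- vapply(names(bundle$contacts), function(id) {
    p <- file.path(dir, "contacts", paste0(id, ".tsv"))
    h <- bundle$contacts[[id]]
    ut <- which(upper.tri(h, diag = TRUE) & h > 0, arr.ind = TRUE)
    utils::write.table(data.frame(bin_i = ut[, 1L] - 1L,
                                  bin_j = ut[, 2L] - 1L,
                                  count = h[ut]),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1L))
  manifest <- data.frame(
    key = c(names(paths), names(cpaths), "seed"),
    path = c(paths, cpaths, as.character(bundle$config$seed)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read an expression matrix from dense CSV or MatrixMarket triplets
#'
#' @param path `.csv` (cells x genes, first column = cell ids) or `.mtx`
#'   (cells x genes triplets; companion `<path>.rownames` /
#'   `<path>.colnames` files supply ids when present).
#' @return Dense cells x genes matrix.
#' @export
read_expression <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (file.exists(rn)) rownames(m) <- readLines(rn)
    if (file.exists(cn)) colnames(m) <- readLines(cn)
    return(m)
  }
  as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
}
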