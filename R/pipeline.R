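#' Impute a set of chromatin traces
#'
#' The package's central fitting function. Runs the three-step procedure over
#' a set of chromosome copies:
#'
#' 1. *Neighbourhoods* — traces are converted to Gaussian proximity matrices;
#'    structurally similar copies are found by Procrustes RMSD within RNA
#'    cluster boundaries (mode 1-2) or over all copies (mode 3), and their
#'    matrices averaged. Mode 1 additionally embeds single-cell Hi-C,
#'    averages each cell's Hi-C neighbours, and joins them to FISH cells
#'    through the pairing table.
#' 2. *Score imputation* — per genomic-distance stratum, a constrained
#'    least-squares blend of the neighbour sources fills the missing locus
#'    pairs ([impute_scores()]).
#' 3. *Coordinate inference* — undetected loci are placed by maximising a
#'    Poisson log-likelihood anchored on the detected loci
#'    ([infer_coordinates()]).
#'
#' @param traces Named list of [locus_trace] over a common locus panel.
#' @param mode 1 (FISH + RNA + Hi-C), 2 (FISH + RNA), or 3 (FISH only).
#' @param labels Cell-type labels (named by cell or trace id). Modes 1-2 use
#'   them to restrict neighbourhoods; when `NULL`, they are computed from
#'   `rna` by [cluster_rna()].
#' @param rna Cells x genes count matrix (modes 1-2 when `labels` is `NULL`).
#' @param contacts Named list of single-cell Hi-C contact matrices (mode 1).
#' @param pairing FISH-to-Hi-C cell pairing data.frame (mode 1).
#' @param sigma Proximity bandwidth in micrometres; `NULL` estimates it as
#'   the median of all observed distances ([estimate_sigma()]).
#' @param m_fish Number of FISH neighbours (default 100).
#' @param m_hic Number of Hi-C neighbours (default 10).
#' @param w_bound Hi-C weight bound inside the informative range (default
#'   0.4).
#' @param k Informative Hi-C range; `NULL` selects it per cell by
#'   [select_k()].
#' @param min_overlap RMSD overlap gate ([rmsd()]).
#' @param scale Poisson count scale ([scale_to_counts()]).
#' @param half_decay Proximity kernel convention ([proximity()]).
#' @param infer_coords Run step 3 (set `FALSE` to stop after score
#'   imputation).
#' @param max_iter Optimiser iteration cap per trace.
#' @param seed Seed for RNA clustering.
#' @param keep_merged Keep the merged neighbour matrices in the result
#'   (needed by [residuals.trace_impute()]; off by default to save memory).
#' @return An object of class `trace_impute` with elements `traces`
#'   (completed), `scores` (imputed proximity matrices), `raw_scores`,
#'   `weights` (per-trace, per-stratum data.frame), `labels`, `sigma`,
#'   `mode`, `graph`, and `call`.
#' @examples
#' cfg <- synth_config(cells_per_type = 8, hic_cells_per_type = 8,
#'                     n_loci = 20, seed = 7)
#' b <- generate_multimodal(cfg)
#' fit <- trace_impute(b$traces, mode = 3, m_fish = 5, min_overlap = 5)
#' fit
#' head(coef(fit))
#' @export
trace_impute <- function(traces, mode = 3L, labels = NULL, rna = NULL,
                         contacts = NULL, pairing = NULL, sigma = NULL,
                         m_fish = 100L, m_hic = 10L, w_bound = 0.4, k = NULL,
                         min_overlap = 10L, scale = 100L, half_decay = FALSE,
                         infer_coords = TRUE, max_iter = 500L, seed = 1L,
                         keep_merged = FALSE) {
  cl <- match.call()
  mode <- as.integer(mode)
  if (!mode %in% 1:3) stop("mode must be 1, 2 or 3")
  if (mode == 1L && (is.null(contacts) || is.null(pairing)))
    stop("mode 1 requires single-cell Hi-C contacts and a pairing table ",
         "(modes 2-3 run without them)")
  if (mode %in% 1:2 && is.null(labels) && is.null(rna))
    stop("modes 1-2 need cell-type labels or an RNA count matrix")

  D <- lapply(traces, pairwise_distances)
  if (is.null(sigma)) sigma <- estimate_sigma(D)
  K <- lapply(D, proximity, sigma = sigma, half_decay = half_decay)

  lab <- if (mode == 3L) {
    stats::setNames(rep("all", length(traces)), names(traces))
  } else if (!is.null(labels)) {
    stats::setNames(.match_labels(traces, labels), names(traces))
  } else {
    rl <- cluster_rna(rna, seed = seed)
    stats::setNames(.match_labels(traces, rl), names(traces))
  }

  graph <- fish_neighbor_graph(traces, lab, m = m_fish,
                               min_overlap = min_overlap)
  K_nf <- merge_fish_neighbors(graph, K)

  H_per_trace <- NULL
  if (mode == 1L) {
    emb <- hic_embed(contacts)
    hg <- hic_neighbor_graph(emb, m = m_hic)
    H_merged <- merge_hic_neighbors(hg, contacts)
    cells <- vapply(traces, function(t) t$cell_id, character(1L))
    H_by_cell <- attach_pairing(pairing, unique(cells), H_merged)
    H_per_trace <- stats::setNames(H_by_cell[cells], names(traces))
  }

  scores <- vector("list", length(traces))
  weights <- vector("list", length(traces))
  completed <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    id <- names(traces)[i]
    Hi <- if (mode == 1L) H_per_trace[[i]] else NULL
    eff_mode <- if (mode == 1L && is.null(Hi)) 2L else mode
    res <- impute_scores(K[[i]], K_nf[[i]], Hi, mode = eff_mode,
                         w_bound = w_bound, k = k)
    scores[[i]] <- res$K
    weights[[i]] <- cbind(trace = id, res$weights)
    completed[[i]] <- if (infer_coords)
      infer_coordinates(traces[[i]], res$K, sigma, c = scale,
                        max_iter = max_iter)
    else traces[[i]]
  }
  names(scores) <- names(completed) <- names(traces)

  structure(list(traces = completed, scores = scores, raw_scores = K,
                 weights = do.call(rbind, weights), labels = lab,
                 sigma = sigma, mode = mode, graph = graph,
                 merged = if (keep_merged) K_nf else NULL,
                 call = cl),
            class = "trace_impute")
}

#' @export
print.trace_impute <- function(x, ...) {
  cat(sprintf("Chromatin trace imputation, mode %d\n", x$mode))
  cat(sprintf("  %d traces, sigma = %.3f um\n", length(x$traces), x$sigma))
  mr <- vapply(names(x$raw_scores), function(id)
    mean(!is.finite(x$raw_scores[[id]][upper.tri(x$raw_scores[[id]])])),
    numeric(1L))
  cat(sprintf("  mean missing pair fraction before imputation: %.2f\n",
              mean(mr)))
  invisible(x)
}

#' @export
summary.trace_impute <- function(object, ...) {
  w <- object$weights
  s <- list(mode = object$mode, sigma = object$sigma,
            n_traces = length(object$traces),
            n_clusters = length(unique(object$labels)),
            mean_a = mean(w$a), mean_b = mean(w$b),
            flagged_strata = sum(w$flag))
  class(s) <- "summary.trace_impute"
  s
}

#' @export
print.summary.trace_impute <- function(x, ...) {
  cat(sprintf(paste0("Trace imputation summary (mode %d)\n",
                     "  traces: %d  clusters: %d  sigma: %.3f um\n",
                     "  mean Hi-C weight a: %.3f  mean FISH weight b: %.3f\n",
                     "  degenerate strata (sentinel weights): %d\n"),
              x$mode, x$n_traces, x$n_clusters, x$sigma,
              x$mean_a, x$mean_b, x$flagged_strata))
  invisible(x)
}

#' @export
#' @describeIn trace_impute Per-trace, per-stratum fitted mixing weights.
coef.trace_impute <- function(object, ...) object$weights

#' @export
#' @describeIn trace_impute The imputed (complete) proximity matrices.
fitted.trace_impute <- function(object, ...) object$scores

#' Stratum-model residuals on observed locus pairs
#'
#' For each trace and genomic-distance stratum, the difference between the
#' observed normalised proximity profile and the fitted blend of the
#' neighbour profiles. Requires the fit to have been run with
#' `keep_merged = TRUE`.
#'
#' @param object A `trace_impute` fit.
#' @param ... Unused.
#' @return Named list (per trace) of numeric residual vectors over observed
#'   upper-triangle pairs.
#' @export
residuals.trace_impute <- function(object, ...) {
  if (is.null(object$merged))
    stop("refit with keep_merged = TRUE to compute stratum residuals")
  lapply(stats::setNames(names(object$raw_scores),
                         names(object$raw_scores)), function(id) {
    K <- object$raw_scores[[id]]
    Knf <- object$merged[[id]]
    w <- object$weights[object$weights$trace == id, ]
    unlist(lapply(w$v, function(v) {
      st <- normalize_stratum(K, Knf, NULL, v)
      b <- w$b[w$v == v]
      st$p_fish[st$observed] - b * st$p_nf_obs[st$observed]
    }))
  })
}

#' @export
plot.trace_impute <- function(x, trace = 1L, which = c("imputed", "raw"),
                              ...) {
  which <- match.arg(which)
  m <- if (which == "imputed") x$scores[[trace]] else x$raw_scores[[trace]]
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), m[, rev(seq_len(n))],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "locus", ylab = "locus",
                  main = sprintf("%s proximity (%s)", which,
                                 names(x$scores)[trace]), ...)
  invisible(x)
}

#' Evaluate an imputation against ground truth
#'
#' Mean Procrustes RMSD between each completed trace and its ground-truth
#' structure, and mean proximity-score MSE between the imputed and the
#' truth-derived proximity matrices.
#'
#' @param truth Named list of complete ground-truth [locus_trace].
#' @param completed Named list of completed traces (same names).
#' @param scores Named list of imputed proximity matrices, or `NULL` to
#'   derive them from `completed`.
#' @param sigma Bandwidth for the truth-side proximity transform.
#' @return data.frame with one row: `mean_rmsd`, `mean_mse`, `n_traces`.
#' @export
evaluate_imputation <- function(truth, completed, scores = NULL, sigma) {
  ids <- names(completed)
  if (is.null(scores))
    scores <- lapply(completed, function(tr)
      proximity(pairwise_distances(tr), sigma))
  rmsds <- vapply(ids, function(id)
    rmsd(truth[[id]], completed[[id]]), numeric(1L))
  mses <- vapply(ids, function(id) {
    Kt <- proximity(pairwise_distances(truth[[id]]), sigma)
    proximity_mse(Kt, scores[[id]])
  }, numeric(1L))
  data.frame(mean_rmsd = mean(rmsds, na.rm = TRUE),
             mean_mse = mean(mses, na.rm = TRUE),
             n_traces = length(ids))
}

#' Linear-interpolation baseline over a trace set
#'
#' @param traces Named list of [locus_trace].
#' @return Named list of completed traces.
#' @export
interpolate_all <- function(traces) lapply(traces, linear_interpolate)

#' Run the full pipeline on a bundle directory
#'
#' Reads the inputs written by [write_bundle()] (traces, optional labels/RNA,
#' optional contacts + pairing, optional ground truth), runs
#' [trace_impute()], writes the completed traces, imputed matrices and —
#' when ground truth is present — an evaluation report in both TSV and JSON.
#'
#' @param input_dir Directory containing `traces.tsv` and companions.
#' @param out_dir Output directory.
#' @param mode Imputation mode.
#' @param seed Seed.
#' @param ... Further arguments to [trace_impute()].
#' @return The evaluation data.frame (or `NULL` without ground truth),
#'   invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, mode = 3L, seed = 1L, ...) {
  traces <- read_traces(file.path(input_dir, "traces.tsv"))
  labels <- NULL; rna <- NULL; contacts <- NULL; pairing <- NULL
  lp <- file.path(input_dir, "labels.tsv")
  if (file.exists(lp)) {
    ld <- utils::read.delim(lp, colClasses = "character")
    labels <- stats::setNames(ld$label, ld$cell_id)
  }
  rp <- file.path(input_dir, "rna.csv")
  if (is.null(labels) && file.exists(rp)) rna <- read_expression(rp)
  if (mode == 1L) {
    pairing <- read_pairing(file.path(input_dir, "pairing.tsv"))
    bins <- read_bins(file.path(input_dir, "bins.bed"))
    cdir <- file.path(input_dir, "contacts")
    cfiles <- list.files(cdir, pattern = "\\.tsv$", full.names = TRUE)
    contacts <- read_contacts(
      stats::setNames(cfiles, sub("\\.tsv$", "", basename(cfiles))), bins)
  }
  fit <- trace_impute(traces, mode = mode, labels = labels, rna = rna,
                      contacts = contacts, pairing = pairing, seed = seed,
                      ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  imp_flags <- lapply(fit$traces, function(t) {
    f <- attr(t, "imputed")
    if (is.null(f)) rep(FALSE, nrow(t$coords)) else f
  })
  write_traces(fit$traces, file.path(out_dir, "completed_traces.tsv"),
               imputed_flags = imp_flags)
  utils::write.table(fit$weights, file.path(out_dir, "stratum_weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- NULL
  tp <- file.path(input_dir, "truth.tsv")
  if (file.exists(tp)) {
    truth <- read_traces(tp)
    report <- evaluate_imputation(truth[names(fit$traces)], fit$traces,
                                  fit$scores, fit$sigma)
    utils::write.table(report, file.path(out_dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf(
      '{"mean_rmsd": %.10g, "mean_mse": %.10g, "n_traces": %d, "seed": %d, "mode": %d}',
      report$mean_rmsd, report$mean_mse, report$n_traces,
      as.integer(seed), as.integer(mode)),
      file.path(out_dir, "evaluation.json"))
  }
  invisible(report)
}
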