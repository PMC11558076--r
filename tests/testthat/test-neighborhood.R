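test_that("rna clustering separates well-separated expression blobs", {
  set.seed(21)
  n <- 40
  mu <- rbind(rep(c(50, 2), each = 10), rep(c(2, 50), each = 10))
  expr <- t(vapply(rep(1:2, each = n / 2), function(t)
    rpois(20, mu[t, ]), numeric(20)))
  rownames(expr) <- paste0("c", seq_len(n))
  lab <- cluster_rna(expr, n_components = 5, seed = 3)
  truth <- rep(1:2, each = n / 2)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1.0)
})

test_that("precomputed labels pass through and isotropic data stays together", {
  expr <- matrix(rpois(60, 5), 10, 6, dimnames = list(paste0("c", 1:10), NULL))
  given <- setNames(rep(c("a", "b"), 5), rownames(expr))
  expect_identical(as.character(cluster_rna(expr, labels = given)),
                   unname(rep(c("a", "b"), 5)))
  set.seed(22)
  iso <- matrix(rpois(300, 20), 30, 10,
                dimnames = list(paste0("c", 1:30), NULL))
  expect_warning(lab <- cluster_rna(iso, n_components = 30, seed = 4, knn = 10),
                 "reducing")
  expect_lte(length(unique(lab)), 3)
})

test_that("fish neighbor graph ranks rigid copies first and respects labels", {
  set.seed(23)
  X <- matrix(rnorm(36), 12, 3)
  tA <- make_trace(X, cell = "A")
  tB <- make_trace(X %*% random_rotation(1) + 1, cell = "B")  # rigid copy
  tC <- make_trace(matrix(rnorm(36), 12, 3), cell = "C")
  tD <- make_trace(matrix(rnorm(36), 12, 3), cell = "D")
  traces <- list(tA, tB, tC, tD)
  names(traces) <- vapply(traces, traceimpute:::trace_id, character(1))
  lab <- setNames(c("x", "x", "x", "y"), names(traces))

  g <- fish_neighbor_graph(traces, lab, m = 1, min_overlap = 5)
  expect_identical(g[["A|chr1|0"]]$id, "B|chr1|0")
  # no self edges anywhere, no cross-label edges
  for (id in names(g)) {
    expect_false(id %in% g[[id]]$id)
    expect_true(all(lab[g[[id]]$id] == lab[id]))
  }
  # singleton cluster gets an empty list
  expect_identical(nrow(g[["D|chr1|0"]]), 0L)
})

test_that("fish neighbor merge averages available values only", {
  g <- structure(list(t1 = data.frame(id = c("t2", "t3", "t4"),
                                      similarity = 1:3)),
                 class = "neighbor_graph")
  mk <- function(v12, v13) {
    m <- matrix(NA_real_, 3, 3)
    m[1, 2] <- m[2, 1] <- v12
    m[1, 3] <- m[3, 1] <- v13
    m
  }
  K <- list(t1 = mk(9, 9), t2 = mk(0.2, NA), t3 = mk(0.4, NA),
            t4 = mk(NA, 0.9))
  merged <- merge_fish_neighbors(g, K)$t1
  expect_equal(merged[1, 2], 0.3)    # mean of the two finite neighbours
  expect_equal(merged[1, 3], 0.9)    # present in one of three
  expect_true(is.na(merged[2, 3]))   # missing in all
  # the cell's own matrix (value 9) never contributes
  expect_true(all(merged[is.finite(merged)] <= 1))

  empty <- structure(list(t1 = data.frame(id = character(),
                                          similarity = numeric())),
                     class = "neighbor_graph")
  out <- merge_fish_neighbors(empty, K)$t1
  expect_true(all(is.na(out)))
  expect_true(attr(out, "empty_neighborhood"))
})

test_that("merging identical neighbours reproduces the matrix and grows with m", {
  set.seed(24)
  m0 <- matrix(runif(16), 4, 4)
  g <- structure(list(a = data.frame(id = c("b", "c"), similarity = 1:2)),
                 class = "neighbor_graph")
  out <- merge_fish_neighbors(g, list(a = m0 * 0, b = m0, c = m0))$a
  expect_equal(out, m0)

  # more neighbours can only add coverage, never remove it
  K <- lapply(1:6, function(i) {
    m <- matrix(runif(16), 4, 4)
    m[sample(16, 6)] <- NA
    m
  })
  names(K) <- paste0("t", 1:6)
  cover <- function(m) sum(is.finite(m))
  g1 <- structure(list(t1 = data.frame(id = "t2", similarity = 1)),
                  class = "neighbor_graph")
  g3 <- structure(list(t1 = data.frame(id = c("t2", "t3", "t4"),
                                       similarity = 1:3)),
                  class = "neighbor_graph")
  expect_gte(cover(merge_fish_neighbors(g3, K)$t1),
             cover(merge_fish_neighbors(g1, K)$t1))
})

test_that("hic embedding is deterministic per cell and separates decay regimes", {
  set.seed(25)
  n <- 12
  sep <- abs(row(diag(n)) - col(diag(n)))
  mkcell <- function(rate) {
    lam <- 20 * exp(-sep / rate)
    m <- matrix(rpois(n * n, lam), n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  }
  fast <- lapply(1:8, function(i) mkcell(1.5))
  slow <- lapply(1:8, function(i) mkcell(6))
  contacts <- c(fast, slow)
  names(contacts) <- paste0("h", seq_along(contacts))
  contacts$h17 <- contacts$h1  # exact duplicate

  expect_warning(emb <- hic_embed(contacts, dim = 30), "reducing")
  expect_equal(emb["h17", ], emb["h1", ])
  # first component linearly separates the two decay regimes
  pc1 <- emb[paste0("h", 1:16), 1]
  expect_true(max(pc1[1:8]) < min(pc1[9:16]) ||
              min(pc1[1:8]) > max(pc1[9:16]))
})

test_that("hic neighbor graph and merge behave on identical and degenerate input", {
  emb <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(5, 5))
  g <- hic_neighbor_graph(emb, m = 1)
  expect_identical(g$a$id, "b")
  expect_identical(g$b$id, "a")

  contacts <- list(a = matrix(2, 3, 3), b = matrix(4, 3, 3),
                   c = matrix(9, 3, 3))
  g2 <- structure(list(c = data.frame(id = c("a", "b"), similarity = 1:2)),
                  class = "neighbor_graph")
  expect_equal(merge_hic_neighbors(g2, contacts)$c, matrix(3, 3, 3))

  lone <- structure(list(a = data.frame(id = character(),
                                        similarity = numeric())),
                    class = "neighbor_graph")
  expect_warning(out <- merge_hic_neighbors(lone, contacts), "no Hi-C")
  expect_equal(out$a, contacts$a)
  # m larger than the population uses all others
  g3 <- hic_neighbor_graph(emb, m = 10)
  expect_identical(nrow(g3$a), 2L)
})

test_that("pairing join resolves cells, falls back, and rejects bad tables", {
  H <- list(h1 = matrix(1, 2, 2), h2 = matrix(2, 2, 2))
  p <- data.frame(fish_cell_id = c("f1", "f2"), hic_cell_id = c("h2", "h1"))
  out <- attach_pairing(p, c("f1", "f2"), H)
  expect_equal(out$f1, H$h2)
  expect_equal(out$f2, H$h1)

  expect_warning(out2 <- attach_pairing(p, c("f1", "f3"), H), "unpaired")
  expect_null(out2$f3)

  expect_error(attach_pairing(rbind(p, p[1, ]), "f1", H), "duplicate")
  bad <- data.frame(fish_cell_id = "f1", hic_cell_id = "nope")
  expect_error(attach_pairing(bad, "f1", H), "unknown Hi-C")
})

test_that("contact triplets and pairing tables read back correctly", {
  dir <- withr::local_tempdir()
  bins <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(10, 20, 30))
  bp <- file.path(dir, "bins.bed")
  write.table(bins, bp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  b <- read_bins(bp)
  expect_equal(b$start, c(0L, 10L, 20L))

  cp <- file.path(dir, "cell1.tsv")
  writeLines(c("bin_i\tbin_j\tcount", "0\t1\t3", "1\t2\t5", "0\t0\t2"), cp)
  h <- read_contacts(c(cell1 = cp), b)$cell1
  expect_equal(h[1, 2], 3)
  expect_equal(h[2, 1], 3)
  expect_equal(h[3, 2], 5)
  expect_equal(h[1, 1], 2)

  pp <- file.path(dir, "pairing.tsv")
  writeLines(c("fish_cell_id\thic_cell_id", "f1\tcell1"), pp)
  expect_identical(read_pairing(pp)$hic_cell_id, "cell1")
})
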