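fixture_predictor_files <- function(n = 5, seed = 71) {
  fx <- gen_localization_fixture(ceiling(n / 2), floor(n / 2), seed = seed)
  dir <- tempfile("pred")
  dir.create(dir)
  keratinscreen:::write_predictor_files(fx$features, dir)
  list(dir = dir, features = fx$features)
}

test_that("three predictor files fuse into one 14-feature vector per protein", {
  fp <- fixture_predictor_files(5)
  fused <- parse_predictor_outputs(file.path(fp$dir, "psortb.tsv"),
                                   file.path(fp$dir, "cello.tsv"),
                                   file.path(fp$dir, "signalp.tsv"))
  expect_equal(nrow(fused), 5)
  expect_equal(ncol(fused) - 1L, 14)
  expect_setequal(names(fused)[-1], localization_feature_names())
  # SignalP derivation: possibility = SP+TAT+LIPO, intracellular = 1 - it
  expect_equal(fused$signalp_possibility,
               fused$signalp_sp + fused$signalp_tat + fused$signalp_lipo)
  expect_equal(fused$signalp_intracellular, 1 - fused$signalp_possibility)
  # SignalP's four probabilities sum to 1 (within write/read rounding)
  expect_true(all(abs(fused$signalp_sp + fused$signalp_tat +
                        fused$signalp_lipo + fused$signalp_other - 1)
                  < 1e-5))
})

test_that("an OTHER=1 SignalP row derives zero possibility; missing proteins error", {
  ps <- write_tmp(c("SeqID\tCytoplasmic_Score\tCytoplasmicMembrane_Score\tCellwall_Score\tExtracellular_Score",
                    "P1\t8.0\t1.0\t0.5\t0.5"))
  ce <- write_tmp(c("SeqID\tCytoplasmic\tMembrane\tCellWall\tExtracellular",
                    "P1\t4.0\t0.5\t0.2\t0.3"))
  sp <- write_tmp(c("# SignalP-5.0", "# ID\tPrediction\t...",
                    "P1\tOTHER\t0\t0\t0\t1.0\t"))
  fused <- parse_predictor_outputs(ps, ce, sp)
  expect_equal(fused$signalp_possibility, 0)
  expect_equal(fused$signalp_intracellular, 1)

  ce_missing <- write_tmp(c("SeqID\tCytoplasmic\tMembrane\tCellWall\tExtracellular",
                            "P2\t4.0\t0.5\t0.2\t0.3"))
  expect_error(parse_predictor_outputs(ps, ce_missing, sp), "P1|P2")
})

test_that("fused table path reads the same features as the raw dialects", {
  fp <- fixture_predictor_files(6)
  fused <- read_fused_features(file.path(fp$dir, "fused_features.tsv"))
  raw <- parse_predictor_outputs(file.path(fp$dir, "psortb.tsv"),
                                 file.path(fp$dir, "cello.tsv"),
                                 file.path(fp$dir, "signalp.tsv"))
  m <- match(fused$id, raw$id)
  for (col in localization_feature_names()) {
    expect_equal(fused[[col]], raw[[col]][m], tolerance = 1e-3)
  }
})

test_that("embedding z-scores features, orders variance ratios and is seeded", {
  fx <- gen_localization_fixture(30, 30, seed = 81)
  cfg <- pipeline_config(tsne_perplexity = 10, tsne_iterations = 250,
                         random_seed = 7)
  emb <- embed_features(fx$features, cfg)
  evr <- emb$explained_variance_ratio
  expect_true(all(evr >= 0 & evr <= 1))
  expect_true(all(diff(evr) <= 1e-12))
  expect_equal(sum(evr), 1, tolerance = 1e-9)
  expect_true(all(emb$tsne >= 0 & emb$tsne <= 1))
  # z-scoring: internal scale leaves each column mean 0, sd 1
  X <- as.matrix(fx$features[, localization_feature_names()])
  Z <- scale(X[, apply(X, 2, stats::sd) > 0])
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, stats::sd) - 1) < 1e-9))
  # determinism
  emb2 <- embed_features(fx$features, cfg)
  expect_identical(emb$tsne, emb2$tsne)
  # too few points is an error
  expect_error(embed_features(fx$features[1:4, ], cfg), "at least 5")
})

test_that("collinear features give PC1 ratio 1; zero-variance columns drop with warning", {
  n <- 12
  base <- seq_len(n)
  X <- data.frame(id = sprintf("P%02d", 1:n))
  for (j in seq_len(14)) X[[localization_feature_names()[j]]] <- base * j
  class(X) <- c("localization_features", "data.frame")
  cfg <- pipeline_config(tsne_perplexity = 3, tsne_iterations = 50,
                         random_seed = 1)
  emb <- suppressWarnings(embed_features(X, cfg))
  expect_equal(emb$explained_variance_ratio[1], 1, tolerance = 1e-9)

  X$psortb_wall <- 1  # constant column
  expect_warning(embed_features(X, cfg), "zero-variance")
})

test_that("t-SNE separates well-separated blobs farther than their internal radius", {
  set.seed(91)
  n <- 100
  X <- rbind(matrix(stats::rnorm(n * 4, 0, 0.3), n, 4),
             matrix(stats::rnorm(n * 4, 6, 0.3), n, 4))
  Y <- tsne_exact(X, perplexity = 30, iterations = 400, seed = 3)
  c1 <- colMeans(Y[1:n, ]); c2 <- colMeans(Y[(n + 1):(2 * n), ])
  between <- sqrt(sum((c1 - c2)^2))
  r1 <- stats::quantile(sqrt(rowSums(sweep(Y[1:n, ], 2, c1)^2)), 0.95)
  r2 <- stats::quantile(sqrt(rowSums(sweep(Y[(n + 1):(2 * n), ], 2,
                                           c2)^2)), 0.95)
  expect_gt(between, max(r1, r2))
})

test_that("DBSCAN geometry: far blobs, isolated noise, identical points", {
  set.seed(92)
  blob <- function(cx, cy, n) cbind(stats::runif(n, cx, cx + 0.02),
                                    stats::runif(n, cy, cy + 0.02))
  X <- rbind(blob(0, 0, 50), blob(0.9, 0.9, 50))
  lab <- dbscan_euclidean(X, eps = 0.05, min_samples = 4)
  expect_equal(length(unique(lab)), 2)
  expect_false(any(lab == -1))
  expect_equal(unname(table(lab)[1]), 50L)

  X2 <- rbind(X, c(0.5, 0.5))   # isolated point
  lab2 <- dbscan_euclidean(X2, eps = 0.05, min_samples = 4)
  expect_equal(lab2[101], -1L)

  X3 <- matrix(0.3, nrow = 10, ncol = 2)   # all identical
  lab3 <- dbscan_euclidean(X3, eps = 0.05, min_samples = 4)
  expect_equal(length(unique(lab3)), 1)
  expect_false(any(lab3 == -1))
})

test_that("t-SNE group labels are renumbered by size and order-invariant", {
  fx <- gen_localization_fixture(60, 30, seed = 93)
  cfg <- pipeline_config(tsne_perplexity = 15, tsne_iterations = 400,
                         random_seed = 2)
  emb <- embed_features(fx$features, cfg)
  gr <- cluster_tsne(emb, eps = 0.05, min_samples = 4)
  sizes <- vapply(gr$groups, length, integer(1))
  expect_true(all(diff(sizes) <= 0))   # decreasing
  expect_equal(names(gr$groups), as.character(seq_along(gr$groups) - 1L))

  # permuting the coordinate rows leaves the renumbered labels identical
  perm <- sample(length(emb$id))
  emb_p <- emb
  emb_p$id <- emb$id[perm]
  emb_p$tsne <- emb$tsne[perm, , drop = FALSE]
  gr_p <- cluster_tsne(emb_p, eps = 0.05, min_samples = 4)
  expect_identical(gr_p$labels[emb$id], gr$labels[emb$id])
})

test_that("group composition table follows the category-by-group layout", {
  recs <- protein_set(c("K1", "K2", "Q1", "Q2", "Q3", "N1"),
                      c("panel", "panel", "G11C", "G11C", "CHD11",
                        "panel"),
                      c("functional_keratinase", "functional_keratinase",
                        "query", "query", "query", "non_keratinase"),
                      rep("MKVL", 6))
  gr <- structure(list(labels = stats::setNames(
    c(0L, 0L, 0L, 1L, 1L, -1L), recs$id),
    groups = list(`0` = c("K1", "K2", "Q1"), `1` = c("Q2", "Q3")),
    n_groups = 2L), class = "tsne_groups")
  comp <- tsne_group_composition(gr, recs, linked_ids = "Q1")
  expect_equal(comp$tsne_group_0[comp$category == "functional_keratinase"],
               2L)
  expect_equal(comp$tsne_group_0[comp$category == "keratinase_linked_G11C"],
               1L)
  expect_equal(comp$tsne_group_1[comp$category == "three_strain_G11C"], 1L)
  expect_equal(comp$tsne_group_1[comp$category == "three_strain_CHD11"],
               1L)
})
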