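#' Names of the 14 fused localization features
#'
#' Four compartment scores from PSORTb, four from CELLO (cytoplasmic,
#' cytoplasmic-membrane, cell-wall, extracellular), and six from
#' SignalP 5 (SP(Sec/SPI), TAT(Tat/SPI), LIPO(Sec/SPII), OTHER, plus the
#' two derived features: intracellular = OTHER-probability and
#' signal-peptide possibility = SP + TAT + LIPO).
#'
#' @return Character vector of length 14.
#' @export
localization_feature_names <- function() {
  c("psortb_cytoplasmic", "psortb_membrane", "psortb_wall",
    "psortb_extracellular",
    "cello_cytoplasmic", "cello_membrane", "cello_wall",
    "cello_extracellular",
    "signalp_sp", "signalp_tat", "signalp_lipo", "signalp_other",
    "signalp_intracellular", "signalp_possibility")
}

read_score_table <- function(path, required, label) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file '%s' lacks column(s): %s", label, path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Parse the three localization predictors into the fused feature matrix
#'
#' Accepted dialects:
#' * PSORTb tab summary with columns `SeqID`, `Cytoplasmic_Score`,
#'   `CytoplasmicMembrane_Score`, `Cellwall_Score`,
#'   `Extracellular_Score` (further columns such as the final call are
#'   ignored; "unknown" compartments are never read).
#' * CELLO score table with columns `SeqID`, `Cytoplasmic`, `Membrane`,
#'   `CellWall`, `Extracellular`.
#' * SignalP 5 tabular output (gram-positive): comment lines starting
#'   `#`, then `ID <tab> Prediction <tab> SP(Sec/SPI) <tab>
#'   TAT(Tat/SPI) <tab> LIPO(Sec/SPII) <tab> OTHER [<tab> CS ...]`.
#'
#' The two derived SignalP features are signal-peptide possibility
#' `SP + TAT + LIPO` and intracellular `1 - (SP + TAT + LIPO)`.
#' A protein must appear in all three files; no imputation is done.
#'
#' @param psortb_path,cello_path,signalp_path Input files.
#' @return data.frame of class `"localization_features"`: `id` plus the
#'   14 numeric columns of [localization_feature_names()].
#' @export
parse_predictor_outputs <- function(psortb_path, cello_path, signalp_path) {
  ps <- read_score_table(psortb_path,
                         c("SeqID", "Cytoplasmic_Score",
                           "CytoplasmicMembrane_Score", "Cellwall_Score",
                           "Extracellular_Score"), "PSORTb")
  ce <- read_score_table(cello_path,
                         c("SeqID", "Cytoplasmic", "Membrane", "CellWall",
                           "Extracellular"), "CELLO")
  sp_lines <- readLines(signalp_path)
  sp_lines <- sp_lines[!startsWith(sp_lines, "#") & nzchar(sp_lines)]
  sp_parts <- strsplit(sp_lines, "\t", fixed = TRUE)
  if (any(lengths(sp_parts) < 6L)) {
    stop("SignalP file '", signalp_path,
         "' must have >= 6 tab-separated columns per record line")
  }
  sp <- data.frame(
    SeqID = vapply(sp_parts, `[[`, "", 1L),
    sp = as.numeric(vapply(sp_parts, `[[`, "", 3L)),
    tat = as.numeric(vapply(sp_parts, `[[`, "", 4L)),
    lipo = as.numeric(vapply(sp_parts, `[[`, "", 5L)),
    other = as.numeric(vapply(sp_parts, `[[`, "", 6L)),
    stringsAsFactors = FALSE)

  ids <- unique(c(ps$SeqID, ce$SeqID, sp$SeqID))
  miss <- lapply(list(PSORTb = ps$SeqID, CELLO = ce$SeqID,
                      SignalP = sp$SeqID),
                 function(have) setdiff(ids, have))
  miss <- miss[lengths(miss) > 0]
  if (length(miss)) {
    stop("protein(s) missing from predictor file(s): ",
         paste(vapply(names(miss), function(n) {
       sprintf("%s: %s", n, paste(utils::head(miss[[n]], 5), collapse = ","))
     }, ""), collapse = "; "))
  }
  mp <- match(ids, ps$SeqID); mc <- match(ids, ce$SeqID)
  ms <- match(ids, sp$SeqID)
  poss <- sp$sp[ms] + sp$tat[ms] + sp$lipo[ms]
  out <- data.frame(
    id = ids,
    psortb_cytoplasmic = ps$Cytoplasmic_Score[mp],
    psortb_membrane = ps$CytoplasmicMembrane_Score[mp],
    psortb_wall = ps$Cellwall_Score[mp],
    psortb_extracellular = ps$Extracellular_Score[mp],
    cello_cytoplasmic = ce$Cytoplasmic[mc],
    cello_membrane = ce$Membrane[mc],
    cello_wall = ce$CellWall[mc],
    cello_extracellular = ce$Extracellular[mc],
    signalp_sp = sp$sp[ms], signalp_tat = sp$tat[ms],
    signalp_lipo = sp$lipo[ms], signalp_other = sp$other[ms],
    signalp_intracellular = 1 - poss,
    signalp_possibility = poss,
    stringsAsFactors = FALSE)
  validate_localization_features(out)
  class(out) <- c("localization_features", "data.frame")
  out
}

#' Read a pre-fused 14-feature score table
#'
#' Alternative to the three raw predictor formats: a TSV whose first
#' column is the protein id followed by the 14 feature columns (named as
#' in [localization_feature_names()]).
#'
#' @param path TSV file.
#' @return A `localization_features` data.frame.
#' @export
read_fused_features <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1] <- "id"
  missing <- setdiff(localization_feature_names(), names(df))
  if (length(missing)) {
    stop("fused feature table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- df[, c("id", localization_feature_names())]
  validate_localization_features(out)
  class(out) <- c("localization_features", "data.frame")
  out
}

validate_localization_features <- function(df) {
  vals <- as.matrix(df[, localization_feature_names()])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("localization features must be finite numerics")
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id in localization features: ",
         df$id[duplicated(df$id)][1])
  }
  invisible(df)
}

#' Write the fused feature table
#' @param features A `localization_features` data.frame.
#' @param path Output TSV.
#' @export
write_fused_features <- function(features, path) {
  write_stage_tsv(as.data.frame(features), path)
}

# ---- t-SNE (exact, O(n^2)) -------------------------------------------------

# Per-point precision calibration: binary search beta so that the
# conditional distribution has the target perplexity.
tsne_p_matrix <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < .Machine$double.xmin) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding
#'
#' Classic t-SNE with exact (quadratic) gradients: perplexity-calibrated
#' input affinities, early exaggeration (factor 12 for the first quarter
#' of the iterations, at most 250), adaptive gains, momentum 0.5 then
#' 0.8, and the auto learning rate `max(n / (4 * 12), 50)` — a fixed
#' rate of 200 catapults points out of their clusters on small inputs,
#' fragmenting clusters irrecoverably. Initialization is random Gaussian
#' from the seed. Identical input, perplexity and seed give identical
#' coordinates.
#'
#' @param X Numeric matrix (observations x features), already scaled.
#' @param perplexity Target perplexity (must be < number of rows).
#' @param iterations Gradient-descent iterations (default 1000).
#' @param seed Integer seed.
#' @return n x 2 coordinate matrix.
#' @export
tsne_exact <- function(X, perplexity = 30, iterations = 1000L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity >= n) stop("perplexity must be smaller than n")
  P <- tsne_p_matrix(X, perplexity)
  exag_iters <- min(250L, max(1L, iterations %/% 4L))
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    eta <- max(n / (4 * 12), 50)
    for (it in seq_len(iterations)) {
      mult <- if (it <= exag_iters) 12 else 1
      momentum <- if (it <= 20L) 0.5 else 0.8
      # low-dimensional affinities (t-distribution kernel)
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (mult * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

min_max_normalize <- function(Y) {
  apply(Y, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) rep(0.5, length(col))
    else (col - rng[1]) / diff(rng)
  })
}

#' Embed localization features (PCA + t-SNE)
#'
#' Features are z-scored per column (zero-variance columns are dropped
#' with a warning), PCA is computed by eigendecomposition of the
#' covariance of the standardized matrix (so, the correlation
#' structure), with loadings = eigenvectors scaled by the square root of
#' their eigenvalues, and the exact t-SNE of [tsne_exact()] is run with
#' the configured perplexity, iteration count and seed. Both coordinate
#' sets are min-max normalized to the unit square.
#'
#' @param features A `localization_features` data.frame.
#' @param config A [pipeline_config()] (perplexity, iterations, seed).
#' @return list of class `"embedding_result"`: `id`, `pca` (n x 2),
#'   `explained_variance_ratio` (all components), `loadings`
#'   (feature x component, first two scaled eigenvectors), `tsne`
#'   (n x 2 in [0,1]^2), `dropped_features`.
#' @export
embed_features <- function(features, config = pipeline_config()) {
  X <- as.matrix(features[, localization_feature_names()])
  rownames(X) <- features$id
  n <- nrow(X)
  if (n < 5) stop("embedding needs at least 5 proteins (got ", n, ")")
  if (n < 4 * config$tsne_perplexity) {
    warning(sprintf(
      "only %d proteins for perplexity %g; recommend n >= 4*perplexity",
      n, config$tsne_perplexity))
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  eig <- eigen(stats::cov(Z), symmetric = TRUE)
  evr <- pmax(eig$values, 0) / sum(pmax(eig$values, 0))
  pcs <- Z %*% eig$vectors[, 1:2, drop = FALSE]
  loadings <- eig$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[1:2], 0)), 2)
  dimnames(loadings) <- list(colnames(Z), c("PC1", "PC2"))
  Yt <- tsne_exact(Z, perplexity = config$tsne_perplexity,
                   iterations = config$tsne_iterations,
                   seed = config$random_seed)
  out <- list(id = features$id,
              pca = min_max_normalize(pcs),
              explained_variance_ratio = evr,
              loadings = loadings,
              tsne = min_max_normalize(Yt),
              dropped_features = dropped)
  dimnames(out$pca) <- list(features$id, c("PC1", "PC2"))
  dimnames(out$tsne) <- list(features$id, c("tSNE1", "tSNE2"))
  class(out) <- "embedding_result"
  out
}

# ---- DBSCAN ----------------------------------------------------------------

#' DBSCAN on a coordinate matrix
#'
#' Euclidean DBSCAN; the eps-neighbourhood includes the point itself
#' (min_samples counts it, as in the common library convention). Border
#' points are attached to the cluster of their nearest core point, which
#' makes the labelling independent of input order. Returns raw cluster
#' labels (arbitrary positive integers) with noise as `-1`.
#'
#' @param X n x d numeric matrix.
#' @param eps Neighbourhood radius.
#' @param min_samples Core-point threshold.
#' @return Integer vector of labels (`-1` = noise).
#' @export
dbscan_euclidean <- function(X, eps, min_samples) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- D <= eps
  core <- rowSums(nb) >= min_samples
  labels <- rep(-1L, n)
  if (!any(core)) return(labels)
  # connected components of the core-core eps-graph
  core_idx <- which(core)
  gcore <- nb[core_idx, core_idx, drop = FALSE]
  comp <- rep(0L, length(core_idx))
  cur <- 0L
  for (s in seq_along(core_idx)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nbrs <- which(gcore[v, ] & comp == 0L)
      comp[nbrs] <- cur
      queue <- c(queue, nbrs)
    }
  }
  labels[core_idx] <- comp
  # border points: nearest core point within eps
  for (i in which(!core)) {
    dc <- D[i, core_idx]
    if (min(dc) <= eps) labels[i] <- comp[which.min(dc)]
  }
  labels
}

#' Cluster the t-SNE plane into localization groups
#'
#' Runs DBSCAN on the min-max-normalized t-SNE coordinates and renumbers
#' the clusters 0..k-1 by decreasing size (ties: smallest member id);
#' noise keeps label -1.
#'
#' @param embedding An [embed_features()] result.
#' @param eps DBSCAN radius (default 0.05 on the unit square).
#' @param min_samples DBSCAN core threshold (default 4).
#' @return list of class `"tsne_groups"`: `labels` (named integer
#'   vector, -1 = noise), `groups` (list id vectors named by label),
#'   `n_groups`.
#' @export
cluster_tsne <- function(embedding, eps = 0.05, min_samples = 4L) {
  raw <- dbscan_euclidean(embedding$tsne, eps, min_samples)
  ids <- embedding$id
  pos <- sort(unique(raw[raw > 0]))
  if (length(pos)) {
    info <- lapply(pos, function(l) {
      mem <- sort(ids[raw == l])
      list(label = l, size = length(mem), first = mem[1])
    })
    o <- order(-vapply(info, `[[`, 0L, "size"),
               vapply(info, `[[`, "", "first"))
    newlab <- stats::setNames(seq_along(pos) - 1L,
                              vapply(info[o], `[[`, 0L, "label"))
    labels <- ifelse(raw > 0, newlab[as.character(raw)], -1L)
  } else {
    labels <- raw
  }
  labels <- stats::setNames(as.integer(labels), ids)
  groups <- lapply(sort(unique(labels[labels >= 0])), function(l) {
    sort(ids[labels == l])
  })
  names(groups) <- sort(unique(labels[labels >= 0]))
  structure(list(labels = labels, groups = groups,
                 n_groups = length(groups)),
            class = "tsne_groups")
}

#' Per-group composition by category and strain
#'
#' The layout of the study's group-composition table: one row per
#' category (functional keratinase; keratinase-linked and three-strain
#' split by strain; non-keratinase), one column per t-SNE group.
#'
#' @param tsne_groups A [cluster_tsne()] result.
#' @param records `protein_set` of all embedded proteins.
#' @param linked_ids Ids labelled keratinase-linked by the network.
#' @return data.frame (`category` x one column per group).
#' @export
tsne_group_composition <- function(tsne_groups, records, linked_ids) {
  strains <- sort(unique(records$strain[records$category == "query"]))
  cat_row <- function(ids) {
    vapply(names(tsne_groups$groups), function(g) {
      sum(ids %in% tsne_groups$groups[[g]])
    }, integer(1))
  }
  rows <- list()
  rows[["functional_keratinase"]] <-
    cat_row(records$id[records$category == "functional_keratinase"])
  for (s in strains) {
    ids_s <- records$id[records$strain == s & records$category == "query"]
    rows[[paste0("keratinase_linked_", s)]] <-
      cat_row(intersect(ids_s, linked_ids))
    rows[[paste0("three_strain_", s)]] <-
      cat_row(setdiff(ids_s, linked_ids))
  }
  rows[["non_keratinase"]] <-
    cat_row(records$id[records$category == "non_keratinase"])
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("tsne_group_", names(tsne_groups$groups))
  cbind(data.frame(category = rownames(out), stringsAsFactors = FALSE),
        `rownames<-`(out, NULL))
}

#' Per-protein extracellular call
#'
#' Majority vote of the three predictors: PSORTb extracellular score is
#' the compartment maximum, CELLO extracellular score is the compartment
#' maximum, and the SignalP signal-peptide possibility is >= 0.5. Two of
#' three votes call the protein extracellular.
#'
#' @param features A `localization_features` data.frame.
#' @return Named logical vector.
#' @export
predicted_extracellular <- function(features) {
  ps <- as.matrix(features[, c("psortb_cytoplasmic", "psortb_membrane",
                               "psortb_wall", "psortb_extracellular")])
  ce <- as.matrix(features[, c("cello_cytoplasmic", "cello_membrane",
                               "cello_wall", "cello_extracellular")])
  votes <- (max.col(ps, ties.method = "first") == 4L) +
    (max.col(ce, ties.method = "first") == 4L) +
    (features$signalp_possibility >= 0.5)
  stats::setNames(votes >= 2L, features$id)
}
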