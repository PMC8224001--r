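#' Default protease-mining keywords
#'
#' The nine annotation keywords used to flag putative proteases in
#' consolidated annotation tables. Matching is case-insensitive substring
#' matching; multi-word keywords are matched as whole phrases, so the
#' generic word "protein" never triggers on its own.
#'
#' @return Character vector of nine keywords.
#' @export
default_mining_keywords <- function() {
  c("peptidase", "protease", "proteinase", "sortase", "caspase",
    "penicillin-binding protein", "insulinase", "snapalysin", "mycosin")
}

#' Pipeline categories
#'
#' The four discrete categories carried through the similarity network,
#' the localization embedding and the ancestral state reconstruction:
#' functionally characterized keratinases, query proteins linked to them
#' through a network community, the remaining query ("three-strain")
#' proteins, and the hypothetical non-keratinase panel.
#'
#' @return Character vector of the four category labels, in canonical order.
#' @export
pipeline_categories <- function() {
  c("functional_keratinase", "keratinase_linked", "three_strain",
    "non_keratinase")
}

#' Build a pipeline configuration
#'
#' Collects every tunable parameter of the keratinase-screening pipeline in
#' one validated list. Defaults are the study conditions: reciprocal
#' best-hit family assignment at E-value 1e-20, orthogrouping and network
#' construction at 1e-40, weighted Louvain at resolution 1, t-SNE with
#' perplexity 30 and 1000 iterations under a fixed seed, DBSCAN on the
#' min-max-normalized t-SNE plane (eps 0.05, min_samples 4), a 70%
#' column-occupancy threshold for MSA compaction, and a 50% summed ancestral
#' probability threshold for clade selection.
#'
#' @param mining_keywords Character vector of annotation keywords.
#' @param family_evalue E-value cutoff for family assignment by RBH.
#' @param orthogroup_evalue E-value cutoff for p-orthogroup clustering.
#' @param network_evalue E-value cutoff for similarity-network edges
#'   (typical choices 1e-5, 1e-20, 1e-40, 1e-80).
#' @param louvain_resolution Resolution parameter of weighted Louvain.
#' @param tsne_perplexity t-SNE perplexity.
#' @param tsne_iterations Number of t-SNE gradient-descent iterations.
#' @param random_seed Single integer seed driving every stochastic step.
#' @param dbscan_eps DBSCAN radius on the [0,1]^2-normalized t-SNE plane.
#' @param dbscan_min_samples DBSCAN core-point neighbourhood size
#'   (neighbourhood includes the point itself).
#' @param occupancy_threshold Minimum column occupancy kept in compact MSAs.
#' @param clade_probability_threshold Ancestral probability that the summed
#'   keratinase + keratinase-linked state must strictly exceed.
#' @param focal_strain Strain whose proteins are reported as candidates.
#' @param clade_probability_rule `"sum"` (default) tests the sum of the two
#'   target-category probabilities; `"either"` requires one of them alone
#'   to exceed the threshold.
#' @param keratinase_link_rule `"community"` (default) links a query to
#'   keratinases through shared community membership; `"direct-edge"`
#'   requires a direct network edge.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mining_keywords = default_mining_keywords(),
                            family_evalue = 1e-20,
                            orthogroup_evalue = 1e-40,
                            network_evalue = 1e-40,
                            louvain_resolution = 1.0,
                            tsne_perplexity = 30,
                            tsne_iterations = 1000L,
                            random_seed = 42L,
                            dbscan_eps = 0.05,
                            dbscan_min_samples = 4L,
                            occupancy_threshold = 0.70,
                            clade_probability_threshold = 0.5,
                            focal_strain = "G11C",
                            clade_probability_rule = c("sum", "either"),
                            keratinase_link_rule = c("community",
                                                     "direct-edge")) {
  cfg <- list(
    mining_keywords = as.character(mining_keywords),
    family_evalue = as.numeric(family_evalue),
    orthogroup_evalue = as.numeric(orthogroup_evalue),
    network_evalue = as.numeric(network_evalue),
    louvain_resolution = as.numeric(louvain_resolution),
    tsne_perplexity = as.numeric(tsne_perplexity),
    tsne_iterations = as.integer(tsne_iterations),
    random_seed = as.integer(random_seed),
    dbscan_eps = as.numeric(dbscan_eps),
    dbscan_min_samples = as.integer(dbscan_min_samples),
    occupancy_threshold = as.numeric(occupancy_threshold),
    clade_probability_threshold = as.numeric(clade_probability_threshold),
    focal_strain = as.character(focal_strain),
    clade_probability_rule = match.arg(clade_probability_rule),
    keratinase_link_rule = match.arg(keratinase_link_rule)
  )
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  ev <- c(family = cfg$family_evalue, orthogroup = cfg$orthogroup_evalue,
          network = cfg$network_evalue)
  bad <- ev <= 0 | ev > 1
  if (any(bad)) {
    stop("E-value thresholds must lie in (0, 1]; offending: ",
         paste(names(ev)[bad], collapse = ", "))
  }
  if (!length(cfg$mining_keywords) || any(!nzchar(cfg$mining_keywords))) {
    stop("mining_keywords must be a non-empty vector of non-empty strings")
  }
  if (cfg$occupancy_threshold <= 0 || cfg$occupancy_threshold > 1) {
    stop("occupancy_threshold must lie in (0, 1]")
  }
  if (cfg$clade_probability_threshold <= 0 ||
      cfg$clade_probability_threshold >= 1) {
    stop("clade_probability_threshold must lie in (0, 1)")
  }
  if (cfg$tsne_perplexity <= 0) stop("tsne_perplexity must be positive")
  if (cfg$tsne_iterations < 1) stop("tsne_iterations must be >= 1")
  if (cfg$dbscan_eps <= 0) stop("dbscan_eps must be positive")
  if (cfg$dbscan_min_samples < 1) stop("dbscan_min_samples must be >= 1")
  if (is.na(cfg$random_seed)) stop("random_seed must be an integer")
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' The on-disk configuration format is JSON (one object whose keys are the
#' `pipeline_config()` arguments); unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's global RNG afterwards. All stochastic components go through
# this so one config seed pins the whole run.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
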