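# Independent oracles and shared fixtures for the suite.

# All set partitions of 1..n (Bell-number enumeration).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Exhaustive maximum modularity over all partitions.
max_modularity <- function(n, edges, resolution = 1) {
  best <- -Inf
  for (p in set_partitions(n)) {
    memb <- integer(n)
    for (b in seq_along(p)) memb[p[[b]]] <- b
    q <- modularity_partition(n, edges, memb, resolution)
    if (q > best) best <- q
  }
  best
}

# Brute-force ER likelihood and marginal posteriors by summation over all
# k^(n internal) ancestral assignments (flat root prior).
brute_asr <- function(tree, tip_idx, q, k) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internals <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  post <- matrix(0, nn, k)
  tot <- 0
  parent <- integer(nn); parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(nn); elen[tree$edge[, 2]] <- tree$edge.length
  for (r in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[seq_len(ntip)] <- tip_idx
    s[internals] <- grid[r, ]
    lik <- 1 / k
    for (v in seq_len(nn)) {
      if (parent[v] != 0) {
        P <- er_transition_matrix(q, elen[v], k)
        lik <- lik * P[s[parent[v]], s[v]]
      }
    }
    tot <- tot + lik
    for (v in internals) post[v, s[v]] <- post[v, s[v]] + lik
  }
  list(marginals = post / tot, loglik = log(tot))
}

# A similarity network straight from an explicit weighted edge list.
toy_network <- function(ids, from, to, weight,
                        category = rep("query", length(ids)),
                        strain = rep("x", length(ids))) {
  structure(list(
    nodes = data.frame(id = ids, strain = strain, category = category,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = from, to = to, evalue = 10^(-weight),
                       weight = weight, stringsAsFactors = FALSE),
    threshold = 1),
    class = "similarity_network")
}

# Random weighted graph for the modularity oracle suite.
random_graph_edges <- function(seed) {
  set.seed(seed)
  n <- sample(5:8, 1)
  prob <- stats::runif(1, 0.3, 0.7)
  em <- which(upper.tri(matrix(0, n, n)) &
                matrix(stats::runif(n * n) < prob, n, n), arr.ind = TRUE)
  if (nrow(em) == 0) em <- cbind(1L, 2L)
  list(n = n,
       edges = data.frame(i = em[, 1], j = em[, 2],
                          w = round(stats::runif(nrow(em), 0.5, 5), 2)))
}

# The minimal keratinase scenario plus its pipeline run is expensive
# (~1 min); build it once and share across test files.
.scenario_cache <- new.env(parent = emptyenv())

shared_scenario <- function() {
  if (is.null(.scenario_cache$bundle)) {
    dir <- file.path(tempdir(), "keratinscreen-shared-scenario")
    .scenario_cache$bundle <- gen_keratinase_scenario(dir, seed = 42)
    .scenario_cache$inputs <- scenario_inputs(.scenario_cache$bundle)
  }
  list(bundle = .scenario_cache$bundle, inputs = .scenario_cache$inputs)
}

shared_pipeline_result <- function() {
  if (is.null(.scenario_cache$result)) {
    sc <- shared_scenario()
    .scenario_cache$outdir <- file.path(tempdir(), "keratinscreen-run1")
    .scenario_cache$result <- run_pipeline(sc$bundle$config, sc$inputs,
                                           outdir = .scenario_cache$outdir)
  }
  list(result = .scenario_cache$result, outdir = .scenario_cache$outdir)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
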