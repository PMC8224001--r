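#' Read / write an aligned FASTA (MSA)
#'
#' An MSA is represented as a named character vector of equal-length
#' aligned sequences; gap characters are `-` and `.` (dots are
#' normalized to dashes on read).
#'
#' @param path Aligned FASTA.
#' @return Named character vector.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr(".", "-", as.character(aa)))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (length(unique(nchar(seqs))) > 1) {
    stop("ragged alignment in '", path, "': sequence lengths differ")
  }
  seqs
}

#' @rdname read_msa
#' @param msa Named character vector of aligned sequences.
#' @export
write_msa <- function(msa, path) {
  x <- Biostrings::BStringSet(msa)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (length(unique(nchar(msa))) > 1) stop("ragged alignment")
  m <- do.call(rbind, strsplit(chartr(".", "-", toupper(msa)), ""))
  rownames(m) <- names(msa)
  m
}

#' Column-occupancy filtering of an MSA
#'
#' Occupancy of a column is the fraction of sequences with a non-gap
#' residue there; average occupancy summarizes the MSA. Columns under
#' the threshold are removed to give a compact MSA; rows that become
#' all-gap are dropped with a warning.
#'
#' @param msa Named character vector (see [read_msa()]) or character
#'   matrix.
#' @param threshold Minimum occupancy kept (default 0.70).
#' @return list of class `"occupancy_result"`: `msa` (compact, named
#'   character vector), `profile` list with `occupancy` (per original
#'   column), `average_before_pct`, `average_after_pct`, `kept_columns`
#'   (original indices), `dropped_rows`.
#' @export
occupancy_filter <- function(msa, threshold = 0.70) {
  m <- msa_matrix(msa)
  occ <- colMeans(m != "-")
  keep <- which(occ >= threshold)
  compact <- m[, keep, drop = FALSE]
  dropped_rows <- character()
  if (ncol(compact)) {
    allgap <- rowSums(compact != "-") == 0
    if (any(allgap)) {
      dropped_rows <- rownames(compact)[allgap]
      warning("dropping all-gap row(s) after filtering: ",
              paste(dropped_rows, collapse = ", "))
      compact <- compact[!allgap, , drop = FALSE]
    }
  }
  out_msa <- stats::setNames(apply(compact, 1, paste, collapse = ""),
                             rownames(compact))
  if (!ncol(compact)) out_msa <- stats::setNames(
    rep("", nrow(compact)), rownames(compact))
  profile <- list(
    occupancy = occ,
    average_before_pct = 100 * mean(occ),
    average_after_pct = if (length(keep)) 100 * mean(occ[keep]) else NA_real_,
    kept_columns = keep,
    dropped_rows = dropped_rows)
  structure(list(msa = out_msa, profile = profile),
            class = "occupancy_result")
}

#' Neighbor-joining fallback tree from an MSA
#'
#' p-distances (mismatch fraction over columns where both sequences have
#' residues; 1 when no column is shared) fed to neighbor joining;
#' negative branch lengths are clamped to zero. This is a fixture-grade
#' fallback: externally inferred maximum-likelihood trees are accepted
#' as Newick input wherever available.
#'
#' @param msa Named character vector or character matrix (>= 3
#'   sequences).
#' @return An unrooted `ape::phylo`.
#' @export
nj_tree <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 3) stop("neighbor joining needs at least 3 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      D[i, j] <- D[j, i] <- if (!any(both)) 1 else
        mean(m[i, both] != m[j, both])
    }
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (phangorn's implementation). A tree whose branches are all zero is
#' rooted deterministically at the first tip with a warning.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at first tip")
    return(ape::root(tree, outgroup = sort(tree$tip.label)[1],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

# ---- equal-rates (ER) Mk model --------------------------------------------

#' ER transition probability matrix
#'
#' For the k-state equal-rates Markov model with rate q per off-diagonal
#' transition: `P_same(t) = 1/k + (k-1)/k * exp(-k q t)` and
#' `P_diff(t) = 1/k * (1 - exp(-k q t))`. Rows sum to one; at t = 0 the
#' matrix is the identity and as t grows it approaches the uniform 1/k.
#'
#' @param q Transition rate (>= 0).
#' @param t Elapsed time (branch length, >= 0).
#' @param k Number of states (default 4).
#' @return k x k matrix.
#' @export
er_transition_matrix <- function(q, t, k = 4L) {
  e <- exp(-k * q * t)
  same <- 1 / k + (k - 1) / k * e
  diff <- (1 - e) / k
  m <- matrix(diff, k, k)
  diag(m) <- same
  m
}

# Postorder pruning pass. Returns list(partials = (Ntip+Nnode) x k matrix of
# scaled conditional likelihoods, logscale = per-node accumulated log
# scalers, loglik = log likelihood under flat root prior).
er_pruning <- function(tree, tip_states_idx, q, k) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- matrix(0, ntip + nnode, k)
  logsc <- numeric(ntip + nnode)
  L[cbind(seq_len(ntip), tip_states_idx)] <- 1
  # accumulate children contributions edge by edge (postorder)
  prod_init <- rep(TRUE, ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    P <- er_transition_matrix(q, tree$edge.length[e], k)
    contrib <- as.vector(P %*% L[chi, ])
    if (prod_init[par]) {
      L[par, ] <- contrib
      prod_init[par] <- FALSE
    } else {
      L[par, ] <- L[par, ] * contrib
    }
    logsc[par] <- logsc[par] + logsc[chi]
    s <- sum(L[par, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      L[par, ] <- L[par, ] / s
      logsc[par] <- logsc[par] + log(s)
    }
  }
  root <- ntip + 1L
  lik <- sum(L[root, ] / k)
  list(partials = L, logscale = logsc,
       loglik = log(lik) + logsc[root], root = root, ntip = ntip)
}

er_loglik <- function(tree, tip_states_idx, q, k) {
  er_pruning(tree, tip_states_idx, q, k)$loglik
}

# ML estimate of the single ER rate: coarse grid on log(q) to bracket the
# global optimum (the likelihood can plateau near saturation, where pure
# golden-section search stalls), then local refinement.
er_fit_q <- function(tree, tip_states_idx, k) {
  f <- function(lq) er_loglik(tree, tip_states_idx, exp(lq), k)
  grid <- seq(log(1e-8), log(1e3), length.out = 61)
  vals <- vapply(grid, f, numeric(1))
  if (all(!is.finite(vals))) {
    stop("ER rate optimization failed; log-likelihood trace: ",
         paste(sprintf("logq=%.2f ll=%.3f", grid[c(1, 31, 61)],
                       vals[c(1, 31, 61)]), collapse = "; "))
  }
  i <- which.max(vals)
  opt <- stats::optimize(f,
                         interval = c(grid[max(1L, i - 1L)],
                                      grid[min(length(grid), i + 1L)]),
                         maximum = TRUE, tol = 1e-8)
  if (is.finite(opt$objective) && opt$objective >= vals[i]) {
    list(q = exp(opt$maximum), loglik = opt$objective)
  } else {
    list(q = exp(grid[i]), loglik = vals[i])
  }
}

# Exact marginal posteriors at every node: outside pass combined with the
# pruning partials (flat root prior).
er_marginals <- function(tree, tip_states_idx, q, k) {
  pr <- er_pruning(tree, tip_states_idx, q, k)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ntip <- pr$ntip
  nn <- ntip + tree$Nnode
  L <- pr$partials
  # children contributions through their edges, per parent
  edge <- tree_po$edge; elen <- tree_po$edge.length
  contrib <- matrix(0, nrow(edge), k)  # P(t_e) %*% L_child
  for (e in seq_len(nrow(edge))) {
    P <- er_transition_matrix(q, elen[e], k)
    contrib[e, ] <- as.vector(P %*% L[edge[e, 2], ])
  }
  O <- matrix(0, nn, k)
  O[pr$root, ] <- 1 / k
  # preorder traversal: reverse postorder edge order visits parents first
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    sib <- which(edge[, 1] == par)
    sib <- sib[sib != e]
    above <- O[par, ]
    for (s2 in sib) above <- above * contrib[s2, ]
    P <- er_transition_matrix(q, elen[e], k)
    O[chi, ] <- as.vector(t(P) %*% above)
    s <- sum(O[chi, ])
    if (s > 0) O[chi, ] <- O[chi, ] / s
  }
  marg <- O * L
  marg <- marg / rowSums(marg)
  marg
}

# Joint draws of node states (backward filtering / forward sampling);
# returns node-frequency matrix over nsim draws.
er_simmap_frequencies <- function(tree, tip_states_idx, q, k, nsim, seed) {
  pr <- er_pruning(tree, tip_states_idx, q, k)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge; elen <- tree_po$edge.length
  ntip <- pr$ntip
  nn <- ntip + tree$Nnode
  L <- pr$partials
  counts <- matrix(0, nn, k)
  pre <- rev(seq_len(nrow(edge)))
  with_seed(seed, {
    for (sim in seq_len(nsim)) {
      state <- integer(nn)
      w <- L[pr$root, ] / k
      state[pr$root] <- sample.int(k, 1, prob = w)
      for (e in pre) {
        par <- edge[e, 1]; chi <- edge[e, 2]
        P <- er_transition_matrix(q, elen[e], k)
        w <- P[state[par], ] * L[chi, ]
        state[chi] <- sample.int(k, 1, prob = w)
      }
      counts[cbind(seq_len(nn), state)] <-
        counts[cbind(seq_len(nn), state)] + 1
    }
  })
  counts / nsim
}

#' Ancestral state reconstruction under the ER Mk model
#'
#' Fits the single equal-rates transition rate q by maximum likelihood
#' (Felsenstein pruning, flat root prior) and computes per-node marginal
#' posterior probabilities over the discrete categories, either exactly
#' (`method = "marginal"`, the default: deterministic) or as empirical
#' node frequencies over seeded stochastic character histories
#' (`method = "simmap"`, the idiom of the tooling this emulates, with
#' 1000 draws by default).
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param tip_categories Named character vector (names = tip labels);
#'   every tip must be categorized.
#' @param categories State space (default [pipeline_categories()]).
#' @param method `"marginal"` or `"simmap"`.
#' @param nsim Number of simmap draws.
#' @param seed Seed for the simmap draws.
#' @param q Fix the rate instead of fitting it.
#' @return list of class `"categorized_tree"`: `tree`, `categories`,
#'   `tip_categories`, `q`, `loglik`, `node_probs` (rows = all nodes in
#'   ape numbering, tips first; tip rows are unit vectors), `method`.
#' @export
asr_er <- function(tree, tip_categories,
                   categories = pipeline_categories(),
                   method = c("marginal", "simmap"), nsim = 1000L,
                   seed = 1L, q = NULL) {
  method <- match.arg(method)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tips <- tree$tip.label
  missing <- setdiff(tips, names(tip_categories))
  if (length(missing)) {
    stop("uncategorized tip(s): ", paste(missing, collapse = ", "))
  }
  states <- tip_categories[tips]
  bad <- setdiff(unique(states), categories)
  if (length(bad)) {
    stop("unknown categor(y/ies): ", paste(bad, collapse = ", "))
  }
  k <- length(categories)
  idx <- match(states, categories)
  if (is.null(q)) {
    fit <- er_fit_q(tree, idx, k)
    q <- fit$q; loglik <- fit$loglik
  } else {
    loglik <- er_loglik(tree, idx, q, k)
  }
  node_probs <- if (method == "marginal") {
    er_marginals(tree, idx, q, k)
  } else {
    er_simmap_frequencies(tree, idx, q, k, nsim, seed)
  }
  colnames(node_probs) <- categories
  structure(list(tree = tree, categories = categories,
                 tip_categories = states, q = q, loglik = loglik,
                 node_probs = node_probs, method = method),
            class = "categorized_tree")
}

#' Write a categorized tree as annotated Newick
#'
#' Internal node labels carry the ancestral probabilities as
#' `cat1=p1|cat2=p2|...` strings.
#'
#' @param ctree A [asr_er()] result.
#' @param path Output Newick file.
#' @export
write_categorized_tree <- function(ctree, path) {
  tr <- ctree$tree
  ntip <- length(tr$tip.label)
  nodes <- (ntip + 1):(ntip + tr$Nnode)
  lab <- apply(ctree$node_probs[nodes, , drop = FALSE], 1, function(p) {
    paste(sprintf("%s=%.4f", abbreviate(ctree$categories, 4), p),
          collapse = "|")
  })
  tr$node.label <- lab
  ape::write.tree(tr, path)
  invisible(path)
}

#' Three-filter clade selection
#'
#' Every internal node is tested against the three filters: (1) the
#' ancestral probability of the functional-keratinase plus
#' keratinase-linked categories strictly exceeds the threshold (their
#' sum by default; rule `"either"` requires one of the two alone to
#' exceed it); (2) the subtree holds at least one functional-keratinase
#' tip; (3) the subtree holds at least one focal-strain tip. A node
#' passing all three is selected; selected nodes nested inside another
#' selected node are subsumed, and the candidates are the focal-strain
#' tips of the maximal selected clades.
#'
#' @param ctree A [asr_er()] result.
#' @param tip_strains Named character vector (tip label -> strain; panel
#'   tips may be absent or carry panel names).
#' @param focal_strain The strain whose tips become candidates.
#' @param prob_threshold Probability threshold (default 0.5).
#' @param rule `"sum"` or `"either"`.
#' @return list of class `"clade_decisions"`: `decisions` data.frame
#'   (`node`, `prob`, `prob_pass`, `has_keratinase`, `has_focal`,
#'   `selected`, `maximal`, `tips` semicolon-joined), `candidates`
#'   (deduplicated focal tips of maximal selected clades).
#' @export
select_clades <- function(ctree, tip_strains, focal_strain,
                          prob_threshold = 0.5, rule = c("sum", "either")) {
  rule <- match.arg(rule)
  tr <- ctree$tree
  ntip <- length(tr$tip.label)
  nodes <- (ntip + 1):(ntip + tr$Nnode)
  desc <- lapply(nodes, function(nd) {
    tr$tip.label[descendant_tips(tr, nd)]
  })
  pk <- ctree$node_probs[nodes, "functional_keratinase"]
  pl <- ctree$node_probs[nodes, "keratinase_linked"]
  prob <- if (rule == "sum") pk + pl else pmax(pk, pl)
  is_ker <- vapply(desc, function(tp) {
    any(ctree$tip_categories[tp] == "functional_keratinase")
  }, logical(1))
  strain_of <- tip_strains
  is_focal <- vapply(desc, function(tp) {
    any(!is.na(strain_of[tp]) & strain_of[tp] == focal_strain)
  }, logical(1))
  prob_pass <- prob > prob_threshold
  selected <- prob_pass & is_ker & is_focal
  # maximal clades: no ancestor also selected
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  maximal <- selected
  for (i in seq_along(nodes)) {
    if (!selected[i]) { maximal[i] <- FALSE; next }
    a <- parent[nodes[i]]
    while (a != 0L) {
      if (selected[match(a, nodes)]) { maximal[i] <- FALSE; break }
      a <- parent[a]
    }
  }
  candidates <- character()
  for (i in which(maximal)) {
    tp <- desc[[i]]
    candidates <- c(candidates,
                    tp[!is.na(strain_of[tp]) & strain_of[tp] == focal_strain])
  }
  candidates <- sort(unique(candidates))
  decisions <- data.frame(
    node = nodes, prob = prob, prob_pass = prob_pass,
    has_keratinase = is_ker, has_focal = is_focal,
    selected = selected, maximal = maximal,
    tips = vapply(desc, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  rownames(decisions) <- NULL
  structure(list(decisions = decisions, candidates = candidates),
            class = "clade_decisions")
}

# tip indices below an internal node
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(); stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(out)
}
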