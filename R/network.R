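#' Build a protein similarity network
#'
#' Nodes are all supplied proteins (query strains plus both reference
#' panels); an undirected edge joins A and B iff the minimum of the two
#' directed E-values is at or under the threshold. Edge weight is
#' `-log10(evalue)` capped at 300 (an E-value of exactly 0 maps to 300).
#' Self-hits are dropped; isolated nodes are retained as nodes.
#'
#' @param hits Alignment-hit data.frame over the union set.
#' @param records `protein_set` supplying the node universe with strain
#'   and category attributes.
#' @param threshold E-value cutoff for edges (default 1e-40).
#' @return list of class `"similarity_network"`: `nodes` (id, strain,
#'   category), `edges` (from, to, evalue, weight; from < to), and
#'   `threshold`.
#' @export
build_network <- function(hits, records, threshold = 1e-40) {
  h <- hits[hits$query != hits$subject &
              hits$query %in% records$id &
              hits$subject %in% records$id, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query, h$subject)
    b <- pmax(h$query, h$subject)
    key <- paste(a, b, sep = "\r")
    o <- order(key, h$evalue)
    keep <- o[!duplicated(key[o])]
    edges <- data.frame(from = a[keep], to = b[keep],
                        evalue = h$evalue[keep], stringsAsFactors = FALSE)
    edges <- edges[edges$evalue <= threshold, , drop = FALSE]
    edges$weight <- ifelse(edges$evalue == 0, 300,
                           pmin(300, -log10(edges$evalue)))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        evalue = numeric(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(id = records$id, strain = records$strain,
                      category = records$category,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "similarity_network")
}

# ---- weighted Louvain ------------------------------------------------------

# Modularity of a partition of an undirected weighted graph without
# self-loops. edges: data.frame/list with integer node indices $i, $j
# (each unordered pair once) and weights $w; membership: integer vector.
#' Modularity of a partition
#'
#' `Q = sum_c [ W_in(c)/m - resolution * (k_tot(c)/(2m))^2 ]` for an
#' undirected weighted graph given once per unordered pair, no
#' self-loops.
#'
#' @param n Number of nodes.
#' @param edges data.frame with integer columns `i`, `j` (1-based) and
#'   weight `w`.
#' @param membership Integer community label per node.
#' @param resolution Resolution parameter.
#' @return Scalar modularity (0 for an edgeless graph).
#' @export
modularity_partition <- function(n, edges, membership, resolution = 1) {
  m <- sum(edges$w)
  if (m == 0) return(0)
  k <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    k[edges$i[r]] <- k[edges$i[r]] + edges$w[r]
    k[edges$j[r]] <- k[edges$j[r]] + edges$w[r]
  }
  same <- membership[edges$i] == membership[edges$j]
  w_in <- sum(edges$w[same])
  ktot <- tapply(k, membership, sum)
  w_in / m - resolution * sum((ktot / (2 * m))^2)
}

# One Louvain level: local moves until no node changes community.
# adj: list per node of list(nb = int vector, w = numeric vector)
# (self-loops excluded from adj but included in k via kself).
louvain_one_level <- function(n, adj, k, kself, m2, gamma, order_vec,
                              comm_init = NULL) {
  comm <- comm_init %||% seq_len(n)
  ktot <- as.numeric(tapply(k, factor(comm, levels = seq_len(n)), sum))
  ktot[is.na(ktot)] <- 0
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (v in order_vec) {
      cv <- comm[v]
      nb <- adj[[v]]$nb; wv <- adj[[v]]$w
      # weight from v to each neighboring community
      if (length(nb)) {
        wc <- tapply(wv, comm[nb], sum)
        cand <- as.integer(names(wc))
        wlink <- as.numeric(wc)
      } else {
        cand <- integer(); wlink <- numeric()
      }
      if (!(cv %in% cand)) { cand <- c(cand, cv); wlink <- c(wlink, 0) }
      # remove v from its community, then evaluate each candidate
      ktot[cv] <- ktot[cv] - k[v]
      gains <- wlink - gamma * k[v] * ktot[cand] / m2
      best <- max(gains)
      target <- min(cand[gains >= best - 1e-15])  # tie: lower community id
      ktot[target] <- ktot[target] + k[v]
      if (target != cv) {
        comm[v] <- target
        improved <- TRUE
      }
    }
  }
  # renumber 1..K preserving first-appearance order by community id
  match(comm, sort(unique(comm)))
}

# Full Louvain with aggregation; returns membership 1..K for the original
# nodes. Deterministic given the RNG state (node orders are drawn from it).
# init: optional starting partition (1..K labels); the classic algorithm
# starts from singletons, restarts may start from random partitions to
# escape the local optima of pure single-node moves.
louvain_run <- function(n, edges, gamma, init = NULL) {
  membership <- seq_len(n)
  cur_n <- n
  cur_edges <- edges
  first_level <- TRUE
  repeat {
    # adjacency and degrees (self-loops go to kself, counted twice in k)
    adj <- vector("list", cur_n)
    for (v in seq_len(cur_n)) adj[[v]] <- list(nb = integer(), w = numeric())
    k <- numeric(cur_n); kself <- numeric(cur_n)
    if (nrow(cur_edges)) {
      for (r in seq_len(nrow(cur_edges))) {
        i <- cur_edges$i[r]; j <- cur_edges$j[r]; w <- cur_edges$w[r]
        if (i == j) {
          kself[i] <- kself[i] + w
          k[i] <- k[i] + 2 * w
        } else {
          adj[[i]]$nb <- c(adj[[i]]$nb, j); adj[[i]]$w <- c(adj[[i]]$w, w)
          adj[[j]]$nb <- c(adj[[j]]$nb, i); adj[[j]]$w <- c(adj[[j]]$w, w)
          k[i] <- k[i] + w; k[j] <- k[j] + w
        }
      }
    }
    m2 <- sum(k)
    if (m2 == 0) break
    ord <- sample.int(cur_n)
    comm <- louvain_one_level(cur_n, adj, k, kself, m2, gamma, ord,
                              comm_init = if (first_level) init)
    first_level <- FALSE
    n_comm <- max(comm)
    membership <- comm[membership]
    if (n_comm == cur_n) break
    # aggregate
    if (nrow(cur_edges)) {
      ci <- comm[cur_edges$i]; cj <- comm[cur_edges$j]
      a <- pmin(ci, cj); b <- pmax(ci, cj)
      key <- paste(a, b)
      agg <- tapply(cur_edges$w, key, sum)
      ij <- do.call(rbind, strsplit(names(agg), " "))
      cur_edges <- data.frame(i = as.integer(ij[, 1]),
                              j = as.integer(ij[, 2]),
                              w = as.numeric(agg))
    }
    cur_n <- n_comm
  }
  membership
}

#' Detect network communities (weighted Louvain)
#'
#' Greedy weighted-modularity maximization with aggregation. Node
#' processing order is drawn from the seed, making the run
#' deterministic; several restarts with derived orders are performed and
#' the partition with the highest modularity kept, which in practice
#' recovers the exhaustive-search optimum on small graphs. Communities
#' of size >= 2 are reported with ids by decreasing size (ties: smallest
#' member id); singletons are listed separately.
#'
#' @param network A [build_network()] result.
#' @param resolution Resolution parameter (default 1).
#' @param seed Integer seed for the node-order shuffles.
#' @param restarts Number of seeded restarts (default 8).
#' @return list of class `"community_set"`: `communities` data.frame
#'   (`community`, `id`, `size`, `contains_functional_keratinase`,
#'   `contains_query`), `membership` (named integer vector over
#'   non-singleton nodes), `singletons`, `modularity`.
#' @export
detect_communities <- function(network, resolution = 1, seed = 1L,
                               restarts = 8L) {
  ids <- network$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  edges <- data.frame(i = idx[network$edges$from],
                      j = idx[network$edges$to],
                      w = network$edges$weight)
  rownames(edges) <- NULL
  best <- NULL; best_q <- -Inf
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      # restart 1 is the classic singleton start; later restarts begin
      # from random partitions, which lets coordinated rearrangements
      # escape the local optima of pure single-node moves
      init <- if (r == 1L) NULL else sample.int(n, n, replace = TRUE)
      memb <- louvain_run(n, edges, resolution, init = init)
      q <- modularity_partition(n, edges, memb, resolution)
      if (q > best_q + 1e-15) { best_q <- q; best <- memb }
    }
    # final single-node refinement from the best partition found
    memb <- louvain_run(n, edges, resolution, init = best)
    q <- modularity_partition(n, edges, memb, resolution)
    if (q > best_q + 1e-15) { best_q <- q; best <- memb }
  })
  memb <- best
  sizes <- table(memb)
  multi <- as.integer(names(sizes)[sizes >= 2])
  info <- lapply(multi, function(cid) {
    members <- sort(ids[memb == cid])
    list(members = members, size = length(members))
  })
  o <- order(-vapply(info, `[[`, 0L, "size"),
             vapply(info, function(x) x$members[1], ""))
  info <- info[o]
  cat_of <- stats::setNames(network$nodes$category, ids)
  rows <- lapply(seq_along(info), function(k) {
    mem <- info[[k]]$members
    data.frame(community = k, id = mem, size = info[[k]]$size,
               contains_functional_keratinase =
                 any(cat_of[mem] == "functional_keratinase"),
               contains_query = any(cat_of[mem] == "query"),
               stringsAsFactors = FALSE)
  })
  communities <- if (length(rows)) do.call(rbind, rows) else
    data.frame(community = integer(), id = character(), size = integer(),
               contains_functional_keratinase = logical(),
               contains_query = logical(), stringsAsFactors = FALSE)
  rownames(communities) <- NULL
  membership <- stats::setNames(communities$community, communities$id)
  singletons <- ids[!(ids %in% communities$id)]
  structure(list(communities = communities, membership = membership,
                 singletons = singletons, modularity = best_q),
            class = "community_set")
}

#' Label keratinase-linked proteins
#'
#' A query protein is keratinase-linked iff its community contains at
#' least one functional-keratinase node (rule `"community"`), or iff it
#' shares a direct network edge with one (rule `"direct-edge"`). Panel
#' sequences never count as linked themselves.
#'
#' @param communities A [detect_communities()] result.
#' @param network The underlying [build_network()] result.
#' @param hits Optional alignment hits; when given, each linked protein
#'   is annotated with its best identity/E-value to any keratinase of
#'   its community.
#' @param rule `"community"` (default) or `"direct-edge"`.
#' @return list: `linked` (character ids), `per_strain` (named counts),
#'   `details` data.frame (`id`, `strain`, `community`,
#'   `best_keratinase`, `best_identity_pct`, `best_evalue`).
#' @export
link_keratinases <- function(communities, network, hits = NULL,
                             rule = c("community", "direct-edge")) {
  rule <- match.arg(rule)
  nodes <- network$nodes
  cat_of <- stats::setNames(nodes$category, nodes$id)
  comm <- communities$communities
  if (rule == "community") {
    linked_rows <- comm[comm$contains_functional_keratinase &
                          cat_of[comm$id] == "query", , drop = FALSE]
    ker_of_comm <- function(cid) {
      mem <- comm$id[comm$community == cid]
      mem[cat_of[mem] == "functional_keratinase"]
    }
  } else {
    e <- network$edges
    ker <- nodes$id[nodes$category == "functional_keratinase"]
    touching <- unique(c(e$to[e$from %in% ker], e$from[e$to %in% ker]))
    ids <- touching[cat_of[touching] == "query"]
    cidx <- communities$membership[ids]
    linked_rows <- data.frame(community = unname(cidx), id = ids,
                              stringsAsFactors = FALSE)
    ker_of_comm <- function(cid) {
      mem <- comm$id[comm$community == cid]
      mem[cat_of[mem] == "functional_keratinase"]
    }
  }
  if (!nrow(linked_rows)) {
    return(list(linked = character(),
                per_strain = integer(),
                details = data.frame(id = character(), strain = character(),
                                     community = integer(),
                                     best_keratinase = character(),
                                     best_identity_pct = numeric(),
                                     best_evalue = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  strain_of <- stats::setNames(nodes$strain, nodes$id)
  details <- lapply(seq_len(nrow(linked_rows)), function(r) {
    id <- linked_rows$id[r]; cid <- linked_rows$community[r]
    kers <- ker_of_comm(cid)
    bi <- NA_real_; be <- NA_real_; bk <- NA_character_
    if (!is.null(hits) && length(kers)) {
      sub <- hits[(hits$query == id & hits$subject %in% kers) |
                    (hits$subject == id & hits$query %in% kers), ,
                  drop = FALSE]
      if (nrow(sub)) {
        b <- which.min(sub$evalue)
        bi <- sub$identity_pct[b]; be <- sub$evalue[b]
        bk <- ifelse(sub$query[b] == id, sub$subject[b], sub$query[b])
      }
    }
    data.frame(id = id, strain = unname(strain_of[id]),
               community = cid, best_keratinase = bk,
               best_identity_pct = bi, best_evalue = be,
               stringsAsFactors = FALSE)
  })
  details <- do.call(rbind, details)
  details <- details[order(details$id), , drop = FALSE]
  rownames(details) <- NULL
  list(linked = details$id,
       per_strain = table(details$strain),
       details = details)
}

#' Export a similarity network as GraphML
#'
#' Node attributes: strain, category, community (0 = singleton) and
#' keratinase_linked flag.
#'
#' @param network A `similarity_network`.
#' @param communities A `community_set`.
#' @param linked Result of [link_keratinases()].
#' @param path Output GraphML file.
#' @export
write_network_graphml <- function(network, communities, linked, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "weight", "evalue")],
    directed = FALSE, vertices = network$nodes)
  memb <- communities$membership[igraph::V(g)$name]
  igraph::V(g)$community <- ifelse(is.na(memb), 0L, as.integer(memb))
  igraph::V(g)$keratinase_linked <-
    igraph::V(g)$name %in% linked$linked
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
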