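test_that("occupancy arithmetic matches hand computation", {
  # gapless MSA: nothing removed, average 100%
  occ <- occupancy_filter(c(a = "MKVL", b = "MKIL"), 0.70)
  expect_equal(occ$profile$average_before_pct, 100)
  expect_equal(occ$profile$kept_columns, 1:4)

  # the two-sequence case: occupancies 1.0 / 0.5 / 0.0, average 50%,
  # only column 1 survives the 70% threshold
  occ2 <- occupancy_filter(c(s1 = "AC-", s2 = "A--"), 0.70)
  expect_equal(occ2$profile$occupancy, c(1, 0.5, 0))
  expect_equal(occ2$profile$average_before_pct, 50)
  expect_equal(occ2$profile$kept_columns, 1L)
  expect_equal(unname(occ2$msa), c("A", "A"))
  expect_gte(occ2$profile$average_after_pct,
             occ2$profile$average_before_pct)

  # threshold zero is the identity transform
  occ3 <- occupancy_filter(c(s1 = "AC-", s2 = "A--"), 0)
  expect_equal(unname(occ3$msa), c("AC-", "A--"))

  # dots are gaps too; ragged alignments error
  occ4 <- occupancy_filter(c(s1 = "A.L", s2 = "AKL"), 0.70)
  expect_equal(occ4$profile$occupancy, c(1, 0.5, 1))
  expect_error(occupancy_filter(c(s1 = "ACD", s2 = "AC")), "ragged")
})

test_that("all-gap rows are dropped with a warning after filtering", {
  # columns 1-4 have occupancy 0.75 (kept), column 5 only 0.25 (removed),
  # which leaves s4 without a single residue
  msa <- c(s1 = "MKVL-", s2 = "MKIL-", s3 = "MKVI-", s4 = "----W")
  expect_warning(occ <- occupancy_filter(msa, 0.70), "s4")
  expect_setequal(names(occ$msa), c("s1", "s2", "s3"))
  expect_equal(unname(occ$msa[["s1"]]), "MKVL")
})

test_that("neighbor joining recovers additive distances and planted topology", {
  # 3 taxa: the unique topology, with additive branch lengths
  msa3 <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AACCCCAAAA")
  tr3 <- nj_tree(msa3)
  D <- ape::cophenetic.phylo(tr3)
  expect_equal(D["a", "b"], 0.1)
  expect_equal(D["a", "c"], 0.4)
  expect_equal(D["b", "c"], 0.5)
  expect_error(nj_tree(msa3[1:2]), "at least 3")

  # 4 taxa from two planted families: NJ must pair the families
  fx <- gen_families(2, 2, length = 200, within_divergence = 0.05,
                     seed = 101, strains = c("s"))
  msa4 <- stats::setNames(fx$records$sequence, fx$records$id)
  tr4 <- nj_tree(msa4)
  fam <- split(fx$truth$id, fx$truth$family)
  for (pair in fam) {
    mrca_dist <- ape::cophenetic.phylo(tr4)[pair[1], pair[2]]
    others <- setdiff(fx$truth$id, pair)
    expect_true(all(mrca_dist <
                      ape::cophenetic.phylo(tr4)[pair[1], others]))
  }
})

test_that("midpoint rooting splits the longest path; caterpillar case by brute force", {
  tr <- ape::read.tree(text = "(A:1,B:3);")
  mr <- midpoint_root(tr)
  expect_equal(sort(mr$edge.length), c(2, 2))

  # caterpillar: longest tip-to-tip path known by all-pairs distances
  cat_tree <- ape::read.tree(
    text = "((((A:5,B:1):1,C:1):1,D:1):1,E:9);")
  D <- ape::cophenetic.phylo(cat_tree)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(D)[far], c("A", "E"))
  mr2 <- midpoint_root(cat_tree)
  # after midpoint rooting, the two deepest tips are equidistant from root
  depths <- ape::node.depth.edgelength(mr2)[seq_along(mr2$tip.label)]
  names(depths) <- mr2$tip.label
  expect_equal(unname(depths["A"]), unname(depths["E"]))
  expect_equal(unname(depths["A"]), max(D) / 2)

  zero <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_warning(mz <- midpoint_root(zero), "zero")
  expect_true(ape::is.rooted(mz))
})

test_that("ER transition matrix rows sum to 1, start at identity, end uniform", {
  for (q in c(0.1, 1, 5)) {
    for (t in c(0, 0.3, 2, 1e6)) {
      P <- er_transition_matrix(q, t, 4)
      expect_equal(rowSums(P), rep(1, 4))
    }
  }
  expect_equal(er_transition_matrix(1, 0, 4), diag(4))
  expect_equal(er_transition_matrix(1, 1e9, 4),
               matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("pruning likelihood and marginals equal brute-force enumeration (<= 6 tips)", {
  set.seed(111)
  for (rep in 1:10) {
    ntip <- sample(3:6, 1)
    tr <- ape::rtree(ntip, rooted = TRUE)
    tipidx <- sample(1:4, ntip, replace = TRUE)
    q <- stats::runif(1, 0.05, 2)
    cats <- pipeline_categories()
    ct <- asr_er(tr, stats::setNames(cats[tipidx], tr$tip.label), q = q)
    oracle <- brute_asr(tr, tipidx[match(tr$tip.label, tr$tip.label)],
                        q, 4)
    expect_equal(ct$loglik, oracle$loglik, tolerance = 1e-8)
    internals <- (ntip + 1):(ntip + tr$Nnode)
    expect_lt(max(abs(ct$node_probs[internals, ] -
                        oracle$marginals[internals, ])), 1e-8)
  }
})

test_that("two-tip symmetry and same-category dominance under ER", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cats <- pipeline_categories()
  ct <- asr_er(tr, stats::setNames(cats[c(1, 2)], c("A", "B")), q = 0.4)
  root <- ct$node_probs[3, ]
  expect_equal(unname(root[1]), unname(root[2]), tolerance = 1e-12)
  expect_equal(unname(root[3]), unname(root[4]), tolerance = 1e-12)
  expect_gt(root[1], root[3])

  tr2 <- ape::rtree(6, rooted = TRUE)
  ct2 <- asr_er(tr2, stats::setNames(rep(cats[2], 6), tr2$tip.label),
                q = 0.5)
  modal <- apply(ct2$node_probs[7:nrow(ct2$node_probs), ], 1, which.max)
  expect_true(all(modal == 2))

  expect_error(asr_er(tr, stats::setNames(cats[1], "A")),
               "uncategorized")
})

test_that("simmap node frequencies converge to the exact marginals", {
  set.seed(121)
  tr <- ape::rtree(6, rooted = TRUE)
  cats <- pipeline_categories()
  tipc <- stats::setNames(cats[sample(1:4, 6, replace = TRUE)],
                          tr$tip.label)
  exact <- asr_er(tr, tipc, q = 0.6)
  sim <- asr_er(tr, tipc, q = 0.6, method = "simmap", nsim = 1000,
                seed = 9)
  expect_lt(max(abs(exact$node_probs - sim$node_probs)), 0.05)
  # seeded draws are reproducible
  sim2 <- asr_er(tr, tipc, q = 0.6, method = "simmap", nsim = 1000,
                 seed = 9)
  expect_identical(sim$node_probs, sim2$node_probs)
})

test_that("fitted ER rate agrees with an independent implementation", {
  # moderate rate on a 40-tip tree keeps the likelihood well peaked
  set.seed(131)
  tr <- ape::rtree(40, rooted = TRUE)
  hist <- gen_er_history(tr, q = 0.3, k = 4, seed = 13)
  fit <- asr_er(tr, hist$tip_categories)
  # independent cross-check: ape::ace with the ER model
  ace_fit <- ape::ace(factor(hist$tip_categories[tr$tip.label],
                             levels = pipeline_categories()),
                      tr, type = "discrete", model = "ER")
  # ace sums the root conditional likelihoods (no 1/k prior factor), so
  # its log-likelihood sits exactly log(k) above the flat-prior one; the
  # fitted rate is unaffected by that additive constant
  expect_equal(fit$loglik + log(4), ace_fit$loglik, tolerance = 1e-4)
  expect_equal(fit$q, unname(ace_fit$rates), tolerance = 1e-2)
})

test_that("clade selection applies the three filters with maximal-clade subsumption", {
  # ((K:1,G:1):1,(C:1,V:1):1); categories: keratinase, linked, 2x three-strain
  tr <- ape::read.tree(text = "((K:1,G:1):1,(C:1,V:1):1);")
  probs <- matrix(0, 7, 4,
                  dimnames = list(NULL, pipeline_categories()))
  probs[1:4, ] <- diag(4)[c(1, 2, 3, 3), ]
  probs[5, ] <- c(0.30, 0.25, 0.25, 0.20)   # root: sum 0.55 > 0.5
  probs[6, ] <- c(0.45, 0.25, 0.20, 0.10)   # (K,G): sum 0.70
  probs[7, ] <- c(0.10, 0.10, 0.60, 0.20)   # (C,V): fails
  ct <- structure(list(
    tree = tr, categories = pipeline_categories(),
    tip_categories = stats::setNames(
      pipeline_categories()[c(1, 2, 3, 3)], c("K", "G", "C", "V")),
    q = 1, loglik = 0, node_probs = probs, method = "marginal"),
    class = "categorized_tree")
  strains <- stats::setNames(c(NA, "G11C", "CHD11", "Vc74B-19"),
                             c("K", "G", "C", "V"))
  sel <- select_clades(ct, strains, "G11C", 0.5)
  # root is selected (0.55, has keratinase, has focal) and subsumes (K,G)
  dec <- sel$decisions
  expect_true(dec$selected[dec$node == 5])
  expect_true(dec$selected[dec$node == 6])
  expect_true(dec$maximal[dec$node == 5])
  expect_false(dec$maximal[dec$node == 6])
  expect_false(dec$selected[dec$node == 7])
  expect_equal(sel$candidates, "G")

  # filter 2: without a keratinase tip the high-probability node fails
  ct2 <- ct
  ct2$tip_categories["K"] <- "keratinase_linked"
  sel2 <- select_clades(ct2, strains, "G11C", 0.5)
  expect_false(any(sel2$decisions$selected))

  # filter 3: no focal tip below
  sel3 <- select_clades(ct, strains, "ABSENT", 0.5)
  expect_false(any(sel3$decisions$selected))

  # threshold is strict: a node at exactly 0.5 does not pass
  ct4 <- ct
  ct4$node_probs[6, ] <- c(0.3, 0.2, 0.3, 0.2)
  ct4$node_probs[5, ] <- c(0.2, 0.2, 0.4, 0.2)
  sel4 <- select_clades(ct4, strains, "G11C", 0.5)
  expect_false(any(sel4$decisions$selected))

  # "either" rule requires one single category above the threshold
  sel5 <- select_clades(ct, strains, "G11C", 0.5, rule = "either")
  expect_false(sel5$decisions$selected[sel5$decisions$node == 5])
})

test_that("candidate set is invariant to tip order of the input tree", {
  set.seed(141)
  fx <- gen_families(2, 4, length = 150, within_divergence = 0.05,
                     seed = 151, strains = c("G11C", "CHD11"))
  msa <- stats::setNames(fx$records$sequence, fx$records$id)
  cats <- stats::setNames(
    ifelse(fx$truth$family == "FAM01", "functional_keratinase",
           "three_strain"), fx$truth$id)
  strains <- stats::setNames(fx$records$strain, fx$records$id)
  run_sel <- function(m) {
    tr <- midpoint_root(nj_tree(m))
    ct <- asr_er(tr, cats)
    select_clades(ct, strains, "G11C", 0.5)$candidates
  }
  c1 <- run_sel(msa)
  c2 <- run_sel(msa[sample(length(msa))])
  expect_identical(c1, c2)
})

test_that("annotated Newick export keeps probabilities on internal nodes", {
  tr <- ape::read.tree(text = "((K:1,G:1):1,(C:1,V:1):1);")
  cats <- pipeline_categories()
  ct <- asr_er(tr, stats::setNames(cats[c(1, 2, 3, 4)],
                                   c("K", "G", "C", "V")), q = 0.5)
  f <- tempfile(fileext = ".nwk")
  write_categorized_tree(ct, f)
  txt <- readLines(f)
  expect_match(txt, "=0\\.")
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), c("C", "G", "K", "V"))
})
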