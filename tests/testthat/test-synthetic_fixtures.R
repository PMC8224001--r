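test_that("family generator calibrates within/between identity and is seed-stable", {
  fx <- gen_families(2, 3, length = 240, within_divergence = 0.05,
                     seed = 161)
  expect_equal(nrow(fx$records), 6)
  fam <- stats::setNames(fx$truth$family, fx$truth$id)
  ids <- fx$records$id
  seqs <- stats::setNames(fx$records$sequence, ids)
  # direct position-wise identity (the generator is indel-free, so
  # sequences are column-comparable without alignment)
  hamming_id <- function(a, b) {
    100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  roots <- stats::setNames(fx$roots, c("FAM01", "FAM02"))
  for (i in 1:6) {
    # members stay >= 90% identical to their family root ...
    expect_gte(hamming_id(seqs[[i]], roots[[fam[ids[i]]]]), 90)
    # ... and at random background (~5%) against the other family root
    other <- setdiff(names(roots), fam[ids[i]])
    expect_lt(hamming_id(seqs[[i]], roots[[other]]), 20)
  }
  # significance mirrors the split: within-family pairs align with tiny
  # E-values, between-family pairs never reach the loosest cutoff
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ev <- align_pair(seqs[[i]], seqs[[j]])$evalue
      if (fam[ids[i]] == fam[ids[j]]) expect_lt(ev, 1e-40)
      else expect_gt(ev, 1e-5)
    }
  }
  # byte-identical regeneration under the same seed
  f1 <- tempfile(fileext = ".faa")
  f2 <- tempfile(fileext = ".faa")
  write_protein_fasta(gen_families(2, 3, seed = 161)$records, f1)
  write_protein_fasta(gen_families(2, 3, seed = 161)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_families(2, 3, within_divergence = 0.5), "0, 0.3")
})

test_that("indel mode produces length variation that exercises gap handling", {
  fx <- gen_families(1, 6, length = 240, within_divergence = 0.05,
                     seed = 171, indel_rate = 1)
  expect_gt(length(unique(nchar(fx$records$sequence))), 1)
})

test_that("ER history generator: q=0 inherits root; large q*t approaches uniform tips", {
  tr <- ape::rtree(20, rooted = TRUE)
  h0 <- gen_er_history(tr, q = 0, k = 4, seed = 5)
  expect_equal(length(unique(h0$tip_states)), 1)
  expect_equal(unique(h0$tip_states), h0$node_states[21])

  # stationary distribution: long branches, high rate -> uniform over k
  big <- ape::rtree(1000, rooted = TRUE)
  big$edge.length <- big$edge.length + 5
  h1 <- gen_er_history(big, q = 5, k = 4, seed = 6)
  tab <- table(factor(h1$tip_states, levels = 1:4))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)

  h2 <- gen_er_history(tr, q = 0.7, k = 4, seed = 7)
  h3 <- gen_er_history(tr, q = 0.7, k = 4, seed = 7)
  expect_identical(h2, h3)
})

test_that("scenario bundle files parse cleanly and regeneration is byte-identical", {
  sc <- shared_scenario()$bundle
  # every FASTA/TSV reads back through the package parsers
  for (s in c("G11C", "CHD11", "Vc74B-19")) {
    ps <- read_protein_fasta(sc$paths[[paste0("proteins_", s)]], s,
                             "query")
    expect_gt(nrow(ps), 0)
  }
  ker <- read_protein_fasta(sc$paths$keratinases, "panel",
                            "functional_keratinase")
  expect_equal(nrow(ker), 10)
  nk <- read_protein_fasta(sc$paths$non_keratinases, "panel",
                           "non_keratinase")
  expect_equal(nrow(nk), 8)
  db <- read_family_reference(sc$paths$family_reference)
  expect_true(all(c("S08", "S01", "M04") %in% db$family))
  fused <- parse_predictor_outputs(sc$paths$psortb, sc$paths$cello,
                                   sc$paths$signalp)
  expect_equal(ncol(fused) - 1L, 14)
  truth <- jsonlite::read_json(sc$paths$truth, simplifyVector = TRUE)
  expect_equal(sort(truth$candidates), sort(sc$truth$candidates))

  # regeneration under the same seed is byte-identical
  dir2 <- tempfile("sc2")
  sc2 <- gen_keratinase_scenario(dir2, seed = 42)
  for (p in c("proteins_G11C", "keratinases", "annotations_prokka",
              "family_reference", "psortb", "signalp", "truth")) {
    expect_identical(readLines(sc$paths[[p]]),
                     readLines(sc2$paths[[p]]),
                     label = paste("file", p))
  }
})

test_that("planted truth is consistent with the generated files", {
  sc <- shared_scenario()$bundle
  inputs <- shared_scenario()$inputs
  # planted keratinase-linked ids really share a family root with panel
  # keratinases: identity with some keratinase sequence is high
  ker <- inputs$keratinases
  seqs <- stats::setNames(inputs$queries$sequence, inputs$queries$id)
  linked_sample <- utils::head(sc$truth$keratinase_linked, 3)
  for (id in linked_sample) {
    best <- max(vapply(ker$sequence, function(ks) {
      align_pair(seqs[[id]], ks)$identity_pct
    }, numeric(1)))
    expect_gte(best, 85)
  }
  # planted extracellular ids score extracellular in the fused table
  feats <- read_fused_features(sc$paths$fused_features)
  extr <- predicted_extracellular(feats)
  expect_true(all(extr[sc$truth$extracellular]))
  intra_ids <- setdiff(feats$id, sc$truth$extracellular)
  expect_false(any(extr[intra_ids]))
})

test_that("scenario variants remove the paths to candidacy", {
  d1 <- tempfile("scnok")
  sc_nok <- gen_keratinase_scenario(d1, seed = 43,
                                    include_keratinase_panel = FALSE)
  expect_length(sc_nok$truth$candidates, 0)
  expect_false(file.exists(file.path(d1, "keratinases.faa")))

  d2 <- tempfile("scnof")
  sc_nof <- gen_keratinase_scenario(d2, seed = 44,
                                    focal_in_linked_family = FALSE)
  expect_length(sc_nof$truth$candidates, 0)
  qs <- read_protein_fasta(file.path(d2, "proteins_G11C.faa"), "G11C",
                           "query")
  expect_gt(nrow(qs), 0)   # focal strain still has (other) proteins
})
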