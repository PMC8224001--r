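test_that("family reference headers parse and malformed ones error", {
  f <- write_tmp(c(">MER0001|S08", "MKVLATGSDE", ">MER0002|M04",
                   "MKILATGSDE"), ".faa")
  db <- read_family_reference(f)
  expect_equal(db$family, c("S08", "M04"))
  expect_equal(db$superfamily, c("S", "M"))

  bad <- write_tmp(c(">MER0001", "MKVLAT"), ".faa")
  expect_error(read_family_reference(bad), "MER0001")
  badfam <- write_tmp(c(">MER0001|X99", "MKVLAT"), ".faa")
  expect_error(read_family_reference(badfam), "invalid family code")
})

test_that("reciprocal best hit assigns the right family and enforces the cutoff", {
  set.seed(41)
  fx <- gen_families(n_families = 2, size_per_family = 1, length = 240,
                     within_divergence = 0.05, seed = 41)
  # references: one S08 matching family 1, one M04 matching family 2
  ref_f <- tempfile(fileext = ".faa")
  writeLines(c(paste0(">R1|S08"), fx$roots[1],
               paste0(">R2|M04"), fx$roots[2]), ref_f)
  db <- read_family_reference(ref_f)
  fam <- assign_families(fx$records, db, 1e-20)
  truth <- stats::setNames(c("S08", "M04"), fx$truth$id)
  expect_equal(nrow(fam), 2)
  expect_equal(stats::setNames(fam$family, fam$id), truth[fam$id])

  # an impossible cutoff leaves everything unassigned
  none <- assign_families(fx$records, db, 1e-300)
  expect_equal(nrow(none), 0)
})

test_that("two near-identical queries competing for one reference: only the reciprocal wins", {
  # brute-force expectation: Q1 is closer to R than Q2, so R's best query
  # is Q1; Q2's best hit is still R but reciprocity fails for Q2
  root <- paste(rep("MSTKEEILRAFKQGLLTSTREEALKWAQRMGMDNPQVVAAYEKGELSREQFL",
                    5), collapse = "")
  q1 <- root
  q2 <- sub("^MSTKEEILRA", "MSTKEEILRV", root)   # one substitution
  queries <- protein_set(c("Q1", "Q2"), "G11C", "query", c(q1, q2))
  ref_f <- write_tmp(c(">R|S01", root), ".faa")
  db <- read_family_reference(ref_f)
  fam <- assign_families(queries, db, 1e-20)
  expect_equal(fam$id, "Q1")
  expect_equal(fam$family, "S01")
})

test_that("orthogroups are connected components above the cutoff; singletons unassigned", {
  hits <- data.frame(
    query =   c("A", "B", "A", "C", "D", "E"),
    subject = c("B", "A", "C", "A", "E", "D"),
    evalue = c(1e-50, 1e-48, 1e-45, 1e-44, 1e-60, 1e-61),
    bitscore = 200, raw_score = NA, identity_pct = 90,
    alignment_length = 100L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, stringsAsFactors = FALSE)
  recs <- protein_set(c("A", "B", "C", "D", "E", "F"),
                      c("G11C", "CHD11", "Vc74B-19", "G11C", "CHD11",
                        "G11C"),
                      "query", rep("MKVLAT", 6))
  og <- cluster_p_orthogroups(hits, recs, 1e-40)
  expect_equal(og$n_groups, 2)
  expect_setequal(og$groups$id[og$groups$group == 1], c("A", "B", "C"))
  expect_setequal(og$groups$id[og$groups$group == 2], c("D", "E"))
  expect_equal(og$unassigned, "F")

  # stricter cutoff can only split/shrink, never merge
  og_strict <- cluster_p_orthogroups(hits, recs, 1e-49)
  for (g in unique(og_strict$groups$group)) {
    members <- og_strict$groups$id[og_strict$groups$group == g]
    parent_groups <- unique(og$groups$group[og$groups$id %in% members])
    expect_length(parent_groups, 1)
  }
})

test_that("planted family partition is recovered exactly", {
  fx <- gen_families(n_families = 10, size_per_family = 3, length = 240,
                     within_divergence = 0.05, seed = 51)
  hits <- all_vs_all(fx$records, evalue_cutoff = 1)
  og <- cluster_p_orthogroups(hits, fx$records, 1e-40)
  expect_equal(og$n_groups, 10)
  expect_length(og$unassigned, 0)
  got <- lapply(split(og$groups$id, og$groups$group), sort)
  want <- lapply(split(fx$truth$id, fx$truth$family), sort)
  expect_setequal(unname(vapply(got, paste, "", collapse = ",")),
                  unname(vapply(want, paste, "", collapse = ",")))
  # partition property: each protease in exactly one group or unassigned
  all_ids <- c(og$groups$id, og$unassigned)
  expect_setequal(all_ids, fx$records$id)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("orthogroups from single-family clusters carry one family code", {
  fx <- gen_families(n_families = 4, size_per_family = 3, length = 240,
                     within_divergence = 0.05, seed = 61)
  ref_f <- tempfile(fileext = ".faa")
  writeLines(as.vector(rbind(sprintf(">R%d|%s", 1:4,
                                     c("S08", "S01", "M04", "C02")),
                             fx$roots)), ref_f)
  db <- read_family_reference(ref_f)
  fam <- assign_families(fx$records, db, 1e-20)
  hits <- all_vs_all(fx$records, evalue_cutoff = 1)
  og <- cluster_p_orthogroups(hits, fx$records, 1e-40)
  gf <- orthogroup_families(og, fam)
  expect_false(any(gf$mixed))
  expect_setequal(gf$family, c("S08", "S01", "M04", "C02"))
})

test_that("strain overlap counts Venn regions and matches a constructed fixture", {
  # 4 groups with all three strains, 2 groups with strain A only
  groups <- do.call(rbind, c(
    lapply(1:4, function(g) data.frame(
      group = g, id = sprintf("g%d_%s", g, c("a", "b", "c")),
      strain = c("A", "B", "C"), stringsAsFactors = FALSE)),
    lapply(5:6, function(g) data.frame(
      group = g, id = sprintf("g%d_%s", g, c("a1", "a2")),
      strain = c("A", "A"), stringsAsFactors = FALSE))))
  og <- structure(list(groups = groups, unassigned = character(),
                       n_groups = 6L), class = "p_orthogroups")
  ov <- strain_overlap(og, c("A", "B", "C"))
  expect_equal(unname(ov$regions[["A&B&C"]]), 4L)
  expect_equal(unname(ov$regions[["A"]]), 2L)
  expect_equal(sum(ov$regions), ov$n_groups)
  expect_equal(unname(ov$totals[["A"]]), 6L)
  expect_equal(unname(ov$totals[["B"]]), 4L)

  # pairwise-only region
  g7 <- data.frame(group = 7, id = c("x1", "x2"), strain = c("A", "B"))
  og2 <- structure(list(groups = rbind(groups, g7),
                        unassigned = character(), n_groups = 7L),
                   class = "p_orthogroups")
  ov2 <- strain_overlap(og2, c("A", "B", "C"))
  expect_equal(unname(ov2$regions[["A&B"]]), 1L)
  expect_equal(sum(ov2$regions), 7L)
})
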