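AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(length) {
  paste(sample(AMINO_ACIDS, length, replace = TRUE), collapse = "")
}

# Poisson(length * divergence) substitutions at distinct interior
# positions, each to a different residue. Interior placement keeps local
# alignments full-length so identity arithmetic on fixtures stays exact.
mutate_protein <- function(seq, divergence, indel_rate = 0) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  nsub <- min(stats::rpois(1, L * divergence), max(L - 4, 0))
  if (nsub > 0) {
    pos <- sample(seq(3, L - 2), nsub)
    for (p in pos) {
      chars[p] <- sample(setdiff(AMINO_ACIDS, chars[p]), 1)
    }
  }
  if (indel_rate > 0 && stats::runif(1) < indel_rate) {
    dlen <- sample(3:10, 1)
    start <- sample(seq(3, L - dlen - 2), 1)
    chars <- chars[-(start:(start + dlen - 1))]
  }
  paste(chars, collapse = "")
}

#' Generate divergent protein families with known membership
#'
#' Each family grows from an independent random root sequence; members
#' carry Poisson(length x within_divergence) substitutions (no indels by
#' default, so members stay aligned and identity arithmetic is exact;
#' an optional indel rate exercises gap handling). Between-family
#' identity is at the random background (about 1/20 per position).
#' Members are assigned round-robin to the strains.
#'
#' @param n_families Number of families.
#' @param size_per_family Members per family (a single integer or one
#'   per family; size-1 families become orthogroup-unassigned
#'   singletons downstream).
#' @param length Root sequence length (default 240).
#' @param within_divergence Expected per-site substitution fraction
#'   within a family, in (0, 0.3) (default 0.05).
#' @param seed Integer seed; the same seed reproduces identical output.
#' @param strains Strain labels for round-robin assignment.
#' @param indel_rate Per-member probability of one short deletion.
#' @return list: `records` ([protein_set()]), `truth` (data.frame `id`,
#'   `family`), `roots` (family root sequences).
#' @export
gen_families <- function(n_families, size_per_family, length = 240L,
                         within_divergence = 0.05, seed = 1L,
                         strains = c("G11C", "CHD11", "Vc74B-19"),
                         indel_rate = 0) {
  if (within_divergence <= 0 || within_divergence >= 0.3) {
    stop("within_divergence must lie in (0, 0.3)")
  }
  if (length < 30) stop("length must be >= 30")
  sizes <- rep_len(size_per_family, n_families)
  with_seed(seed, {
    counters <- stats::setNames(integer(base::length(strains)), strains)
    rows <- list(); truth <- list(); roots <- character(n_families)
    member_i <- 0L
    for (f in seq_len(n_families)) {
      root <- random_protein(length)
      roots[f] <- root
      for (s in seq_len(sizes[f])) {
        member_i <- member_i + 1L
        strain <- strains[(member_i - 1L) %% base::length(strains) + 1L]
        counters[strain] <- counters[strain] + 1L
        id <- sprintf("%s_%05d", strain, counters[strain])
        rows[[base::length(rows) + 1L]] <- data.frame(
          id = id, strain = strain, category = "query",
          sequence = mutate_protein(root, within_divergence, indel_rate),
          stringsAsFactors = FALSE)
        truth[[base::length(truth) + 1L]] <- data.frame(
          id = id, family = sprintf("FAM%02d", f),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    list(records = protein_set(df$id, df$strain, df$category, df$sequence),
         truth = do.call(rbind, truth), roots = roots)
  })
}

#' Simulate a discrete-character history under the ER model
#'
#' Draws a root state uniformly over the k states, then evolves states
#' down every branch under the equal-rates Markov process (transition
#' probabilities of [er_transition_matrix()]). Internal-node truth is
#' returned for recovery tests.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param q ER transition rate (> 0; q = 0 copies the root state
#'   everywhere).
#' @param k Number of states (default 4).
#' @param seed Integer seed.
#' @return list: `tip_states` (named integer vector over tips),
#'   `node_states` (integer vector over all nodes in ape numbering),
#'   `tip_categories` (named character vector using
#'   [pipeline_categories()] when k = 4, else `state<i>` labels).
#' @export
gen_er_history <- function(tree, q, k = 4L, seed = 1L) {
  if (q < 0) stop("q must be >= 0")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tree_po <- ape::reorder.phylo(tree, "postorder")
  with_seed(seed, {
    state <- integer(nn)
    state[ntip + 1L] <- sample.int(k, 1)
    for (e in rev(seq_len(nrow(tree_po$edge)))) {
      par <- tree_po$edge[e, 1]; chi <- tree_po$edge[e, 2]
      P <- er_transition_matrix(q, tree_po$edge.length[e], k)
      state[chi] <- sample.int(k, 1, prob = P[state[par], ])
    }
    labels <- if (k == 4L) pipeline_categories() else
      paste0("state", seq_len(k))
    tips <- stats::setNames(state[seq_len(ntip)], tree$tip.label)
    list(tip_states = tips, node_states = state,
         tip_categories = stats::setNames(labels[tips], tree$tip.label))
  })
}

# Draw one fused 14-feature localization vector for a profile class.
# PSORTb-style scores live on a 0-10 scale, CELLO-style on roughly 0-5,
# SignalP rows are 4 probabilities renormalized to sum exactly 1.
localization_profile_vector <- function(profile, noise_sd = 0.15) {
  base <- switch(profile,
    extracellular_sp  = list(ps = c(0.5, 0.5, 0.3, 9.0),
                             ce = c(0.3, 0.3, 0.8, 4.0),
                             sig = c(0.88, 0.03, 0.03)),
    extracellular_tat = list(ps = c(0.6, 0.8, 1.6, 7.6),
                             ce = c(0.3, 0.6, 1.4, 3.4),
                             sig = c(0.03, 0.85, 0.03)),
    extracellular_lipo = list(ps = c(0.5, 1.4, 0.6, 8.2),
                              ce = c(0.3, 1.0, 0.6, 3.8),
                              sig = c(0.03, 0.03, 0.84)),
    intracellular = list(ps = c(8.8, 0.6, 0.2, 0.2),
                         ce = c(4.3, 0.4, 0.1, 0.2),
                         sig = c(0.015, 0.01, 0.01)),
    stop("unknown profile: ", profile))
  ps <- pmax(0, stats::rnorm(4, base$ps, noise_sd))
  ce <- pmax(0, stats::rnorm(4, base$ce, noise_sd / 2))
  sig3 <- pmax(1e-4, stats::rnorm(3, base$sig, noise_sd / 10))
  other <- max(1e-4, 1 - sum(base$sig) + stats::rnorm(1, 0, noise_sd / 10))
  sig4 <- c(sig3, other) / sum(c(sig3, other))
  poss <- sum(sig4[1:3])
  c(ps, ce, sig4, 1 - poss, poss)
}

#' Generate a localization feature fixture with planted classes
#'
#' Score vectors for a planted mixture of extracellular (signal-peptide
#' carrying) and intracellular proteins, in the fused 14-feature layout.
#' Used to test that the embedding plus DBSCAN recovers the planted
#' separation.
#'
#' @param n_extracellular,n_intracellular Class sizes.
#' @param seed Integer seed.
#' @return list: `features` (`localization_features`), `truth` (named
#'   character vector id -> `"extracellular"`/`"intracellular"`).
#' @export
gen_localization_fixture <- function(n_extracellular = 150L,
                                     n_intracellular = 150L, seed = 1L) {
  with_seed(seed, {
    n <- n_extracellular + n_intracellular
    ids <- sprintf("P%04d", seq_len(n))
    classes <- c(rep("extracellular", n_extracellular),
                 rep("intracellular", n_intracellular))
    rows <- t(vapply(classes, function(cl) {
      localization_profile_vector(
        if (cl == "extracellular") "extracellular_sp" else "intracellular")
    }, numeric(14)))
    df <- data.frame(id = ids, rows, stringsAsFactors = FALSE)
    names(df) <- c("id", localization_feature_names())
    rownames(df) <- NULL
    class(df) <- c("localization_features", "data.frame")
    list(features = df, truth = stats::setNames(classes, ids))
  })
}

# Write predictor files in the three raw dialects plus the fused TSV.
# All four files carry the same rounded values (4 decimals for the
# compartment scores, 6 for the SignalP probabilities, derived features
# recomputed from the rounded ones), so the raw-dialect and fused input
# paths are numerically identical downstream.
write_predictor_files <- function(features, dir) {
  f <- as.data.frame(features)
  for (col in grep("^(psortb|cello)_", names(f), value = TRUE)) {
    f[[col]] <- round(f[[col]], 4)
  }
  for (col in c("signalp_sp", "signalp_tat", "signalp_lipo",
                "signalp_other")) {
    f[[col]] <- round(f[[col]], 6)
  }
  f$signalp_possibility <- f$signalp_sp + f$signalp_tat + f$signalp_lipo
  f$signalp_intracellular <- 1 - f$signalp_possibility
  features <- f
  class(features) <- c("localization_features", "data.frame")
  fmt <- function(x) sprintf("%.4f", x)
  ps <- data.frame(SeqID = f$id,
                   Cytoplasmic_Score = fmt(f$psortb_cytoplasmic),
                   CytoplasmicMembrane_Score = fmt(f$psortb_membrane),
                   Cellwall_Score = fmt(f$psortb_wall),
                   Extracellular_Score = fmt(f$psortb_extracellular),
                   Final_Localization = ifelse(
                     f$psortb_extracellular >
                       pmax(f$psortb_cytoplasmic, f$psortb_membrane,
                            f$psortb_wall),
                     "Extracellular", "Cytoplasmic"))
  write_stage_tsv(ps, file.path(dir, "psortb.tsv"))
  ce <- data.frame(SeqID = f$id, Cytoplasmic = fmt(f$cello_cytoplasmic),
                   Membrane = fmt(f$cello_membrane),
                   CellWall = fmt(f$cello_wall),
                   Extracellular = fmt(f$cello_extracellular))
  write_stage_tsv(ce, file.path(dir, "cello.tsv"))
  sp_path <- file.path(dir, "signalp.tsv")
  con <- file(sp_path, "w")
  writeLines(c("# SignalP-5.0\tOrganism: gram+\ttimestamp: fixed",
               paste0("# ID\tPrediction\tSP(Sec/SPI)\tTAT(Tat/SPI)\t",
                      "LIPO(Sec/SPII)\tOTHER\tCS Position")), con)
  pred <- c("SP(Sec/SPI)", "TAT(Tat/SPI)", "LIPO(Sec/SPII)", "OTHER")
  which4 <- max.col(cbind(f$signalp_sp, f$signalp_tat, f$signalp_lipo,
                          f$signalp_other), ties.method = "first")
  writeLines(sprintf("%s\t%s\t%.6f\t%.6f\t%.6f\t%.6f\t",
                     f$id, pred[which4], f$signalp_sp, f$signalp_tat,
                     f$signalp_lipo, f$signalp_other), con)
  close(con)
  write_fused_features(features, file.path(dir, "fused_features.tsv"))
  invisible(dir)
}

#' Generate the full keratinase screening scenario
#'
#' Builds a self-contained fixture bundle emulating the study's data
#' shape: three query strains, a functional-keratinase panel and a
#' non-keratinase panel; a planted keratinase-linked family structure
#' (two extracellular families shared with panel keratinases, one
#' extracellular decoy without keratinases, one extracellular family
#' absent from the focal strain, one intracellular family, and
#' orthogroup-unassigned singletons); localization score files in the
#' three raw predictor dialects plus the fused table; per-extracellular
#' profile MSAs; and a truth JSON with the planted families, linked
#' ids, extracellular ids and candidate ids.
#'
#' The planted candidates are exactly the focal-strain members of the
#' two keratinase-sharing extracellular families: their clades contain
#' functional keratinases and focal tips, and their ancestral states are
#' dominated by the keratinase/keratinase-linked categories, so the
#' three-filter clade selection should return them and nothing else.
#'
#' @param dir Output directory (created; files are overwritten).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param preset `"minimal"` (ca. 66 proteins, perplexity 10, DBSCAN eps
#'   0.08 — radius scaled for the sparser plane) or `"paper-shaped"`
#'   (584 query proteases + 61 + 50 panel members, study defaults).
#' @param include_keratinase_panel Set `FALSE` to drop the functional
#'   keratinase panel (then no clade can pass filter 2).
#' @param focal_in_linked_family Set `FALSE` to remove the focal strain
#'   from the keratinase-sharing families (then filter 3 can never
#'   pass).
#' @return list of class `"fixture_bundle"`: `dir`, `paths`, `config`,
#'   `truth`.
#' @export
gen_keratinase_scenario <- function(dir = tempfile("scenario"),
                                    seed = 42L,
                                    preset = c("minimal", "paper-shaped"),
                                    include_keratinase_panel = TRUE,
                                    focal_in_linked_family = TRUE) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strains <- c("G11C", "CHD11", "Vc74B-19")
  # per-preset composition: counts per strain for the query families,
  # totals for panels/singletons. The paper-shaped preset reproduces the
  # study scale (580 query proteases, 61 keratinases, 50 non-keratinases).
  nn <- if (preset == "minimal") {
    list(f1q = 2L, f2q = 2L, f3q = 2L, f4q = 3L, f5q = 2L, singleton = 5L,
         f1ker = 6L, f2ker = 2L, f5ker = 2L, f2nk = 2L, nk_scatter = 6L,
         non_protease = 4L)
  } else {
    list(f1q = 12L, f2q = 12L, f3q = 12L, f4q = 140L, f5q = 12L,
         singleton = 28L, f1ker = 45L, f2ker = 8L, f5ker = 8L,
         f2nk = 10L, nk_scatter = 40L, non_protease = 8L)
  }
  config <- if (preset == "minimal") {
    # perplexity and DBSCAN radius rescaled for the sparser plane
    pipeline_config(random_seed = seed, tsne_perplexity = 10,
                    dbscan_eps = 0.08, focal_strain = "G11C")
  } else {
    pipeline_config(random_seed = seed, focal_strain = "G11C")
  }

  with_seed(seed + 1L, {
    counters <- stats::setNames(integer(3), strains)
    next_id <- function(strain) {
      counters[strain] <<- counters[strain] + 1L
      sprintf("%s_%05d", strain, counters[strain])
    }
    L <- 240L; div <- 0.05
    proteins <- list(); fam_truth <- list()
    panels <- list()
    ker_i <- 0L; nk_i <- 0L
    add_query <- function(strain, seq, family) {
      id <- next_id(strain)
      proteins[[length(proteins) + 1L]] <<- data.frame(
        id = id, strain = strain, category = "query", sequence = seq,
        stringsAsFactors = FALSE)
      fam_truth[[length(fam_truth) + 1L]] <<- data.frame(
        id = id, family = family, stringsAsFactors = FALSE)
      id
    }
    add_panel <- function(category, seq) {
      if (category == "functional_keratinase") {
        ker_i <<- ker_i + 1L
        id <- sprintf("KER%03d", ker_i)
        strain <- "keratinase_panel"
      } else {
        nk_i <<- nk_i + 1L
        id <- sprintf("NONKER%03d", nk_i)
        strain <- "non_keratinase_panel"
      }
      panels[[length(panels) + 1L]] <<- data.frame(
        id = id, strain = strain, category = category, sequence = seq,
        stringsAsFactors = FALSE)
      id
    }

    fam_root <- list()
    fam <- function(name) {
      fam_root[[name]] <<- random_protein(L)
      fam_root[[name]]
    }
    ids <- list()

    # F1: keratinase-linked family (subtilisin-like, S08 analog)
    r <- fam("F1")
    ids$F1_query <- character()
    for (s in strains) {
      n_here <- if (s == "G11C" && !focal_in_linked_family) 0L else nn$f1q
      for (i in seq_len(n_here)) {
        ids$F1_query <- c(ids$F1_query,
                          add_query(s, mutate_protein(r, div), "F1"))
      }
    }
    ids$F1_ker <- character()
    if (include_keratinase_panel) {
      for (i in seq_len(nn$f1ker)) {
        ids$F1_ker <- c(ids$F1_ker,
                        add_panel("functional_keratinase",
                                  mutate_protein(r, div)))
      }
    }

    # F2: second keratinase-linked family (trypsin-like, S01 analog),
    # with two non-keratinase panel members as in the study's community 4
    r <- fam("F2")
    ids$F2_query <- character()
    for (s in strains) {
      n_here <- if (s == "G11C" && !focal_in_linked_family) 0L else nn$f2q
      for (i in seq_len(n_here)) {
        ids$F2_query <- c(ids$F2_query,
                          add_query(s, mutate_protein(r, div), "F2"))
      }
    }
    ids$F2_ker <- character(); ids$F2_nk <- character()
    if (include_keratinase_panel) {
      for (i in seq_len(nn$f2ker)) {
        ids$F2_ker <- c(ids$F2_ker,
                        add_panel("functional_keratinase",
                                  mutate_protein(r, div)))
      }
    }
    for (i in seq_len(nn$f2nk)) {
      ids$F2_nk <- c(ids$F2_nk,
                     add_panel("non_keratinase", mutate_protein(r, div)))
    }

    # F3: extracellular decoy family without any keratinase (M04 analog)
    r <- fam("F3")
    ids$F3_query <- unlist(lapply(strains, function(s) {
      vapply(seq_len(nn$f3q), function(i) {
        add_query(s, mutate_protein(r, div), "F3")
      }, "")
    }))

    # F4: intracellular family (Lon-protease analog)
    r <- fam("F4")
    ids$F4_query <- unlist(lapply(strains, function(s) {
      vapply(seq_len(nn$f4q), function(i) {
        add_query(s, mutate_protein(r, div), "F4")
      }, "")
    }))

    # F5: extracellular keratinase-sharing family absent from the focal
    # strain (filter-3 decoy)
    r <- fam("F5")
    ids$F5_query <- unlist(lapply(c("CHD11", "Vc74B-19"), function(s) {
      vapply(seq_len(nn$f5q), function(i) {
        add_query(s, mutate_protein(r, div), "F5")
      }, "")
    }))
    ids$F5_ker <- character()
    if (include_keratinase_panel) {
      for (i in seq_len(nn$f5ker)) {
        ids$F5_ker <- c(ids$F5_ker,
                        add_panel("functional_keratinase",
                                  mutate_protein(r, div)))
      }
    }

    # unassigned-orthogroup singletons (intracellular)
    singleton_strains <- rep(strains, length.out = nn$singleton)
    ids$singleton <- vapply(singleton_strains, function(s) {
      add_query(s, random_protein(L), paste0("SINGLETON"))
    }, "")

    # scattered non-keratinase panel singletons (intracellular profile)
    ids$nk_scatter <- vapply(seq_len(nn$nk_scatter), function(i) {
      add_panel("non_keratinase", random_protein(L))
    }, "")

    # non-protease genes (never mined, no localization rows)
    ids$non_protease <- unlist(lapply(strains, function(s) {
      vapply(seq_len(nn$non_protease), function(i) next_id(s), "")
    }))
    for (id in ids$non_protease) {
      s <- strains[startsWith(id, strains)][1]
      proteins[[length(proteins) + 1L]] <- data.frame(
        id = id, strain = s, category = "query",
        sequence = random_protein(L), stringsAsFactors = FALSE)
    }

    prot_df <- do.call(rbind, proteins)
    panel_df <- do.call(rbind, panels)
    queries <- protein_set(prot_df$id, prot_df$strain, prot_df$category,
                           prot_df$sequence)
    panel_set <- if (!is.null(panel_df)) {
      protein_set(panel_df$id, panel_df$strain, panel_df$category,
                  panel_df$sequence)
    } else NULL

    # ---- annotations (three annotators) --------------------------------
    fam_of <- do.call(rbind, fam_truth)
    desc_for <- function(id) {
      f <- fam_of$family[fam_of$id == id]
      if (!length(f)) return(NULL)
      switch(f,
        F1 = list(prokka = "Subtilisin-like serine peptidase",
                  pannzer = "Peptidase S8 family protein",
                  eggnog = "serine protease"),
        F2 = list(prokka = "Trypsin-like serine protease",
                  pannzer = "trypsin-like serine protease"),
        F3 = list(prokka = "Zinc metalloprotease"),
        F4 = list(prokka = "ATP-dependent protease La",
                  eggnog = "Lon protease homolog"),
        F5 = list(pannzer = "Peptidase S1 family protein"),
        SINGLETON = NULL)
    }
    singleton_desc <- list(
      list(prokka = "Sortase A"),
      list(pannzer = "Caspase-like domain protein"),
      list(prokka = "Insulinase family protein"),
      list(eggnog = "Penicillin-binding protein 2"),
      list(prokka = "Snapalysin"))
    non_protease_desc <- list(
      list(prokka = "hypothetical protein"),
      list(prokka = "DNA gyrase subunit A",
           eggnog = "DNA topoisomerase (ATP-hydrolyzing)"),
      list(pannzer = "50S ribosomal protein L1"),
      list(prokka = "Penicillin amidase family protein"))
    ann <- list(prokka = list(), pannzer = list(), eggnog = list())
    push_desc <- function(id, d) {
      for (a in names(d)) {
        ann[[a]][[length(ann[[a]]) + 1L]] <<- data.frame(
          id = id, description = d[[a]], stringsAsFactors = FALSE)
      }
    }
    for (id in fam_of$id[fam_of$family != "SINGLETON"]) {
      push_desc(id, desc_for(id))
    }
    for (i in seq_along(ids$singleton)) {
      push_desc(ids$singleton[i],
                singleton_desc[[(i - 1L) %% 5L + 1L]])
    }
    for (i in seq_along(ids$non_protease)) {
      push_desc(ids$non_protease[i],
                non_protease_desc[[(i - 1L) %% 4L + 1L]])
    }

    # ---- family reference DB -------------------------------------------
    ref_fams <- c(F1 = "S08", F2 = "S01", F3 = "M04", F4 = "S16",
                  F5 = "S01")
    ref <- lapply(names(ref_fams), function(f) {
      sprintf(">MER%04d|%s\n%s", match(f, names(ref_fams)), ref_fams[f],
              mutate_protein(fam_root[[f]], 0.02))
    })
    # unrelated references (should never be assigned)
    ref <- c(ref, lapply(1:3, function(i) {
      sprintf(">MER%04d|%s", 100 + i, c("C02", "M17", "A01")[i]) |>
        paste(random_protein(L), sep = "\n")
    }))

    # ---- localization profiles -----------------------------------------
    profile_of <- c(
      stats::setNames(rep("extracellular_sp",
                          length(c(ids$F1_query, ids$F1_ker, ids$F2_query,
                                   ids$F2_ker, ids$F2_nk))),
                      c(ids$F1_query, ids$F1_ker, ids$F2_query, ids$F2_ker,
                        ids$F2_nk)),
      stats::setNames(rep("extracellular_tat", length(ids$F3_query)),
                      ids$F3_query),
      stats::setNames(rep("extracellular_lipo",
                          length(c(ids$F5_query, ids$F5_ker))),
                      c(ids$F5_query, ids$F5_ker)),
      stats::setNames(rep("intracellular",
                          length(c(ids$F4_query, ids$singleton,
                                   ids$nk_scatter))),
                      c(ids$F4_query, ids$singleton, ids$nk_scatter)))
    loc_ids <- names(profile_of)
    feat_rows <- t(vapply(loc_ids, function(id) {
      localization_profile_vector(profile_of[[id]])
    }, numeric(14)))
    features <- data.frame(id = loc_ids, feat_rows,
                           stringsAsFactors = FALSE)
    names(features) <- c("id", localization_feature_names())
    rownames(features) <- NULL
    class(features) <- c("localization_features", "data.frame")

    # ---- write everything ----------------------------------------------
    paths <- list()
    for (s in strains) {
      p <- file.path(dir, sprintf("proteins_%s.faa", s))
      write_protein_fasta(queries[queries$strain == s, ], p)
      paths[[paste0("proteins_", s)]] <- p
    }
    if (!is.null(panel_set)) {
      kp <- panel_set[panel_set$category == "functional_keratinase", ]
      if (nrow(kp)) {
        paths$keratinases <- file.path(dir, "keratinases.faa")
        write_protein_fasta(kp, paths$keratinases)
      }
      np <- panel_set[panel_set$category == "non_keratinase", ]
      paths$non_keratinases <- file.path(dir, "non_keratinases.faa")
      write_protein_fasta(np, paths$non_keratinases)
    }
    for (a in names(ann)) {
      tab <- do.call(rbind, ann[[a]])
      p <- file.path(dir, sprintf("annotations_%s.tsv", a))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths[[paste0("annotations_", a)]] <- p
    }
    paths$family_reference <- file.path(dir, "family_reference.faa")
    writeLines(unlist(ref), paths$family_reference)
    write_predictor_files(features, dir)
    paths$psortb <- file.path(dir, "psortb.tsv")
    paths$cello <- file.path(dir, "cello.tsv")
    paths$signalp <- file.path(dir, "signalp.tsv")
    paths$fused_features <- file.path(dir, "fused_features.tsv")

    # per-profile MSAs over the planted extracellular sets (members are
    # equal-length and indel-free, so the stacked sequences are aligned)
    all_recs <- if (is.null(panel_set)) queries else
      bind_protein_sets(queries, panel_set)
    seq_of <- stats::setNames(all_recs$sequence, all_recs$id)
    msa_sets <- list(
      extracellular_sp = c(ids$F1_query, ids$F1_ker, ids$F2_query,
                           ids$F2_ker, ids$F2_nk),
      extracellular_tat = ids$F3_query,
      extracellular_lipo = c(ids$F5_query, ids$F5_ker))
    for (nm in names(msa_sets)) {
      mem <- msa_sets[[nm]]
      if (length(mem) < 3) next
      p <- file.path(dir, sprintf("msa_%s.fasta", nm))
      write_msa(seq_of[mem], p)
      paths[[paste0("msa_", nm)]] <- p
    }

    planted_candidates <- if (include_keratinase_panel &&
                                focal_in_linked_family) {
      sort(c(ids$F1_query[startsWith(ids$F1_query, "G11C")],
             ids$F2_query[startsWith(ids$F2_query, "G11C")]))
    } else character()
    truth <- list(
      seed = seed, preset = preset,
      families = stats::setNames(fam_of$family, fam_of$id),
      orthogroup_partition = lapply(
        split(fam_of$id[fam_of$family != "SINGLETON"],
              fam_of$family[fam_of$family != "SINGLETON"]), sort),
      unassigned = sort(ids$singleton),
      keratinase_linked = sort(c(ids$F1_query, ids$F2_query,
                                 ids$F5_query)),
      extracellular = sort(names(profile_of)[
        profile_of != "intracellular"]),
      family_codes = as.list(ref_fams),
      candidates = planted_candidates)
    if (!include_keratinase_panel) truth$keratinase_linked <- character()
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths$config <- file.path(dir, "config.json")
    write_pipeline_config(config, paths$config)

    structure(list(dir = dir, paths = paths, config = config,
                   truth = truth),
              class = "fixture_bundle")
  })
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Two label vectors of equal length (any atomic type).
#' @return Scalar ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
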