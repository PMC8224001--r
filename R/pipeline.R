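resolve_protein_input <- function(x, strain, category) {
  if (inherits(x, "protein_set")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_protein_fasta(x, strain, category))
  }
  stop("expected a protein_set or a FASTA path")
}

#' Assemble pipeline inputs
#'
#' Normalizes the heterogeneous stage inputs into one list consumed by
#' [run_pipeline()]. Every element accepts either an in-memory object or
#' a file path.
#'
#' @param proteins Named list/vector: strain -> `protein_set` or FASTA
#'   path (all records become category `"query"`).
#' @param keratinases `protein_set` or FASTA of the functional
#'   keratinase panel (may be `NULL`).
#' @param non_keratinases `protein_set` or FASTA of the non-keratinase
#'   panel (may be `NULL`).
#' @param annotations Named list/vector: annotator -> annotation table
#'   (data.frame or TSV path).
#' @param family_reference Family reference (data.frame from
#'   [read_family_reference()] or FASTA path).
#' @param localization One of: a `localization_features` data.frame; a
#'   fused TSV path; or a list with `psortb`, `cello`, `signalp` paths.
#' @param msas Optional list of MSAs (named character vectors or aligned
#'   FASTA paths); each is used for the t-SNE group whose member set
#'   matches its sequence names.
#' @param trees Optional list of trees (`ape::phylo` or Newick paths),
#'   matched to groups by tip set.
#' @return list of class `"pipeline_inputs"`.
#' @export
pipeline_inputs <- function(proteins, keratinases = NULL,
                            non_keratinases = NULL, annotations = list(),
                            family_reference = NULL, localization = NULL,
                            msas = NULL, trees = NULL) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  prot <- lapply(names(proteins), function(s) {
    resolve_protein_input(proteins[[s]], s, "query")
  })
  queries <- do.call(bind_protein_sets, prot)
  ker <- if (!is.null(keratinases)) {
    resolve_protein_input(keratinases, "keratinase_panel",
                          "functional_keratinase")
  }
  nonker <- if (!is.null(non_keratinases)) {
    resolve_protein_input(non_keratinases, "non_keratinase_panel",
                          "non_keratinase")
  }
  ann <- lapply(names(annotations), function(a) {
    x <- annotations[[a]]
    if (is.data.frame(x)) x else read_annotation_table(x, a)
  })
  ann <- do.call(consolidate_annotations, ann)
  fam <- if (!is.null(family_reference)) {
    if (is.data.frame(family_reference)) family_reference
    else read_family_reference(family_reference)
  }
  loc <- if (!is.null(localization)) {
    if (inherits(localization, "localization_features")) localization
    else if (is.character(localization)) read_fused_features(localization)
    else parse_predictor_outputs(localization$psortb, localization$cello,
                                 localization$signalp)
  }
  msas <- if (!is.null(msas)) {
    lapply(msas, function(m) if (is.character(m) && length(m) == 1L &&
                                   file.exists(m)) read_msa(m) else m)
  }
  trees <- if (!is.null(trees)) {
    lapply(trees, function(t) if (inherits(t, "phylo")) t
           else ape::read.tree(t))
  }
  structure(list(queries = queries, keratinases = ker,
                 non_keratinases = nonker, annotations = ann,
                 family_reference = fam, localization = loc,
                 msas = msas, trees = trees),
            class = "pipeline_inputs")
}

#' Pipeline inputs from a fixture bundle
#'
#' @param bundle A [gen_keratinase_scenario()] result (or its directory).
#' @param fused Use the pre-fused feature table instead of the three raw
#'   predictor files (default FALSE).
#' @param use_msas Hand the planted per-profile MSAs to the pipeline
#'   (default TRUE; set FALSE to exercise the internal MSA path).
#' @return A `pipeline_inputs` list.
#' @export
scenario_inputs <- function(bundle, fused = FALSE, use_msas = TRUE) {
  dir <- if (is.character(bundle)) bundle else bundle$dir
  strains <- c("G11C", "CHD11", "Vc74B-19")
  prot <- stats::setNames(
    file.path(dir, sprintf("proteins_%s.faa", strains)), strains)
  ker_path <- file.path(dir, "keratinases.faa")
  msa_paths <- Sys.glob(file.path(dir, "msa_*.fasta"))
  pipeline_inputs(
    proteins = as.list(prot),
    keratinases = if (file.exists(ker_path)) ker_path else NULL,
    non_keratinases = file.path(dir, "non_keratinases.faa"),
    annotations = list(
      prokka = file.path(dir, "annotations_prokka.tsv"),
      pannzer = file.path(dir, "annotations_pannzer.tsv"),
      eggnog = file.path(dir, "annotations_eggnog.tsv")),
    family_reference = file.path(dir, "family_reference.faa"),
    localization = if (fused) file.path(dir, "fused_features.tsv") else
      list(psortb = file.path(dir, "psortb.tsv"),
           cello = file.path(dir, "cello.tsv"),
           signalp = file.path(dir, "signalp.tsv")),
    msas = if (use_msas && length(msa_paths)) as.list(msa_paths) else NULL)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

# MSA for a t-SNE group: a supplied MSA with exactly the member set wins;
# otherwise indel-free equal-length sequences are stacked; otherwise mafft
# (if on PATH) aligns them.
group_msa <- function(members, seq_of, supplied) {
  if (!is.null(supplied)) {
    for (m in supplied) {
      if (setequal(names(m), members)) return(m[sort(members)])
    }
  }
  seqs <- seq_of[sort(members)]
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  if (Sys.which("mafft") != "") {
    td <- tempfile("mafft"); dir.create(td)
    on.exit(unlink(td, recursive = TRUE))
    inp <- file.path(td, "in.fasta")
    write_msa(seqs, inp)  # unaligned is valid FASTA too
    out <- system2("mafft", c("--auto", "--quiet", inp), stdout = TRUE)
    tf <- file.path(td, "out.fasta"); writeLines(out, tf)
    return(read_msa(tf))
  }
  stop("group sequences are unaligned and no MSA was supplied ",
       "(and mafft is not on the PATH)")
}

find_tree <- function(members, supplied) {
  if (is.null(supplied)) return(NULL)
  for (t in supplied) if (setequal(t$tip.label, members)) return(t)
  NULL
}

#' Run the full keratinase-screening pipeline
#'
#' Executes the stages in order: keyword mining over consolidated
#' annotations; reciprocal-best-hit family assignment; p-orthogroup
#' clustering with strain-overlap accounting; similarity-network
#' construction over the query proteases plus both panels with weighted
#' Louvain communities and keratinase linkage; localization-score
#' embedding (PCA, t-SNE) with DBSCAN grouping; and, for every t-SNE
#' group holding at least one functional keratinase and three members,
#' occupancy-filtered MSA, (supplied or neighbor-joining) midpoint-rooted
#' tree, ER ancestral state reconstruction and three-filter clade
#' selection. Deterministic given `config$random_seed`.
#'
#' @param config A [pipeline_config()].
#' @param inputs A [pipeline_inputs()] list.
#' @param outdir Optional directory for per-stage TSV/JSON/GraphML
#'   artifacts.
#' @param align_backend `"auto"` (blastp when on PATH and the union set
#'   is large), `"native"`, or `"blast"`.
#' @return list of class `"candidate_report"`: `report` (one row per
#'   mined query protease), `candidates`, plus the per-stage objects
#'   (`mining`, `families`, `orthogroups`, `overlap`, `network`,
#'   `communities`, `linked`, `embedding`, `tsne_groups`, `trees`,
#'   `clades`).
#' @export
run_pipeline <- function(config, inputs, outdir = NULL,
                         align_backend = c("auto", "native", "blast")) {
  align_backend <- match.arg(align_backend)
  stopifnot(inherits(config, "pipeline_config"),
            inherits(inputs, "pipeline_inputs"))
  queries <- inputs$queries

  mining <- stage("mine", mine_proteases(queries, inputs$annotations,
                                         config$mining_keywords))
  proteases <- queries[queries$id %in% mining$selected, , drop = FALSE]

  empty <- function() {
    structure(list(report = empty_report(), candidates = character(),
                   mining = mining, families = empty_family_assignment(),
                   orthogroups = NULL, overlap = NULL, network = NULL,
                   communities = NULL, linked = NULL, embedding = NULL,
                   tsne_groups = NULL, trees = list(), clades = list(),
                   config = config),
              class = "candidate_report")
  }
  if (!nrow(proteases)) {
    res <- empty()
    if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
    return(res)
  }

  union_set <- stage("network", bind_protein_sets(
    proteases, inputs$keratinases, inputs$non_keratinases))
  backend <- if (align_backend == "auto") {
    if (nrow(union_set) > 150 && Sys.which("blastp") != "") "blast"
    else "native"
  } else align_backend
  hits <- stage("align", all_vs_all(union_set, evalue_cutoff = 1,
                                    backend = backend))

  families <- stage("families", {
    if (is.null(inputs$family_reference)) empty_family_assignment()
    else assign_families(proteases, inputs$family_reference,
                         config$family_evalue)
  })

  protease_hits <- hits[hits$query %in% proteases$id &
                          hits$subject %in% proteases$id, , drop = FALSE]
  orthogroups <- stage("orthogroups", cluster_p_orthogroups(
    protease_hits, proteases, config$orthogroup_evalue))
  overlap <- stage("orthogroups", strain_overlap(
    orthogroups, unique(proteases$strain)))

  network <- stage("network", build_network(hits, union_set,
                                            config$network_evalue))
  communities <- stage("network", detect_communities(
    network, config$louvain_resolution, config$random_seed))
  linked <- stage("network", link_keratinases(
    communities, network, hits, rule = config$keratinase_link_rule))

  features <- stage("embed", {
    loc <- inputs$localization
    if (is.null(loc)) stop("no localization input supplied")
    missing <- setdiff(union_set$id, loc$id)
    if (length(missing)) {
      stop("no localization scores for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    out <- loc[match(union_set$id, loc$id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  embedding <- stage("embed", embed_features(features, config))
  tsne_groups <- stage("embed", cluster_tsne(
    embedding, config$dbscan_eps, config$dbscan_min_samples))
  extracellular <- stage("embed", predicted_extracellular(features))

  # phylogeny on groups holding at least one functional keratinase
  seq_of <- stats::setNames(union_set$sequence, union_set$id)
  cat_of <- stats::setNames(union_set$category, union_set$id)
  strain_of <- stats::setNames(union_set$strain, union_set$id)
  tip_category <- ifelse(
    cat_of == "query",
    ifelse(names(cat_of) %in% linked$linked, "keratinase_linked",
           "three_strain"),
    cat_of)
  names(tip_category) <- names(cat_of)

  trees <- list(); clades <- list(); candidates <- character()
  analyzed_groups <- character()
  for (g in names(tsne_groups$groups)) {
    members <- tsne_groups$groups[[g]]
    if (length(members) < 3) next
    if (!any(cat_of[members] == "functional_keratinase")) next
    analyzed_groups <- c(analyzed_groups, g)
    res <- stage(paste0("phylo[group ", g, "]"), {
      msa <- group_msa(members, seq_of, inputs$msas)
      occ <- occupancy_filter(msa, config$occupancy_threshold)
      kept <- names(occ$msa)
      tr <- find_tree(members, inputs$trees)
      if (is.null(tr)) {
        if (length(kept) < 3) stop("fewer than 3 sequences after ",
                                   "occupancy filtering")
        tr <- nj_tree(occ$msa)
      }
      tr <- midpoint_root(tr)
      ctree <- asr_er(tr, tip_category[tr$tip.label],
                      seed = config$random_seed)
      sel <- select_clades(ctree, strain_of, config$focal_strain,
                           config$clade_probability_threshold,
                           rule = config$clade_probability_rule)
      list(occupancy = occ, ctree = ctree, selection = sel)
    })
    trees[[g]] <- res$ctree
    clades[[g]] <- res
    candidates <- c(candidates, res$selection$candidates)
  }
  candidates <- sort(unique(candidates))

  report <- build_report(proteases, mining, families, orthogroups,
                         communities, linked, tsne_groups, extracellular,
                         analyzed_groups, candidates)
  res <- structure(list(report = report, candidates = candidates,
                        mining = mining, families = families,
                        orthogroups = orthogroups, overlap = overlap,
                        network = network, communities = communities,
                        linked = linked, embedding = embedding,
                        tsne_groups = tsne_groups, trees = trees,
                        clades = clades, config = config),
                   class = "candidate_report")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

empty_report <- function() {
  data.frame(id = character(), strain = character(), family = character(),
             p_orthogroup = character(), community = character(),
             keratinase_linked = logical(), tsne_group = character(),
             predicted_extracellular = logical(),
             clade_selected = logical(), evidence = character(),
             stringsAsFactors = FALSE)
}

build_report <- function(proteases, mining, families, orthogroups,
                         communities, linked, tsne_groups, extracellular,
                         analyzed_groups, candidates) {
  ids <- proteases$id
  fam <- families$family[match(ids, families$id)]
  og <- orthogroups$groups$group[match(ids, orthogroups$groups$id)]
  comm <- communities$membership[ids]
  grp <- vapply(ids, function(i) {
    hit <- names(Filter(function(mem) i %in% mem, tsne_groups$groups))
    if (length(hit)) hit[1] else NA_character_
  }, "")
  mined_tab <- mining$table
  evid <- vapply(ids, function(i) {
    row <- mined_tab[mined_tab$id == i, , drop = FALSE]
    notes <- sprintf("keywords=%s", row$keywords)
    if (row$review_flagged) notes <- paste0(notes, ";single-annotator")
    notes
  }, "")
  data.frame(
    id = ids, strain = proteases$strain,
    family = ifelse(is.na(fam), "unassigned", fam),
    p_orthogroup = ifelse(is.na(og), "unassigned", as.character(og)),
    community = ifelse(is.na(comm), "singleton", as.character(comm)),
    keratinase_linked = ids %in% linked$linked,
    tsne_group = ifelse(is.na(grp), "noise", grp),
    predicted_extracellular = unname(extracellular[ids]),
    clade_selected = ids %in% candidates,
    evidence = evid, stringsAsFactors = FALSE)
}

#' Write all per-stage pipeline artifacts
#'
#' TSVs for mining, families, orthogroups, communities, embedding and
#' the final report; Venn-region and run-summary JSONs; network GraphML
#' and edge list; per-group annotated Newick trees and compact MSAs.
#'
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_stage_tsv(result$report, file.path(outdir, "report.tsv"))
  writeLines(result$candidates, file.path(outdir, "candidates.txt"))
  if (!is.null(result$mining)) {
    write_stage_tsv(result$mining$table, file.path(outdir, "mining.tsv"))
  }
  if (!is.null(result$families) && nrow(result$families)) {
    write_stage_tsv(result$families, file.path(outdir, "families.tsv"))
  }
  if (!is.null(result$orthogroups)) {
    write_orthogroups_tsv(result$orthogroups,
                          file.path(outdir, "orthogroups.tsv"),
                          result$families)
    jsonlite::write_json(
      list(regions = as.list(result$overlap$regions),
           totals = as.list(result$overlap$totals),
           n_groups = result$overlap$n_groups),
      file.path(outdir, "venn_regions.json"), auto_unbox = TRUE)
  }
  if (!is.null(result$network)) {
    write_stage_tsv(result$network$edges, file.path(outdir, "edges.tsv"))
    write_stage_tsv(result$communities$communities,
                    file.path(outdir, "communities.tsv"))
    write_network_graphml(result$network, result$communities,
                          result$linked,
                          file.path(outdir, "network.graphml"))
  }
  if (!is.null(result$embedding)) {
    emb <- data.frame(id = result$embedding$id,
                      result$embedding$pca, result$embedding$tsne,
                      tsne_group = result$tsne_groups$labels[
                        result$embedding$id])
    write_stage_tsv(emb, file.path(outdir, "embedding.tsv"))
  }
  for (g in names(result$trees)) {
    write_categorized_tree(result$trees[[g]],
                           file.path(outdir, sprintf("tree_group%s.nwk", g)))
    write_msa(result$clades[[g]]$occupancy$msa,
              file.path(outdir, sprintf("msa_group%s_compact.fasta", g)))
  }
  summary <- list(
    n_proteases = nrow(result$report),
    n_candidates = length(result$candidates),
    candidates = result$candidates,
    n_orthogroups = result$orthogroups$n_groups %||% 0L,
    n_communities = if (is.null(result$communities)) 0L else
      length(unique(result$communities$communities$community)),
    n_keratinase_linked = if (is.null(result$linked)) 0L else
      length(result$linked$linked),
    modularity = result$communities$modularity %||% NA_real_,
    analyzed_groups = names(result$trees) %||% character())
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
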