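#' Read a MEROPS-style family reference FASTA
#'
#' Headers carry the family code after a pipe: `>REFID|S08`. Family codes
#' are a superfamily letter (A, C, G, M, N, S, T, P or U — aspartic,
#' cysteine, glutamic, metallo, asparagine, serine, threonine, mixed,
#' unknown) followed by digits.
#'
#' @param path Reference FASTA.
#' @return data.frame (`id`, `family`, `superfamily`, `sequence`).
#' @export
read_family_reference <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed family reference header (expected 'id|FAMILY'): ",
         hdr[which(bad)[1]])
  }
  id <- vapply(parts, `[[`, "", 1L)
  fam <- vapply(parts, `[[`, "", 2L)
  okfam <- grepl("^[ACGMNSTPU][0-9]+$", fam)
  if (any(!okfam)) {
    stop("invalid family code in reference header: ", hdr[which(!okfam)[1]])
  }
  seqs <- toupper(as.character(aa)); names(seqs) <- NULL
  seqs <- sub("\\*$", "", seqs)
  if (anyDuplicated(id)) {
    stop("duplicate reference id: ", id[duplicated(id)][1])
  }
  data.frame(id = id, family = fam, superfamily = substr(fam, 1, 1),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Assign peptidase families by reciprocal best hit
#'
#' A query receives the family of reference R iff R is the query's best
#' hit (lowest E-value at or under the cutoff) and the query is in turn
#' R's best hit among all queries. Best-hit ties break toward the higher
#' bitscore, then the lexicographically smaller id, so assignment is
#' deterministic.
#'
#' @param queries A [protein_set()].
#' @param reference_db data.frame from [read_family_reference()].
#' @param evalue_cutoff RBH E-value threshold (default 1e-20).
#' @param scoring An [align_scoring()].
#' @return data.frame (`id`, `family`, `superfamily`, `reference_id`,
#'   `evalue`), one row per assigned query; unassigned queries have no
#'   row.
#' @export
assign_families <- function(queries, reference_db, evalue_cutoff = 1e-20,
                            scoring = align_scoring()) {
  nq <- nrow(queries); nr <- nrow(reference_db)
  if (!nq || !nr) return(empty_family_assignment())
  ref_res <- sum(nchar(reference_db$sequence))
  qry_res <- sum(nchar(queries$sequence))

  hits <- vector("list", nr)
  for (j in seq_len(nr)) {
    e <- align_engine(queries$sequence, reference_db$sequence[j], scoring)
    bit <- bit_from_raw(e$raw, scoring)
    hits[[j]] <- data.frame(
      qi = seq_len(nq), rj = j, bitscore = bit,
      ev_qr = evalue_from_bit(bit, nchar(queries$sequence), ref_res),
      ev_rq = evalue_from_bit(bit, nchar(reference_db$sequence[j]), qry_res))
  }
  h <- do.call(rbind, hits)

  # best reference per query (query -> reference direction)
  hq <- data.frame(by = h$qi, evalue = h$ev_qr, bitscore = h$bitscore,
                   other = h$rj, other_id = reference_db$id[h$rj])
  hq <- hq[hq$evalue <= evalue_cutoff, , drop = FALSE]
  oq <- order(hq$by, hq$evalue, -hq$bitscore, hq$other_id)
  hq <- hq[oq[!duplicated(hq$by[oq])], , drop = FALSE]
  # best query per reference (reference -> query direction)
  hr <- data.frame(by = h$rj, evalue = h$ev_rq, bitscore = h$bitscore,
                   other = h$qi, other_id = queries$id[h$qi])
  hr <- hr[hr$evalue <= evalue_cutoff, , drop = FALSE]
  or_ <- order(hr$by, hr$evalue, -hr$bitscore, hr$other_id)
  hr <- hr[or_[!duplicated(hr$by[or_])], , drop = FALSE]

  if (!nrow(hq) || !nrow(hr)) return(empty_family_assignment())
  rows <- lapply(seq_len(nrow(hq)), function(k) {
    qi <- hq$by[k]; rj <- hq$other[k]
    back <- hr$other[hr$by == rj]
    if (length(back) == 1L && back == qi) {
      data.frame(id = queries$id[qi],
                 family = reference_db$family[rj],
                 superfamily = reference_db$superfamily[rj],
                 reference_id = reference_db$id[rj],
                 evalue = hq$evalue[k], stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_family_assignment() else out
}

empty_family_assignment <- function() {
  data.frame(id = character(), family = character(),
             superfamily = character(), reference_id = character(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Cluster proteases into p-orthogroups
#'
#' Builds an undirected graph on the mined proteases with an edge when
#' either directed hit passes the E-value cutoff, and reports connected
#' components of size >= 2 as protease orthogroups (p-orthogroups);
#' singletons are "unassigned p-orthogroup" peptidases. Group ids are
#' assigned by decreasing size, then by lexicographically smallest
#' member.
#'
#' @param hits Alignment-hit data.frame from [all_vs_all()] over the
#'   protease set (reference panels excluded).
#' @param records `protein_set` of the clustered proteases (supplies the
#'   node universe and strain labels).
#' @param evalue_cutoff Orthogrouping threshold (default 1e-40).
#' @return list of class `"p_orthogroups"`: `groups` data.frame
#'   (`group`, `id`, `strain`), `unassigned` character vector,
#'   `n_groups`.
#' @export
cluster_p_orthogroups <- function(hits, records, evalue_cutoff = 1e-40) {
  ids <- records$id
  h <- hits[hits$evalue <= evalue_cutoff & hits$query != hits$subject &
              hits$query %in% ids & hits$subject %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = h$query, to = h$subject), directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  memb <- comp$membership[ids]
  sizes <- table(memb)
  group_of <- names(sizes)[sizes >= 2]
  # order groups by decreasing size, then smallest member id
  info <- lapply(group_of, function(cid) {
    members <- ids[memb == cid]
    list(cid = cid, size = length(members), min_id = min(members))
  })
  o <- order(-vapply(info, `[[`, 0L, "size"),
             vapply(info, `[[`, "", "min_id"))
  info <- info[o]
  rows <- lapply(seq_along(info), function(k) {
    members <- sort(ids[memb == info[[k]]$cid])
    data.frame(group = k, id = members,
               strain = records$strain[match(members, ids)],
               stringsAsFactors = FALSE)
  })
  groups <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = integer(), id = character(), strain = character(),
               stringsAsFactors = FALSE)
  unassigned <- ids[!(ids %in% groups$id)]
  structure(list(groups = groups, unassigned = unassigned,
                 n_groups = length(info)),
            class = "p_orthogroups")
}

#' Family composition of p-orthogroups
#'
#' Annotates each group with the single family code shared by its
#' assigned members, or flags it mixed when members carry different
#' codes.
#'
#' @param orthogroups A `p_orthogroups` object.
#' @param families data.frame from [assign_families()].
#' @return data.frame (`group`, `family`, `mixed`): `family` is the
#'   shared code, `"unassigned"` when no member has one, or the
#'   semicolon-joined codes when `mixed`.
#' @export
orthogroup_families <- function(orthogroups, families) {
  gs <- unique(orthogroups$groups$group)
  rows <- lapply(gs, function(g) {
    members <- orthogroups$groups$id[orthogroups$groups$group == g]
    fam <- unique(families$family[families$id %in% members])
    if (!length(fam)) {
      data.frame(group = g, family = "unassigned", mixed = FALSE)
    } else if (length(fam) == 1L) {
      data.frame(group = g, family = fam, mixed = FALSE)
    } else {
      data.frame(group = g, family = paste(sort(fam), collapse = ";"),
                 mixed = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = integer(), family = character(),
                      mixed = logical())
  }
  out
}

#' Strain overlap of p-orthogroups (Venn regions)
#'
#' Counts groups per region of the strain Venn diagram: for every
#' non-empty subset S of strains, the number of groups whose represented
#' strain set is exactly S.
#'
#' @param orthogroups A `p_orthogroups` object.
#' @param strains Character vector of all strains (regions are
#'   enumerated over these even when empty).
#' @return list: `regions` named integer vector (names are
#'   `&`-joined sorted strain subsets), `totals` groups per strain,
#'   `n_groups` total group count.
#' @export
strain_overlap <- function(orthogroups, strains) {
  strains <- sort(unique(strains))
  subsets <- unlist(lapply(seq_along(strains), function(k) {
    utils::combn(strains, k, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- stats::setNames(integer(length(subsets)), subsets)
  gs <- unique(orthogroups$groups$group)
  for (g in gs) {
    pres <- sort(unique(
      orthogroups$groups$strain[orthogroups$groups$group == g]))
    key <- paste(pres, collapse = "&")
    if (key %in% names(regions)) regions[key] <- regions[key] + 1L
  }
  totals <- vapply(strains, function(s) {
    length(unique(
      orthogroups$groups$group[orthogroups$groups$strain == s]))
  }, integer(1))
  list(regions = regions, totals = totals, n_groups = length(gs))
}

#' Write p-orthogroups as TSV
#'
#' Columns: `group`, `id`, `strain`, `family` (per-group family code from
#' [orthogroup_families()] when supplied); unassigned proteases appear
#' with group `NA`.
#'
#' @param orthogroups A `p_orthogroups`.
#' @param path Output TSV.
#' @param families Optional [assign_families()] table.
#' @export
write_orthogroups_tsv <- function(orthogroups, path, families = NULL) {
  df <- orthogroups$groups
  if (!is.null(families) && nrow(df)) {
    gf <- orthogroup_families(orthogroups, families)
    df$family <- gf$family[match(df$group, gf$group)]
  } else if (nrow(df)) {
    df$family <- NA_character_
  }
  if (length(orthogroups$unassigned)) {
    df <- rbind(df, data.frame(group = NA_integer_,
                               id = orthogroups$unassigned,
                               strain = NA_character_,
                               family = NA_character_))
  }
  write_stage_tsv(df, path)
}
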