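#' Construct a protein record table
#'
#' The shared container for every stage: one row per protein with its id,
#' strain (or panel name), category and amino-acid sequence. Categories are
#' `"query"` for proteins of the strains under study,
#' `"functional_keratinase"` for the characterized reference panel and
#' `"non_keratinase"` for the hypothetical non-keratinase panel.
#'
#' @param id Character vector of unique protein ids.
#' @param strain Strain label or panel name per protein.
#' @param category One of `"query"`, `"functional_keratinase"`,
#'   `"non_keratinase"` per protein (recycled if length 1).
#' @param sequence Amino-acid sequences (20 standard letters plus X).
#'
#' @return A data.frame of class `"protein_set"`.
#' @export
protein_set <- function(id, strain, category, sequence) {
  df <- data.frame(id = as.character(id), strain = as.character(strain),
                   category = as.character(category),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  validate_protein_set(df)
  class(df) <- c("protein_set", "data.frame")
  df
}

valid_protein_categories <- c("query", "functional_keratinase",
                              "non_keratinase")

validate_protein_set <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (any(!nzchar(df$id))) stop("protein ids must be non-empty")
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("duplicate protein id(s): ", paste(utils::head(dup, 5),
                                            collapse = ", "))
  }
  bad_cat <- setdiff(unique(df$category), valid_protein_categories)
  if (length(bad_cat)) {
    stop("unknown protein category: ", paste(bad_cat, collapse = ", "))
  }
  if (any(!nzchar(df$sequence))) {
    stop("zero-length sequence for id(s): ",
         paste(df$id[!nzchar(df$sequence)], collapse = ", "))
  }
  check_residues(df$sequence, df$id)
  invisible(df)
}

# 20 standard amino acids plus X (unknown residue)
check_residues <- function(seqs, ids) {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  hit <- which(bad > 0)
  if (length(hit)) {
    i <- hit[1]
    stop(sprintf("non-amino-acid character '%s' at position %d of '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  invisible(TRUE)
}

#' Read a protein FASTA file into a protein set
#'
#' Ids are the first whitespace-delimited token of each header. Sequences
#' are upper-cased and a terminal stop character (`*`) is stripped;
#' any other non-amino-acid character is an error.
#'
#' @param path FASTA file.
#' @param strain Strain label (or panel name) applied to all records.
#' @param category Category applied to all records (see [protein_set()]).
#' @return A `protein_set`.
#' @export
read_protein_fasta <- function(path, strain, category = "query") {
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- NULL
  protein_set(id = ids, strain = strain, category = category,
              sequence = seqs)
}

#' Write a protein set as FASTA
#'
#' @param records A `protein_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Combine several protein sets
#'
#' @param ... `protein_set` objects.
#' @return A single `protein_set`; duplicate ids across the inputs are an
#'   error.
#' @export
bind_protein_sets <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  df <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  rownames(df) <- NULL
  protein_set(df$id, df$strain, df$category, df$sequence)
}

#' Read a per-annotator annotation table
#'
#' Tab-separated table whose first column is a protein id; the description
#' column is selected by index or name. Multiple rows for one id are kept
#' as multiple descriptions.
#'
#' @param path TSV file (a header line is detected when the configured
#'   description column is non-numeric and the first field equals
#'   `id_col`'s name; simplest is headerless id/description pairs).
#' @param annotator_name Label recorded with every description.
#' @param desc_col Description column (1-based index, default 2).
#' @param header Does the file carry a header line?
#' @return A data.frame (`id`, `annotator`, `description`), one row per
#'   description; ids absent from the table simply have no rows.
#' @export
read_annotation_table <- function(path, annotator_name, desc_col = 2L,
                                  header = FALSE) {
  df <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) {
      # empty file -> empty mapping
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      stop(e)
    })
  if (!nrow(df)) {
    return(data.frame(id = character(), annotator = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  if (ncol(df) < desc_col) {
    stop(sprintf("annotation table '%s' lacks description column %d (%d columns found)",
                 path, desc_col, ncol(df)))
  }
  data.frame(id = as.character(df[[1L]]),
             annotator = annotator_name,
             description = as.character(df[[desc_col]]),
             stringsAsFactors = FALSE)
}

#' Consolidate annotator tables
#'
#' Joins any number of per-annotator description tables into one long
#' table keyed by protein id. Ids present in the protein set but absent
#' from every table are tolerated (they carry no descriptions and can
#' never be selected by keyword mining).
#'
#' @param ... Data frames from [read_annotation_table()].
#' @return One long data.frame (`id`, `annotator`, `description`).
#' @export
consolidate_annotations <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0,
                        logical(1))]
  if (!length(parts)) {
    return(data.frame(id = character(), annotator = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Annotation descriptions for one id
#'
#' @param annotations Long annotation table.
#' @param id Protein id.
#' @return Character vector of descriptions (possibly empty).
#' @export
annotations_for <- function(annotations, id) {
  annotations$description[annotations$id == id]
}

# Deterministic TSV writer shared by all stage outputs: fixed column order,
# no quoting, no row names, "." decimal marks.
write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
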