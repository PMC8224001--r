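#' Mine putative proteases by annotation keywords
#'
#' A protein is selected iff any keyword occurs as a case-insensitive
#' substring of any of its descriptions from any annotator ("a keyword in
#' at least one of the predictions"). Multi-word keywords are matched as
#' whole phrases, so "penicillin-binding protein" can hit while the
#' generic word "protein" alone never does. Selection by a single
#' annotator only is recorded in `review_flagged` — the stand-in for
#' manual homology curation of borderline calls.
#'
#' @param records A [protein_set()] (query proteins).
#' @param annotations Long annotation table from
#'   [consolidate_annotations()].
#' @param keywords Keyword vector; defaults to
#'   [default_mining_keywords()].
#' @return A list of class `"mining_result"`: `selected` (character ids,
#'   in input order), `table` (one row per selected id: matched keywords,
#'   triggering annotators, review flag), `review_flagged` (ids whose
#'   keyword evidence comes from exactly one annotator).
#' @export
mine_proteases <- function(records, annotations,
                           keywords = default_mining_keywords()) {
  stopifnot(length(keywords) >= 1)
  ann <- annotations[annotations$id %in% records$id, , drop = FALSE]
  desc_l <- tolower(ann$description)
  kw_l <- tolower(keywords)

  # keyword k matched in description row r?
  match_rows <- lapply(kw_l, function(k) grepl(k, desc_l, fixed = TRUE))
  any_match <- Reduce(`|`, match_rows, accumulate = FALSE) %||%
    logical(length(desc_l))

  sel_tab <- NULL
  if (length(desc_l)) {
    hit_idx <- which(any_match)
    if (length(hit_idx)) {
      per_hit <- lapply(hit_idx, function(r) {
        kws <- keywords[vapply(match_rows, function(m) m[r], logical(1))]
        data.frame(id = ann$id[r], annotator = ann$annotator[r],
                   keyword = kws, stringsAsFactors = FALSE)
      })
      sel_tab <- do.call(rbind, per_hit)
    }
  }

  if (is.null(sel_tab)) {
    selected <- character()
    table <- data.frame(id = character(), keywords = character(),
                        annotators = character(),
                        review_flagged = logical(),
                        stringsAsFactors = FALSE)
  } else {
    selected <- records$id[records$id %in% unique(sel_tab$id)]
    rows <- lapply(selected, function(i) {
      sub <- sel_tab[sel_tab$id == i, , drop = FALSE]
      anns <- sort(unique(sub$annotator))
      data.frame(id = i,
                 keywords = paste(sort(unique(sub$keyword)), collapse = ";"),
                 annotators = paste(anns, collapse = ";"),
                 review_flagged = length(anns) == 1L,
                 stringsAsFactors = FALSE)
    })
    table <- do.call(rbind, rows)
  }

  out <- list(selected = selected, table = table,
              review_flagged = table$id[table$review_flagged])
  class(out) <- "mining_result"
  out
}

#' Write a mining result as TSV
#'
#' One row per input protein: `id`, `selected`, `keywords`, `annotators`,
#' `review_flag`.
#'
#' @param mining A `mining_result`.
#' @param records The `protein_set` mined.
#' @param path Output TSV.
#' @export
write_mining_tsv <- function(mining, records, path) {
  tab <- mining$table
  m <- match(records$id, tab$id)
  df <- data.frame(id = records$id,
                   selected = !is.na(m),
                   keywords = ifelse(is.na(m), "", tab$keywords[m]),
                   annotators = ifelse(is.na(m), "", tab$annotators[m]),
                   review_flag = !is.na(m) & tab$review_flagged[m],
                   stringsAsFactors = FALSE)
  write_stage_tsv(df, path)
}
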