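#' Alignment scoring parameters
#'
#' Substitution matrix plus affine gap penalties and gapped
#' Karlin–Altschul parameters used to convert raw Smith–Waterman scores
#' into bitscores and E-values. Defaults mirror standard protein-search
#' settings: BLOSUM62, gap open 11, gap extend 1, lambda 0.267, K 0.041,
#' so E-value magnitudes are comparable with blastp output.
#'
#' @param matrix Substitution matrix name (one shipped with Biostrings,
#'   e.g. `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty per residue (positive).
#' @param lambda,K Gapped Karlin–Altschul parameters.
#' @return A list of class `"align_scoring"`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    mat <- get(matrix, envir = env)
  } else {
    mat <- matrix
  }
  structure(list(matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "align_scoring")
}

# Karlin-Altschul conversion: bitscore from raw score, E-value from search
# space m*n (single pair) or m*N (database of N residues).
bit_from_raw <- function(raw, scoring) {
  (scoring$lambda * raw - log(scoring$K)) / log(2)
}

evalue_from_bit <- function(bit, m, n) {
  # in log space to survive bitscores > 1074
  exp(log(m) + log(n) - bit * log(2))
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(),
             raw_score = numeric(), bitscore = numeric(),
             evalue = numeric(), identity_pct = numeric(),
             alignment_length = integer(), qstart = integer(),
             qend = integer(), sstart = integer(), send = integer(),
             stringsAsFactors = FALSE)
}

# Core engine: local (Smith-Waterman) alignment of one subject sequence
# against a set of patterns; returns per-pattern score, identity (gap
# columns counted in the denominator, the blastp convention), alignment
# length and 1-based aligned spans.
align_engine <- function(patterns, subject, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = FALSE)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  alen <- nchar(p)
  nid <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, p, s, USE.NAMES = FALSE)
  list(raw = Biostrings::score(aln),
       identity_pct = 100 * nid / alen,
       alignment_length = as.integer(alen),
       qstart = Biostrings::start(Biostrings::pattern(aln)),
       qend = Biostrings::end(Biostrings::pattern(aln)),
       sstart = Biostrings::start(Biostrings::subject(aln)),
       send = Biostrings::end(Biostrings::subject(aln)))
}

#' Align one pair of protein sequences
#'
#' Smith–Waterman local alignment with affine gaps. Percent identity
#' counts gap columns in the denominator. The bitscore is
#' `(lambda * raw - ln K) / ln 2` and the E-value `m * n * 2^(-bitscore)`
#' with `m`, `n` the two sequence lengths (single-pair convention), or
#' `n = db_residues` when a database size is supplied.
#'
#' @param seqA,seqB Amino-acid sequences (character).
#' @param scoring An [align_scoring()].
#' @param db_residues Optional database residue count replacing `n`.
#' @param query,subject Optional ids recorded in the hit.
#' @return One-row data.frame (an alignment hit): `query`, `subject`,
#'   `raw_score`, `bitscore`, `evalue`, `identity_pct`,
#'   `alignment_length`, `qstart`, `qend`, `sstart`, `send`.
#' @export
align_pair <- function(seqA, seqB, scoring = align_scoring(),
                       db_residues = NULL, query = "query",
                       subject = "subject") {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  stopifnot(nzchar(seqA), nzchar(seqB))
  check_residues(c(seqA, seqB), c(query, subject))
  e <- align_engine(seqA, seqB, scoring)
  bit <- bit_from_raw(e$raw, scoring)
  n <- db_residues %||% nchar(seqB)
  data.frame(query = query, subject = subject, raw_score = e$raw,
             bitscore = bit,
             evalue = evalue_from_bit(bit, nchar(seqA), n),
             identity_pct = e$identity_pct,
             alignment_length = e$alignment_length,
             qstart = e$qstart, qend = e$qend,
             sstart = e$sstart, send = e$send,
             stringsAsFactors = FALSE)
}

#' All-vs-all local alignment of a protein set
#'
#' Every unordered pair is aligned once (the raw score is symmetric) and
#' reported in both directions, as search tools do; the two directed
#' E-values differ through the query length. The database size entering
#' the E-value is the total residue count of the record set. The
#' `"blast"` backend shells out to `makeblastdb`/`blastp` when those
#' binaries are on the PATH and is interchangeable with the native engine
#' at the order-of-magnitude level of E-values.
#'
#' @param records A [protein_set()] with >= 2 rows (a single record
#'   yields an empty hit table).
#' @param scoring An [align_scoring()] (native backend only).
#' @param evalue_cutoff Keep directed hits with `evalue <= cutoff`.
#' @param backend `"native"` (Smith–Waterman in-process) or `"blast"`.
#' @return Alignment-hit data.frame (see [align_pair()]).
#' @export
all_vs_all <- function(records, scoring = align_scoring(),
                       evalue_cutoff = 1, backend = c("native", "blast")) {
  backend <- match.arg(backend)
  n_rec <- nrow(records)
  if (n_rec < 2) return(empty_hits())
  if (backend == "blast") {
    return(all_vs_all_blast(records, evalue_cutoff))
  }
  db <- sum(nchar(records$sequence))
  out <- vector("list", n_rec - 1L)
  for (i in seq_len(n_rec - 1L)) {
    js <- (i + 1L):n_rec
    e <- align_engine(records$sequence[js], records$sequence[i], scoring)
    bit <- bit_from_raw(e$raw, scoring)
    ev_ji <- evalue_from_bit(bit, nchar(records$sequence[js]), db)
    ev_ij <- evalue_from_bit(bit, nchar(records$sequence[i]), db)
    # direction j -> i (patterns were the j sequences)
    fwd <- data.frame(query = records$id[js], subject = records$id[i],
                      raw_score = e$raw, bitscore = bit, evalue = ev_ji,
                      identity_pct = e$identity_pct,
                      alignment_length = e$alignment_length,
                      qstart = e$qstart, qend = e$qend,
                      sstart = e$sstart, send = e$send,
                      stringsAsFactors = FALSE)
    rev <- data.frame(query = records$id[i], subject = records$id[js],
                      raw_score = e$raw, bitscore = bit, evalue = ev_ij,
                      identity_pct = e$identity_pct,
                      alignment_length = e$alignment_length,
                      qstart = e$sstart, qend = e$send,
                      sstart = e$qstart, send = e$qend,
                      stringsAsFactors = FALSE)
    both <- rbind(fwd, rev)
    out[[i]] <- both[both$evalue <= evalue_cutoff, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (is.null(res)) empty_hits() else res
}

# blastp adapter: best HSP per directed pair, self-hits dropped.
all_vs_all_blast <- function(records, evalue_cutoff) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("blast backend requested but blastp/makeblastdb not on PATH")
  }
  td <- tempfile("blastdb"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "set.faa")
  write_protein_fasta(records, fa)
  dbp <- file.path(td, "db")
  sys_quiet("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", dbp))
  outp <- file.path(td, "hits.tsv")
  sys_quiet("blastp", c("-query", fa, "-db", dbp, "-outfmt", "6",
                        "-evalue", format(evalue_cutoff, scientific = TRUE),
                        "-out", outp))
  hits <- import_alignment_tabular(outp)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  # best HSP per directed pair
  key <- paste(hits$query, hits$subject, sep = "\r")
  hits <- hits[order(key, hits$evalue, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$query, hits$subject, sep = "\r")), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

sys_quiet <- function(cmd, args) {
  res <- system2(cmd, args, stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    stop(sprintf("%s failed (exit %d): %s", cmd, status,
                 paste(utils::tail(res, 3), collapse = " | ")))
  }
  invisible(res)
}

#' Import precomputed alignment hits (12-column tabular format)
#'
#' Parses the standard 12-column tabular search format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`); identity, length, E-value and bitscore are taken
#' verbatim. Lines starting with `#` are skipped.
#'
#' @param path Tabular file.
#' @return Alignment-hit data.frame (see [align_pair()]); `raw_score` is
#'   `NA` for imported hits.
#' @export
import_alignment_tabular <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L)) {
    i <- which(ncols != 12L)[1]
    stop(sprintf("line %d of '%s' has %d columns (12 expected)",
                 lineno[i], path, ncols[i]))
  }
  m <- do.call(rbind, parts)
  data.frame(query = m[, 1], subject = m[, 2],
             raw_score = NA_real_,
             bitscore = as.numeric(m[, 12]),
             evalue = as.numeric(m[, 11]),
             identity_pct = as.numeric(m[, 3]),
             alignment_length = as.integer(m[, 4]),
             qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
             sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
             stringsAsFactors = FALSE)
}

#' Write alignment hits in the 12-column tabular format
#'
#' @param hits Alignment-hit data.frame.
#' @param path Output file.
#' @export
write_alignment_tabular <- function(hits, path) {
  df <- data.frame(hits$query, hits$subject,
                   sprintf("%.1f", hits$identity_pct),
                   hits$alignment_length, 0L, 0L,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   format(hits$evalue, digits = 3, scientific = TRUE),
                   sprintf("%.1f", hits$bitscore))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
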