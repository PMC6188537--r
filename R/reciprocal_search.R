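## Desk-scale exact Smith-Waterman search with Karlin-Altschul style
## e-values, and the reciprocal ("hidden ortholog") search built on it.

## Gapped Karlin-Altschul parameters at the default gap penalties for each
## matrix (BLOSUM62: open 11 / extend 1; BLOSUM45: open 14 / extend 2), as
## tabulated for gapped protein search. E = K * m * n * exp(-lambda * S).
KA_PARAMS <- list(
  BLOSUM62 = list(lambda = 0.267, K = 0.041, gap_open = 11, gap_ext = 1),
  BLOSUM45 = list(lambda = 0.224, K = 0.0744, gap_open = 14, gap_ext = 2))

.subst_matrix <- function(matrix = c("BLOSUM62", "BLOSUM45")) {
  matrix <- match.arg(matrix)
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  env[[matrix]]
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' \code{E = K * m * n * exp(-lambda * S)} with precomputed gapped
#' \code{(lambda, K)} for BLOSUM62 (gap 11/1) and BLOSUM45 (gap 14/2).
#'
#' @param score Raw alignment score.
#' @param query_len Query length (residues).
#' @param db_len Total database residue count.
#' @param matrix \code{"BLOSUM62"} or \code{"BLOSUM45"}.
#' @return E-value.
#' @export
karlin_altschul_evalue <- function(score, query_len, db_len,
                                   matrix = "BLOSUM62") {
  p <- KA_PARAMS[[matrix]]
  if (is.null(p)) stop("unknown matrix: ", matrix)
  p$K * query_len * db_len * exp(-p$lambda * score)
}

#' Local similarity search of protein queries against a database
#'
#' Exact Smith-Waterman local alignment of every query against every
#' database sequence (affine gaps at the matrix's default penalties),
#' scored with BLOSUM62 or BLOSUM45, with a Karlin-Altschul e-value
#' computed from the score, the query length and the database residue
#' count. Hits with e-value above the cutoff are removed.
#'
#' @param queries,database Lists of \code{\link{protein_sequence}} objects
#'   (or named character vectors).
#' @param matrix \code{"BLOSUM62"} (default) or \code{"BLOSUM45"}.
#' @param evalue_cutoff Keep hits with \code{evalue <= cutoff} (default 1,
#'   the precursor-search preset; \code{1e-30} is the stringent receptor
#'   preset).
#' @param score_cutoff Optional raw-score cutoff applied in addition.
#' @return Data frame with columns \code{query_id}, \code{subject_id},
#'   \code{score}, \code{evalue}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end} (0-based half-open), sorted by query then
#'   increasing e-value.
#' @export
sw_search <- function(queries, database, matrix = "BLOSUM62",
                      evalue_cutoff = 1, score_cutoff = -Inf) {
  qs <- .as_named_seqs(queries)
  db <- .as_named_seqs(database)
  stopifnot(length(qs) > 0L, length(db) > 0L)
  if (!matrix %in% names(KA_PARAMS)) stop("unknown matrix: ", matrix)
  mat <- .subst_matrix(matrix)
  p <- KA_PARAMS[[matrix]]
  db_len <- sum(nchar(db))
  ## vectorise pairwiseAlignment over the larger side to amortise call
  ## overhead; scores are symmetric, spans are swapped back as needed
  if (length(qs) >= length(db)) {
    qset <- Biostrings::AAStringSet(qs)
    rows <- vector("list", length(db))
    for (j in seq_along(db)) {
      aln <- Biostrings::pairwiseAlignment(
        qset, Biostrings::AAString(db[[j]]), type = "local",
        substitutionMatrix = mat, gapOpening = p$gap_open,
        gapExtension = p$gap_ext)
      sc <- Biostrings::score(aln)
      pr <- Biostrings::pattern(aln)
      sr <- Biostrings::subject(aln)
      rows[[j]] <- data.frame(
        query_id = names(qs), subject_id = names(db)[j], score = sc,
        evalue = karlin_altschul_evalue(sc, nchar(qs), db_len, matrix),
        q_start = IRanges::start(pr) - 1L, q_end = IRanges::end(pr),
        s_start = IRanges::start(sr) - 1L, s_end = IRanges::end(sr),
        stringsAsFactors = FALSE)
    }
  } else {
    dset <- Biostrings::AAStringSet(db)
    rows <- vector("list", length(qs))
    for (i in seq_along(qs)) {
      aln <- Biostrings::pairwiseAlignment(
        dset, Biostrings::AAString(qs[[i]]), type = "local",
        substitutionMatrix = mat, gapOpening = p$gap_open,
        gapExtension = p$gap_ext)
      sc <- Biostrings::score(aln)
      pr <- Biostrings::pattern(aln)   # spans on the db sequences
      sr <- Biostrings::subject(aln)   # spans on the query
      rows[[i]] <- data.frame(
        query_id = names(qs)[i], subject_id = names(db), score = sc,
        evalue = karlin_altschul_evalue(sc, nchar(qs[[i]]), db_len, matrix),
        q_start = IRanges::start(sr) - 1L, q_end = IRanges::end(sr),
        s_start = IRanges::start(pr) - 1L, s_end = IRanges::end(pr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$evalue <= evalue_cutoff & out$score >= score_cutoff, ,
             drop = FALSE]
  out <- out[order(out$query_id, out$evalue, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_named_seqs <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  out <- vapply(x, `[[`, "", "residues")
  names(out) <- vapply(x, `[[`, "", "id")
  out
}

#' Reciprocal similarity search for hidden orthologs
#'
#' Forward search of positive precursor hits against each target dataset;
#' each forward best hit is searched back against the positives' source
#' set. A pair is reciprocal-best when each sequence is the other's
#' top-scoring hit.
#'
#' @param pos_hits List of \code{\link{protein_sequence}} (the positives).
#' @param all_datasets Named list of datasets (each a list of
#'   \code{ProteinSequence} or named character vector).
#' @param matrix,evalue_cutoff Passed to \code{\link{sw_search}}.
#' @return Data frame with columns \code{dataset}, \code{a_id} (positive),
#'   \code{b_id} (dataset sequence), \code{forward_score},
#'   \code{forward_evalue}, \code{reverse_score}, \code{reverse_evalue},
#'   \code{reciprocal_best}.
#' @export
reciprocal_search <- function(pos_hits, all_datasets, matrix = "BLOSUM62",
                              evalue_cutoff = 1) {
  pos <- .as_named_seqs(pos_hits)
  stopifnot(length(pos) > 0L, length(all_datasets) > 0L)
  if (is.null(names(all_datasets)))
    names(all_datasets) <- paste0("dataset", seq_along(all_datasets))
  rows <- list()
  for (ds in names(all_datasets)) {
    dbseqs <- .as_named_seqs(all_datasets[[ds]])
    if (!length(dbseqs)) next
    fwd <- sw_search(pos, dbseqs, matrix, evalue_cutoff)
    if (!nrow(fwd)) next
    ## top forward hit per positive in this dataset
    top_fwd <- fwd[!duplicated(fwd$query_id), , drop = FALSE]
    rev <- sw_search(dbseqs[unique(top_fwd$subject_id)], pos, matrix,
                     evalue_cutoff)
    top_rev <- rev[!duplicated(rev$query_id), , drop = FALSE]
    for (i in seq_len(nrow(top_fwd))) {
      f <- top_fwd[i, ]
      r <- top_rev[top_rev$query_id == f$subject_id, , drop = FALSE]
      if (!nrow(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, a_id = f$query_id, b_id = f$subject_id,
        forward_score = f$score, forward_evalue = f$evalue,
        reverse_score = r$score, reverse_evalue = r$evalue,
        reciprocal_best = identical(r$subject_id, f$query_id),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(dataset = character(), a_id = character(),
                      b_id = character(), forward_score = numeric(),
                      forward_evalue = numeric(), reverse_score = numeric(),
                      reverse_evalue = numeric(),
                      reciprocal_best = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write hits in 12-column tabular format
#'
#' Mirrors the common tabular search output (query, subject, pident is
#' reported as NA since the aligner reports score-level hits, alignment
#' length from the query span, mismatch/gap columns NA, 1-based coordinates,
#' e-value, bit-like score).
#'
#' @param hits Data frame from \code{\link{sw_search}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id, pident = NA,
    length = hits$q_end - hits$q_start, mismatch = NA, gapopen = NA,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = hits$evalue, score = hits$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 12-column tabular hits (external-engine adapter)
#'
#' Parses the 12-column tabular output of an external search engine into
#' the same shape as \code{\link{sw_search}}, so large-scale runs can swap
#' engines without changing downstream code.
#'
#' @param path TSV path (no header, 12 columns).
#' @return Data frame with \code{sw_search} columns.
#' @export
read_hits_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 12L)
  data.frame(query_id = as.character(tab[[1L]]),
             subject_id = as.character(tab[[2L]]),
             score = as.numeric(tab[[12L]]), evalue = as.numeric(tab[[11L]]),
             q_start = as.integer(tab[[7L]]) - 1L,
             q_end = as.integer(tab[[8L]]),
             s_start = as.integer(tab[[9L]]) - 1L,
             s_end = as.integer(tab[[10L]]),
             stringsAsFactors = FALSE)
}
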