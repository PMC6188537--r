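#' @import methods
#' @importFrom Biostrings readBStringSet DNAString DNAStringSet AAStringSet
#'   translate reverseComplement writeXStringSet subseq
NULL

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                      "R","S","T","V","W","Y")

#' Construct a protein sequence record
#'
#' A \code{ProteinSequence} carries a translated (or directly supplied)
#' amino-acid sequence together with its provenance: the source transcript,
#' the reading frame, and whether its 5' end is complete. Completeness gates
#' whether a signal peptide can be called at all downstream.
#'
#' @param id Unique sequence identifier.
#' @param residues Amino-acid string over the 20 standard residues plus
#'   \code{X}; stop symbols are not allowed.
#' @param source_id Originating transcript id, or \code{"direct"} for protein
#'   input.
#' @param frame Reading frame in \code{-3:-1, 1:3}, or \code{NA} for direct
#'   protein input.
#' @param five_prime_complete Logical; \code{TRUE} when the segment's start
#'   is known to be the true N-terminus (in-frame upstream stop codon, or
#'   direct protein input).
#' @return An object of class \code{ProteinSequence}.
#' @export
protein_sequence <- function(id, residues, source_id = "direct",
                             frame = NA_integer_,
                             five_prime_complete = TRUE) {
  stopifnot(is.character(id), nzchar(id), is.character(residues),
            nchar(residues) >= 1L)
  residues <- toupper(residues)
  if (grepl("\\*", residues))
    stop("residues must not contain a stop symbol: ", id)
  bad <- regmatches(residues, regexpr("[^A-Z]", residues))
  if (length(bad)) stop("non-residue character '", bad, "' in ", id)
  if (is.na(frame) && !identical(source_id, "direct") && source_id != "direct")
    stop("frame must be set for translated sequences")
  structure(list(id = id, residues = residues, source_id = source_id,
                 frame = as.integer(frame),
                 five_prime_complete = isTRUE(five_prime_complete)),
            class = "ProteinSequence")
}

#' @export
print.ProteinSequence <- function(x, ...) {
  cat(sprintf("ProteinSequence %s (%d aa, source=%s, frame=%s, 5'%s)\n",
              x$id, nchar(x$residues), x$source_id,
              ifelse(is.na(x$frame), "-", sprintf("%+d", x$frame)),
              if (x$five_prime_complete) "complete" else "partial"))
  invisible(x)
}

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file into a list of transcript or protein
#' records. Sequences are uppercased; for nucleotide input \code{U} is
#' mapped to \code{T}. Record ids are the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"nucleotide"} or \code{"protein"}.
#' @return For \code{alphabet = "nucleotide"}, a list of records with fields
#'   \code{id}, \code{sequence}, \code{description}; for \code{"protein"}, a
#'   list of \code{\link{protein_sequence}} objects.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(set))
  if (alphabet == "nucleotide") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop("non-nucleotide character in ", ids[i], " at position ", bad[i])
    }
    recs <- Map(function(i, s, d)
      structure(list(id = i, sequence = s, description = d),
                class = "TranscriptRecord"),
      ids, seqs, desc)
  } else {
    ok <- paste0(c(PROTEIN_ALPHABET, "X"), collapse = "")
    bad <- regexpr(sprintf("[^%s]", ok), seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop("non-residue character in ", ids[i], " at position ", bad[i])
    }
    recs <- Map(function(i, s) protein_sequence(i, s), ids, seqs)
  }
  names(recs) <- ids
  unname(recs)
}

#' Write sequences to FASTA
#'
#' Writes transcript records or protein sequences as multi-record FASTA,
#' wrapped at 60 columns.
#'
#' @param records List of \code{TranscriptRecord} or \code{ProteinSequence}
#'   objects, or a named character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    ids <- names(records)
    seqs <- unname(records)
  } else {
    ids <- vapply(records, `[[`, "", "id")
    seqs <- vapply(records, function(r)
      if (!is.null(r$residues)) r$residues else r$sequence, "")
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## Translate one frame of a nucleotide string; returns the aa string with
## '*' at stops. frame in 1:3 on the given strand.
.translate_frame <- function(nt, frame) {
  n <- nchar(nt)
  start <- frame
  len <- (n - start + 1L) %/% 3L * 3L
  if (len < 3L) return("")
  codons <- substr(nt, start, start + len - 1L)
  aa <- Biostrings::translate(Biostrings::DNAString(codons),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

#' Six-frame translation with stop-codon segmentation
#'
#' Translates a transcript in all six reading frames with the standard
#' genetic code, splits each translation at stop codons, and returns the
#' resulting segments as \code{\link{protein_sequence}} objects. A segment
#' preceded in-frame by a stop codon has a known 5' boundary: it is trimmed
#' to its first Met and flagged \code{five_prime_complete = TRUE}. A segment
#' abutting the transcript edge may be missing its true start and is kept
#' untrimmed with \code{five_prime_complete = FALSE}. Codons containing
#' \code{N} translate to \code{X}.
#'
#' @param record A \code{TranscriptRecord} (list with \code{id},
#'   \code{sequence}) from \code{\link{read_fasta}}.
#' @param min_len Minimum segment length in amino acids (default 20);
#'   shorter segments are dropped.
#' @param table Genetic code id; only the standard code (1) is supported.
#' @return List of \code{ProteinSequence} segments (possibly empty). Ids are
#'   \code{<transcript>_f<frame>_<k>}.
#' @export
six_frame_translate <- function(record, min_len = 20L, table = 1L) {
  if (!identical(as.integer(table), 1L))
    stop("only the standard genetic code (table 1) is supported")
  nt <- toupper(record$sequence)
  if (nchar(nt) < 3L) {
    warning("transcript ", record$id, " shorter than one codon; skipped")
    return(list())
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  out <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- .translate_frame(if (fr > 0L) nt else rc, abs(fr))
    if (!nzchar(aa)) next
    ## split at stops, keeping track of whether a stop precedes each segment
    parts <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    k <- 0L
    for (j in seq_along(parts)) {
      seg <- parts[j]
      if (!nzchar(seg)) next
      complete <- j > 1L  # an in-frame stop precedes this segment
      if (complete) {
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0L) next            # no ORF start within a bounded segment
        seg <- substr(seg, m, nchar(seg))
      }
      if (nchar(seg) < min_len) next
      k <- k + 1L
      out[[length(out) + 1L]] <- protein_sequence(
        id = sprintf("%s_f%+d_%d", record$id, fr, k),
        residues = seg, source_id = record$id, frame = fr,
        five_prime_complete = complete)
    }
  }
  out
}

#' Translate every record of a nucleotide FASTA file
#'
#' Convenience wrapper applying \code{\link{six_frame_translate}} to every
#' transcript of a file.
#'
#' @inheritParams six_frame_translate
#' @param path Nucleotide FASTA path.
#' @return Flat list of \code{ProteinSequence} segments.
#' @export
translate_fasta <- function(path, min_len = 20L, table = 1L) {
  recs <- read_fasta(path, "nucleotide")
  out <- lapply(recs, six_frame_translate, min_len = min_len, table = table)
  unlist(out, recursive = FALSE, use.names = FALSE)
}
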