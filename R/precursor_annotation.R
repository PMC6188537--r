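## Prohormone processing model: signal-peptide gate, dibasic/monobasic
## convertase cleavage, peptide excision, C-terminal amidation via the
## glycine donor.

HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")
SMALL_RES <- c("A", "G", "S", "C", "T")
BASIC <- c("K", "R")

#' Built-in signal-peptide heuristic
#'
#' Dependency-free stand-in for an external signal-peptide predictor, used
#' when no external prediction table is supplied (primarily on synthetic
#' data). A sequence is called positive iff residue 0 is Met, positions
#' 1--30 contain a run of at least 6 consecutive hydrophobic residues
#' (A,I,L,M,F,V,W,C), and a small residue (A,G,S,C,T) follows that run; the
#' predicted mature chain starts immediately after the first such small
#' residue. The score is the hydrophobic run length / 10, capped at 1.
#'
#' @param residues Residue string.
#' @return List with \code{has_signal}, \code{cleavage_pos} (0-based mature
#'   start, or \code{NA}), \code{score}.
#' @keywords internal
signal_heuristic <- function(residues) {
  neg <- list(has_signal = FALSE, cleavage_pos = NA_integer_, score = 0)
  if (substr(residues, 1L, 1L) != "M") return(neg)
  window <- strsplit(substr(residues, 2L, 31L), "")[[1L]]
  r <- rle(window %in% HYDROPHOBIC)
  runs <- which(r$values & r$lengths >= 6L)
  if (!length(runs)) return(neg)
  ## 0-based end (exclusive) of the first qualifying run, in full-sequence
  ## coordinates (window starts at residue 1)
  first <- runs[1L]
  run_len <- r$lengths[first]
  run_end <- 1L + sum(r$lengths[seq_len(first)])
  chars <- strsplit(residues, "")[[1L]]
  small <- which(chars %in% SMALL_RES)
  small <- small[small - 1L >= run_end]   # 0-based pos >= run_end
  if (!length(small)) return(neg)
  cleave <- small[1L]                     # 1-based small residue = last of signal
  if (cleave >= nchar(residues)) return(neg)  # mature chain must be non-empty
  list(has_signal = TRUE, cleavage_pos = cleave,
       score = min(run_len / 10, 1))
}

#' Call a signal peptide
#'
#' Gates secreted-protein candidacy. If an external prediction table
#' contains a row for the sequence id, its score is compared against
#' \code{threshold} (default 0.34, the D-cutoff used for precursor
#' screening). Otherwise the built-in heuristic is applied. Sequences whose
#' 5' end is incomplete cannot be tested and are returned with method
#' \code{"untestable_partial"} and \code{has_signal = NA}.
#'
#' @param protein A \code{\link{protein_sequence}}.
#' @param external Optional data frame with columns \code{id}, \code{score},
#'   \code{cleavage_pos} (0-based mature-chain start), e.g. read from a
#'   predictor's short-format output.
#' @param threshold Score cutoff (default 0.34).
#' @return List of class \code{SignalPeptideCall}: \code{has_signal}
#'   (logical, \code{NA} when untestable), \code{cleavage_pos},
#'   \code{score}, \code{method}.
#' @export
call_signal_peptide <- function(protein, external = NULL, threshold = 0.34) {
  stopifnot(inherits(protein, "ProteinSequence"))
  ext_row <- NULL
  if (!is.null(external)) {
    stopifnot(all(c("id", "score", "cleavage_pos") %in% names(external)))
    hit <- which(external$id == protein$id)
    if (length(hit) > 1L) stop("duplicate external rows for id ", protein$id)
    if (length(hit) == 1L) ext_row <- external[hit, ]
  }
  if (!is.null(ext_row)) {
    score <- suppressWarnings(as.numeric(ext_row$score))
    if (is.na(score)) stop("malformed external score for id ", protein$id)
    has <- score >= threshold
    cp <- if (has) as.integer(ext_row$cleavage_pos) else NA_integer_
    if (has && (is.na(cp) || cp < 1L || cp >= nchar(protein$residues)))
      stop("malformed external cleavage_pos for id ", protein$id)
    call <- list(has_signal = has, cleavage_pos = cp, score = score,
                 method = "external_table")
  } else if (!protein$five_prime_complete) {
    call <- list(has_signal = NA, cleavage_pos = NA_integer_,
                 score = NA_real_, method = "untestable_partial")
  } else {
    h <- signal_heuristic(protein$residues)
    call <- list(has_signal = h$has_signal && h$score >= threshold,
                 cleavage_pos = if (h$has_signal) h$cleavage_pos else NA_integer_,
                 score = h$score, method = "builtin_heuristic")
  }
  structure(call, class = "SignalPeptideCall")
}

#' Find prohormone-convertase cleavage sites
#'
#' Dibasic sites: every occurrence of KK, KR, RK or RR downstream of the
#' signal cleavage point, resolved left-to-right non-overlapping (in a
#' basic run such as KRR the leftmost pair wins and scanning resumes after
#' it). Monobasic sites: by default a single R in an F-G-R context (the
#' RFamide monobasic convention), i.e. R at position p with F at p-2 and G
#' at p-1, not overlapping any dibasic site.
#'
#' @param protein A \code{\link{protein_sequence}} or residue string.
#' @param mature_start 0-based start of the mature chain (signal cleavage
#'   point); sites are only called at or after it. Default 0.
#' @param monobasic One of \code{"fgr"} (default: the F-G-R context rule),
#'   \code{"none"}, or a function \code{f(chars, pos0)} returning TRUE when
#'   a lone basic residue at 0-based \code{pos0} is a cleavage site.
#' @return Data frame with columns \code{pos} (0-based first residue of the
#'   site), \code{kind} ("dibasic"/"monobasic"), \code{residues}.
#' @export
find_cleavage_sites <- function(protein, mature_start = 0L,
                                monobasic = "fgr") {
  s <- if (inherits(protein, "ProteinSequence")) protein$residues
       else toupper(as.character(protein))
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  pos <- integer(); kind <- character(); res <- character()
  i <- mature_start + 1L                     # 1-based scan index
  while (i <= n - 1L) {
    if (chars[i] %in% BASIC && chars[i + 1L] %in% BASIC) {
      pos <- c(pos, i - 1L); kind <- c(kind, "dibasic")
      res <- c(res, paste0(chars[i], chars[i + 1L]))
      i <- i + 2L
    } else i <- i + 1L
  }
  if (!identical(monobasic, "none")) {
    test <- if (is.function(monobasic)) monobasic
            else if (identical(monobasic, "fgr"))
              function(ch, p0) p0 >= 2L && ch[p0 + 1L] == "R" &&
                ch[p0 - 1L] == "F" && ch[p0] == "G"
            else stop("unknown monobasic rule: ", monobasic)
    dib_cov <- unlist(lapply(pos[kind == "dibasic"], function(p) c(p, p + 1L)))
    for (p0 in seq.int(mature_start, n - 1L)) {
      if (!chars[p0 + 1L] %in% BASIC) next
      if (p0 %in% dib_cov) next
      if (isTRUE(test(chars, p0))) {
        pos <- c(pos, p0); kind <- c(kind, "monobasic")
        res <- c(res, chars[p0 + 1L])
      }
    }
  }
  o <- order(pos)
  data.frame(pos = pos[o], kind = kind[o], residues = res[o],
             stringsAsFactors = FALSE)
}

#' Excise predicted peptides between cleavage sites
#'
#' Segments between the signal cleavage point (or the sequence start) and
#' the sequence end, interleaved with cleavage sites, become predicted
#' peptides. Site residues are excluded from peptides. A segment ending in
#' Gly donates its G: the peptide is amidated and loses the terminal G. A
#' segment starting with Gln is flagged as a pyroglutamation candidate
#' (annotation only). Empty segments, and segments consisting of a lone
#' donor G, are skipped.
#'
#' @param protein A \code{\link{protein_sequence}}.
#' @param signal A \code{SignalPeptideCall}; the mature chain starts at its
#'   \code{cleavage_pos} when \code{has_signal} is TRUE, else at 0.
#' @param sites Data frame from \code{\link{find_cleavage_sites}}.
#' @return Data frame with one row per peptide: \code{parent_id},
#'   \code{start}, \code{end} (0-based half-open pre-processing span, G
#'   donor included), \code{sequence} (mature, G excluded), \code{amidated},
#'   \code{n_term_pyroglu}, \code{flank_left}, \code{flank_right}.
#' @export
extract_peptides <- function(protein, signal, sites) {
  s <- protein$residues
  n <- nchar(s)
  mstart <- if (isTRUE(signal$has_signal)) signal$cleavage_pos else 0L
  bounds_start <- c(mstart, sites$pos + nchar(sites$residues))
  bounds_end <- c(sites$pos, n)
  flank_l <- c(if (mstart > 0L) "signal" else "", sites$residues)
  flank_r <- c(sites$residues, "")
  rows <- list()
  for (i in seq_along(bounds_start)) {
    a <- bounds_start[i]; b <- bounds_end[i]
    if (b <= a) next
    seg <- substr(s, a + 1L, b)
    amid <- substr(seg, nchar(seg), nchar(seg)) == "G"
    mature <- if (amid) substr(seg, 1L, nchar(seg) - 1L) else seg
    if (!nzchar(mature)) {
      warning("degenerate lone-G segment at ", a, " in ", protein$id,
              "; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = protein$id, start = a, end = b, sequence = mature,
      amidated = amid,
      n_term_pyroglu = substr(mature, 1L, 1L) == "Q",
      flank_left = flank_l[i], flank_right = flank_r[i],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      amidated = logical(), n_term_pyroglu = logical(),
                      flank_left = character(), flank_right = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Annotate a candidate preproneuropeptide
#'
#' Full processing model: signal-peptide call, cleavage-site prediction on
#' the mature chain, peptide excision with amidation inference. The tiling
#' invariant (signal peptide + peptide pre-processing spans + site residues
#' reconstruct the protein exactly) is verified before returning.
#'
#' @param protein A \code{\link{protein_sequence}}.
#' @param external Optional external signal-prediction table (see
#'   \code{\link{call_signal_peptide}}).
#' @param threshold Signal score cutoff (default 0.34).
#' @param monobasic Monobasic rule (see \code{\link{find_cleavage_sites}}).
#' @return Object of class \code{PrecursorAnnotation}: list with
#'   \code{protein}, \code{signal}, \code{sites}, \code{peptides}.
#' @export
annotate_precursor <- function(protein, external = NULL, threshold = 0.34,
                               monobasic = "fgr") {
  signal <- call_signal_peptide(protein, external, threshold)
  mstart <- if (isTRUE(signal$has_signal)) signal$cleavage_pos else 0L
  sites <- find_cleavage_sites(protein, mature_start = mstart,
                               monobasic = monobasic)
  peptides <- suppressWarnings(extract_peptides(protein, signal, sites))
  ann <- structure(list(protein = protein, signal = signal, sites = sites,
                        peptides = peptides),
                   class = "PrecursorAnnotation")
  stopifnot(check_tiling(ann))
  ann
}

#' Verify the precursor tiling invariant
#'
#' Reconstructs the protein from signal peptide, peptide pre-processing
#' spans and cleavage-site residues, allowing for skipped degenerate
#' segments, and compares residue-by-residue.
#'
#' @param ann A \code{PrecursorAnnotation}.
#' @return TRUE iff every annotated span reproduces the protein residues
#'   and spans are non-overlapping and ordered.
#' @export
check_tiling <- function(ann) {
  s <- ann$protein$residues
  mstart <- if (isTRUE(ann$signal$has_signal)) ann$signal$cleavage_pos else 0L
  spans <- rbind(
    if (mstart > 0L) data.frame(start = 0L, end = mstart, what = "signal"),
    if (nrow(ann$sites))
      data.frame(start = ann$sites$pos,
                 end = ann$sites$pos + nchar(ann$sites$residues),
                 what = "site"),
    if (nrow(ann$peptides))
      data.frame(start = ann$peptides$start, end = ann$peptides$end,
                 what = "peptide"))
  if (is.null(spans) || !nrow(spans)) return(nchar(s) == 0L)
  spans <- spans[order(spans$start), ]
  if (any(spans$start[-1L] < spans$end[-nrow(spans)])) return(FALSE)
  ## peptide spans must reproduce sequences (+ donor G where amidated)
  for (i in seq_len(nrow(ann$peptides))) {
    p <- ann$peptides[i, ]
    seg <- substr(s, p$start + 1L, p$end)
    want <- if (p$amidated) paste0(p$sequence, "G") else p$sequence
    if (seg != want) return(FALSE)
    if (p$amidated && substr(seg, nchar(seg), nchar(seg)) != "G")
      return(FALSE)
  }
  ## coverage: gaps are only allowed where degenerate segments were skipped
  covered <- logical(nchar(s))
  for (i in seq_len(nrow(spans)))
    if (spans$end[i] > spans$start[i])
      covered[(spans$start[i] + 1L):spans$end[i]] <- TRUE
  gaps <- which(!covered)
  if (length(gaps)) {
    ## every uncovered residue must be a skipped lone-G or empty segment
    if (!all(strsplit(s, "")[[1L]][gaps] == "G")) return(FALSE)
  }
  TRUE
}

#' @export
print.PrecursorAnnotation <- function(x, ...) {
  cat(sprintf("PrecursorAnnotation %s: signal=%s, %d cleavage sites, %d peptides\n",
              x$protein$id,
              if (is.na(x$signal$has_signal)) "untestable"
              else if (x$signal$has_signal)
                sprintf("yes@%d", x$signal$cleavage_pos) else "no",
              nrow(x$sites), nrow(x$peptides)))
  if (nrow(x$peptides)) {
    amid <- ifelse(x$peptides$amidated, "-NH2", "")
    cat(paste0("  ", x$peptides$sequence, amid, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read an external signal-peptide prediction table
#'
#' TSV with columns \code{id}, \code{score}, \code{cleavage_pos} (0-based
#' mature-chain start), compatible with the short-format output of common
#' predictors after column mapping.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_signal_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "score", "cleavage_pos") %in% names(df)))
  df
}
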