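## Paracopy grouping and multicopy-peptide (MCP) family calling.
##
## "Recurrent peptide sequences between the cleavage sites" are formalized
## as single-linkage clusters under a normalized global-alignment
## similarity; clusters with >= min_copies members make a precursor an MCP
## candidate, and groups are merged across sequences/datasets into families
## named by their consensus motif (e.g. "SFxNa", with `x` marking variable
## positions and a trailing `a` for uniformly amidated families).

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

.self_score <- function(seq, mat) {
  ch <- strsplit(seq, "")[[1L]]
  sum(mat[cbind(ch, ch)])
}

#' Normalized pairwise peptide similarity
#'
#' Global (Needleman-Wunsch) alignment score with BLOSUM62, gap open 10 /
#' extend 1, normalized by the self-alignment score of the shorter peptide.
#' Identical peptides score 1; unrelated peptides score near or below 0.
#'
#' @param a,b Peptide strings.
#' @return Numeric similarity (at most 1 for substitution-only alignments).
#' @export
peptide_similarity <- function(a, b) {
  mat <- .blosum62()
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
    scoreOnly = TRUE)
  shorter <- if (nchar(a) <= nchar(b)) a else b
  denom <- .self_score(shorter, mat)
  if (denom <= 0) return(ifelse(a == b, 1, 0))
  sc / denom
}

## Pairwise similarity matrix for a character vector of peptides.
.sim_matrix <- function(seqs) {
  n <- length(seqs)
  mat <- .blosum62()
  sims <- diag(1, n)
  if (n < 2L) return(sims)
  selfs <- vapply(seqs, .self_score, 0, mat = mat)
  aa <- Biostrings::AAStringSet(seqs)
  for (j in 2:n) {
    sc <- Biostrings::pairwiseAlignment(
      aa[seq_len(j - 1L)], Biostrings::AAString(seqs[j]), type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    denom <- pmin(selfs[seq_len(j - 1L)],
                  rep(selfs[j], j - 1L))
    v <- ifelse(denom > 0, sc / denom, as.numeric(seqs[seq_len(j - 1L)] == seqs[j]))
    sims[j, seq_len(j - 1L)] <- sims[seq_len(j - 1L), j] <- v
  }
  sims
}

## Connected components of sim >= threshold (single linkage).
.linkage_components <- function(sims, threshold) {
  n <- nrow(sims)
  parent <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || sims[i, j] < threshold) next
      ri <- i; while (parent[ri] != ri) ri <- parent[ri]
      rj <- j; while (parent[rj] != rj) rj <- parent[rj]
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, 0L)
  match(roots, unique(roots))
}

## Pad sequences to equal length with "-", anchored left or right.
.pad_align <- function(seqs, anchor = c("left", "right")) {
  anchor <- match.arg(anchor)
  w <- max(nchar(seqs))
  vapply(seqs, function(s) {
    pad <- strrep("-", w - nchar(s))
    if (anchor == "right") paste0(pad, s) else paste0(s, pad)
  }, "", USE.NAMES = FALSE)
}

## Position-frequency matrix of an equal-length alignment; rows are the 20
## residues plus X and the pad symbol, columns positions.
.pfm <- function(alignment) {
  chars <- strsplit(alignment, "")
  w <- nchar(alignment[1L])
  syms <- c(PROTEIN_ALPHABET, "X", "-")
  m <- matrix(0L, nrow = length(syms), ncol = w,
              dimnames = list(syms, NULL))
  for (ch in chars) {
    idx <- cbind(match(ch, syms), seq_len(w))
    m[idx] <- m[idx] + 1L
  }
  m
}

.consensus_from_pfm <- function(pfm, n_members, conservation_min = 0.5) {
  cons <- vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[, j]
    if (col["-"] == n_members) return("-")        # all-pad column
    col <- col[names(col) != "-"]
    top <- which.max(col)
    if (col[top] / n_members >= conservation_min) names(col)[top] else "x"
  }, "")
  paste(cons, collapse = "")
}

.mean_conservation <- function(pfm, n_members) {
  vals <- vapply(seq_len(ncol(pfm)), function(j) {
    col <- pfm[rownames(pfm) != "-", j]
    max(col) / n_members
  }, 0)
  mean(vals)
}

.build_group <- function(parent_id, members, conservation_min = 0.5) {
  amid <- members$amidated
  profile <- if (all(amid)) "all" else if (!any(amid)) "none" else "mixed"
  ## anchoring: right for uniformly amidated C-terminal motifs, else the
  ## anchor that maximizes mean column conservation
  n <- nrow(members)
  if (profile == "all") {
    anchor <- "right"
  } else {
    cl <- .mean_conservation(.pfm(.pad_align(members$sequence, "left")), n)
    cr <- .mean_conservation(.pfm(.pad_align(members$sequence, "right")), n)
    anchor <- if (cr > cl) "right" else "left"
  }
  alignment <- .pad_align(members$sequence, anchor)
  pfm <- .pfm(alignment)
  consensus <- .consensus_from_pfm(pfm, n, conservation_min)
  consensus <- gsub("^-+|-+$", "", consensus)     # trim all-pad end columns
  structure(list(parent_id = parent_id, members = members,
                 alignment = alignment, anchor = anchor, pfm = pfm,
                 consensus = consensus, amidation_profile = profile),
            class = "ParacopyGroup")
}

#' Group peptide paracopies within a precursor
#'
#' Single-linkage clustering of a precursor's predicted peptides under the
#' normalized alignment similarity of \code{\link{peptide_similarity}}.
#' Clusters with at least \code{min_copies} members are returned as
#' paracopy groups with padded alignment, position-frequency matrix and
#' consensus motif. Uniformly amidated groups are aligned right-anchored
#' (C-terminal motifs); otherwise the anchor maximizing mean column
#' conservation is used.
#'
#' @param peptides Data frame from \code{\link{extract_peptides}} (one
#'   parent only).
#' @param min_copies Minimum cluster size to call a group (default 2).
#' @param threshold Linkage similarity threshold (default 0.5).
#' @param conservation_min Consensus conservation threshold (default 0.5).
#' @return List of \code{ParacopyGroup} objects, largest first.
#' @export
group_paracopies <- function(peptides, min_copies = 2L, threshold = 0.5,
                             conservation_min = 0.5) {
  if (!nrow(peptides)) return(list())
  stopifnot(length(unique(peptides$parent_id)) == 1L)
  ## canonical order for clustering determinism
  peptides <- peptides[order(peptides$sequence, peptides$start), ,
                       drop = FALSE]
  comp <- .linkage_components(.sim_matrix(peptides$sequence), threshold)
  groups <- list()
  for (k in unique(comp)) {
    members <- peptides[comp == k, , drop = FALSE]
    if (nrow(members) < min_copies) next
    members <- members[order(members$start), , drop = FALSE]
    groups[[length(groups) + 1L]] <-
      .build_group(peptides$parent_id[1L], members, conservation_min)
  }
  sizes <- vapply(groups, function(g) nrow(g$members), 0L)
  cons <- vapply(groups, `[[`, "", "consensus")
  groups[order(-sizes, cons)]
}

#' Consensus motif of a paracopy group
#'
#' Per alignment column, the modal residue if its frequency among members
#' reaches \code{conservation_min}, else \code{x}; all-pad columns are
#' trimmed from the ends.
#'
#' @param group A \code{ParacopyGroup}.
#' @param conservation_min Conservation threshold (default 0.5).
#' @return Consensus string.
#' @export
consensus_motif <- function(group, conservation_min = 0.5) {
  cons <- .consensus_from_pfm(group$pfm, nrow(group$members),
                              conservation_min)
  gsub("^-+|-+$", "", cons)
}

#' Group/family display name
#'
#' The consensus motif with a trailing \code{"a"} when every member is
#' amidated (the field's "-amide" naming convention).
#'
#' @param consensus Consensus string.
#' @param amidation_profile \code{"all"}, \code{"none"} or \code{"mixed"}.
#' @return Name string.
#' @export
motif_name <- function(consensus, amidation_profile) {
  if (identical(amidation_profile, "all")) paste0(consensus, "a")
  else consensus
}

#' @export
print.ParacopyGroup <- function(x, ...) {
  cat(sprintf("ParacopyGroup %s: %d copies, consensus %s (%s amidated)\n",
              x$parent_id, nrow(x$members),
              motif_name(x$consensus, x$amidation_profile),
              x$amidation_profile))
  invisible(x)
}

## Similarity of two consensus motifs; `x` positions are aligned as the
## ambiguity residue X of BLOSUM62.
.consensus_similarity <- function(a, b) {
  peptide_similarity(gsub("x", "X", a, fixed = TRUE),
                     gsub("x", "X", b, fixed = TRUE))
}

#' Merge paracopy groups into MCP families
#'
#' Single-linkage merge over group-consensus similarity across sequences
#' and datasets. Family consensus and amidation are recomputed from the
#' pooled member peptides; families are named consensus + \code{"a"} when
#' uniformly amidated, and ordered by (size desc, name).
#'
#' @param groups List of \code{ParacopyGroup}; each may carry a
#'   \code{dataset} attribute (set by the pipeline).
#' @param threshold Consensus similarity threshold (default 0.5).
#' @param conservation_min Consensus conservation threshold (default 0.5).
#' @return List of \code{MCPFamily} objects: \code{name},
#'   \code{family_consensus}, \code{amidated}, \code{groups},
#'   \code{n_peptides}, \code{datasets}.
#' @export
merge_families <- function(groups, threshold = 0.5, conservation_min = 0.5) {
  if (!length(groups)) return(list())
  ## canonical order for determinism
  key <- vapply(groups, function(g) paste(g$consensus, g$parent_id), "")
  groups <- groups[order(key)]
  cons <- vapply(groups, `[[`, "", "consensus")
  n <- length(groups)
  sims <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      sims[i, j] <- sims[j, i] <- .consensus_similarity(cons[i], cons[j])
  }
  comp <- .linkage_components(sims, threshold)
  fams <- lapply(unique(comp), function(k) {
    g <- groups[comp == k]
    members <- do.call(rbind, lapply(g, `[[`, "members"))
    amid <- members$amidated
    profile <- if (all(amid)) "all" else if (!any(amid)) "none" else "mixed"
    anchor <- if (profile == "all") "right" else {
      cl <- .mean_conservation(.pfm(.pad_align(members$sequence, "left")),
                               nrow(members))
      cr <- .mean_conservation(.pfm(.pad_align(members$sequence, "right")),
                               nrow(members))
      if (cr > cl) "right" else "left"
    }
    pfm <- .pfm(.pad_align(members$sequence, anchor))
    fc <- gsub("^-+|-+$", "",
               .consensus_from_pfm(pfm, nrow(members), conservation_min))
    datasets <- sort(unique(unlist(lapply(g, function(x)
      attr(x, "dataset") %||% NA_character_))))
    datasets <- datasets[!is.na(datasets)]
    structure(list(name = motif_name(fc, profile), family_consensus = fc,
                   amidated = profile, groups = g, pfm = pfm,
                   n_peptides = nrow(members), datasets = datasets),
              class = "MCPFamily")
  })
  sizes <- vapply(fams, `[[`, 0L, "n_peptides")
  nms <- vapply(fams, `[[`, "", "name")
  fams[order(-sizes, nms)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MCPFamily <- function(x, ...) {
  cat(sprintf("MCPFamily %s: %d groups, %d peptides, datasets [%s], %s amidated\n",
              x$name, length(x$groups), x$n_peptides,
              paste(x$datasets, collapse = ","), x$amidated))
  invisible(x)
}

#' Export a family's position-frequency matrix
#'
#' Writes the PFM as a TSV matrix (rows residues, columns positions)
#' suitable for standard sequence-logo tools.
#'
#' @param family An \code{MCPFamily} or \code{ParacopyGroup}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_pfm <- function(family, path) {
  utils::write.table(family$pfm, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
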