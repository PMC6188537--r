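## Theoretical monoisotopic peptide masses under the fixed/variable
## modification set, and ppm-window matching against observed masses.

#' Monoisotopic residue masses (Da)
#'
#' Standard monoisotopic masses of the 20 amino-acid residues (i.e. amino
#' acids minus water, as polymerized in a peptide chain).
#'
#' @format Named numeric vector.
#' @export
RESIDUE_MONO_MASS <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048458, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294)

WATER_MONO <- 18.0105646863
PROTON_MONO <- 1.007276466812

#' Modification constants
#'
#' The modification set used for precursor-mass validation: fixed
#' carbamidomethylation of Cys; variable oxidation of Met, acetylation of
#' the peptide N-terminus, amidation of the peptide C-terminus, sulfation
#' of Tyr. Deltas are monoisotopic (Da).
#'
#' @return Data frame with columns \code{name}, \code{delta}, \code{site},
#'   \code{fixed}.
#' @export
modification_set <- function() {
  data.frame(
    name = c("carbamidomethyl", "oxidation", "acetyl", "amide", "sulfo"),
    delta = c(57.02146, 15.99491, 42.01057, -0.98402, 79.95682),
    site = c("C_residue", "M_residue", "peptide_N_term", "peptide_C_term",
             "Y_residue"),
    fixed = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' deltas. Nonstandard residues (X, B, Z, ...) make a peptide unmatchable
#' and raise an error.
#'
#' @param sequence Residue string over the 20 standard amino acids.
#' @param deltas Numeric vector of modification mass shifts to add
#'   (default none).
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, deltas = numeric()) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(ch, names(RESIDUE_MONO_MASS))
  if (length(bad))
    stop("nonstandard residue '", bad[1L], "' in peptide ", sequence)
  sum(RESIDUE_MONO_MASS[ch]) + WATER_MONO + sum(deltas)
}

#' Convert m/z and charge to neutral monoisotopic mass
#'
#' \code{M = m/z * z - z * m_proton} for positive-mode ions.
#'
#' @param mz Observed m/z.
#' @param charge Charge state (positive integer).
#' @return Neutral mass in Da.
#' @export
mz_to_neutral <- function(mz, charge) {
  stopifnot(all(charge >= 1L))
  mz * charge - charge * PROTON_MONO
}

#' Enumerate modified forms of a predicted peptide
#'
#' Applies fixed modifications at every eligible site and enumerates
#' variable-modification combinations up to \code{max_variable} per
#' peptide. C-terminal amidation is forced on (not variable) when the
#' precursor model flagged the peptide as amidated (glycine donor present).
#' Peptides shorter than \code{min_length} are excluded.
#'
#' @param peptide One row of an \code{\link{extract_peptides}} data frame,
#'   or a list with \code{sequence}, \code{amidated} and optionally
#'   \code{protein_n_term} (TRUE for the mature protein's N-terminal
#'   peptide, enabling N-terminal acetylation).
#' @param mods Modification table (default \code{\link{modification_set}}).
#' @param max_variable Maximum simultaneous variable modifications
#'   (default 3).
#' @param min_length Minimum peptide length (default 4).
#' @return Data frame with one row per form: \code{sequence},
#'   \code{amidated}, \code{mods} (comma-separated \code{name@pos} with
#'   0-based residue positions, \code{@N}/\code{@C} for termini),
#'   \code{mass}.
#' @export
enumerate_modified_forms <- function(peptide, mods = modification_set(),
                                     max_variable = 3L, min_length = 4L) {
  seqs <- peptide$sequence
  stopifnot(length(seqs) == 1L)
  if (nchar(seqs) < min_length)
    return(data.frame(sequence = character(), amidated = logical(),
                      mods = character(), mass = numeric(),
                      stringsAsFactors = FALSE))
  ch <- strsplit(seqs, "")[[1L]]
  ## N-terminal acetylation is only eligible on the mature protein's
  ## N-terminal peptide, per the usual database-search convention
  sites_of <- function(m) switch(m$site,
    C_residue = which(ch == "C") - 1L,
    M_residue = which(ch == "M") - 1L,
    Y_residue = which(ch == "Y") - 1L,
    peptide_N_term = if (isTRUE(peptide$protein_n_term)) "N"
                     else character(0),
    peptide_C_term = "C",
    stop("unknown site: ", m$site))
  base_deltas <- 0
  base_labels <- character()
  occupied_cterm <- FALSE
  var_sites <- list()
  for (i in seq_len(nrow(mods))) {
    m <- as.list(mods[i, ])
    pos <- sites_of(m)
    if (!length(pos)) next
    if (m$name == "amide") {
      if (isTRUE(peptide$amidated)) {
        if (occupied_cterm) stop("C-terminal site already occupied")
        base_deltas <- base_deltas + m$delta
        base_labels <- c(base_labels, "amide@C")
        occupied_cterm <- TRUE
      }
      next  # never enumerated as variable: driven by the precursor model
    }
    if (m$fixed) {
      base_deltas <- base_deltas + m$delta * length(pos)
      base_labels <- c(base_labels, paste0(m$name, "@", pos))
    } else {
      for (p in pos)
        var_sites[[length(var_sites) + 1L]] <-
          list(label = paste0(m$name, "@", p), delta = m$delta,
               terminus = if (identical(p, "C")) "C" else NA)
    }
  }
  nv <- length(var_sites)
  forms <- list()
  add_form <- function(idx) {
    deltas <- base_deltas + sum(vapply(var_sites[idx], `[[`, 0, "delta"))
    labels <- c(base_labels,
                vapply(var_sites[idx], `[[`, "", "label"))
    forms[[length(forms) + 1L]] <<- data.frame(
      sequence = seqs, amidated = isTRUE(peptide$amidated),
      mods = paste(labels, collapse = ","),
      mass = peptide_mass(seqs) + deltas, stringsAsFactors = FALSE)
  }
  add_form(integer())
  if (nv > 0L) {
    for (k in seq_len(min(max_variable, nv))) {
      combos <- utils::combn(nv, k, simplify = FALSE)
      for (cmb in combos) {
        ## a terminus accepts at most one modification
        term <- vapply(var_sites[cmb], function(v)
          if (is.na(v$terminus)) "" else v$terminus, "")
        if (any(term == "C") && occupied_cterm) next
        if (anyDuplicated(term[nzchar(term)])) next
        add_form(cmb)
      }
    }
  }
  do.call(rbind, forms)
}

#' Match theoretical peptide masses to observed masses
#'
#' Pairs every theoretical form with every observed neutral mass within the
#' ppm tolerance (boundary inclusive: \code{|ppm| <= tolerance} matches).
#'
#' @param theoreticals Data frame with columns \code{sequence},
#'   \code{mods}, \code{mass} (from \code{\link{enumerate_modified_forms}}).
#' @param observed Data frame with columns \code{id} and
#'   \code{neutral_mass}, or a numeric vector of neutral masses.
#' @param tolerance_ppm Tolerance (default 4.5 ppm, the precursor-level
#'   window).
#' @return Data frame of matches sorted by \code{abs(ppm_error)}:
#'   theoretical columns plus \code{observed_id}, \code{observed_mass},
#'   \code{ppm_error}, \code{within_tolerance} (always TRUE for returned
#'   rows).
#' @export
match_masses <- function(theoreticals, observed, tolerance_ppm = 4.5) {
  if (tolerance_ppm <= 0) stop("tolerance must be positive")
  if (is.numeric(observed))
    observed <- data.frame(id = paste0("obs", seq_along(observed)),
                           neutral_mass = observed)
  stopifnot(all(c("id", "neutral_mass") %in% names(observed)))
  nt <- nrow(theoreticals); no <- nrow(observed)
  if (!nt || !no)
    return(data.frame(sequence = character(), mods = character(),
                      mass = numeric(), observed_id = character(),
                      observed_mass = numeric(), ppm_error = numeric(),
                      within_tolerance = logical(),
                      stringsAsFactors = FALSE))
  ppm <- outer(theoreticals$mass, observed$neutral_mass,
               function(t, o) 1e6 * (o - t) / t)
  ## boundary-inclusive with a guard for floating-point representation of
  ## masses sitting exactly on the tolerance (1e-9 ppm ~ 1e-15 relative)
  hit <- which(abs(ppm) <= tolerance_ppm + 1e-9, arr.ind = TRUE)
  if (!nrow(hit))
    return(match_masses(theoreticals[0, , drop = FALSE], observed,
                        tolerance_ppm))
  out <- data.frame(
    sequence = theoreticals$sequence[hit[, 1L]],
    mods = theoreticals$mods[hit[, 1L]],
    mass = theoreticals$mass[hit[, 1L]],
    observed_id = observed$id[hit[, 2L]],
    observed_mass = observed$neutral_mass[hit[, 2L]],
    ppm_error = ppm[hit], stringsAsFactors = FALSE)
  out$within_tolerance <- TRUE
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an observed-mass table
#'
#' TSV with either (\code{id}, \code{neutral_mass}) or (\code{id},
#' \code{mz}, \code{charge}); m/z rows are converted to neutral masses with
#' the proton mass.
#'
#' @param path TSV path with header.
#' @return Data frame with \code{id}, \code{neutral_mass}.
#' @export
read_observed_masses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("neutral_mass" %in% names(df))
    return(df[, c("id", "neutral_mass")])
  stopifnot(all(c("id", "mz", "charge") %in% names(df)))
  data.frame(id = df$id,
             neutral_mass = mz_to_neutral(df$mz, df$charge),
             stringsAsFactors = FALSE)
}

#' Export predicted peptides as a search database FASTA
#'
#' Writes the base sequences of modified forms with modification
#' annotations in headers, usable as a database by external search
#' engines. Fragment-level tolerance (20 ppm) is recorded as metadata in
#' the header comment line of the file.
#'
#' @param forms Data frame from \code{\link{enumerate_modified_forms}}
#'   (rows from several peptides may be concatenated; an \code{id} column
#'   is used when present).
#' @param path Output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
write_peptide_db <- function(forms, path) {
  ids <- if (!is.null(forms$id)) forms$id else
    sprintf("pep%d", seq_len(nrow(forms)))
  hdr <- sprintf("%s mods=%s mass=%.5f fragment_tol_ppm=20", ids,
                 ifelse(nzchar(forms$mods), forms$mods, "none"), forms$mass)
  lines <- as.vector(rbind(paste0(">", hdr), forms$sequence))
  writeLines(lines, path)
  invisible(path)
}
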