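## Ground-truthed synthetic benchmark: decoy proteomes with planted
## multicopy neuropeptide precursors, and matching observed-mass lists.
##
## A planted precursor is built to the same grammar the screening patterns
## assume: signal peptide (Met + hydrophobic core + small cleavage
## residue), then alternating spacer / paracopy / (Gly donor) / dibasic
## blocks. Decoys are random-composition proteins: dibasic pairs arise in
## them by chance, which is intended -- the MCP call must depend on
## paracopy recurrence, not on mere cleavage sites.

## residues allowed in spacers and `x` realizations: no basics (would
## split paracopies), no Gly (would create spurious amide donors /
## monobasic contexts)
.SPACER_ALPHA <- setdiff(PROTEIN_ALPHABET, c("K", "R", "G"))

## run body with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, body) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(body)
}

#' Specification for a synthetic planted dataset
#'
#' @param n_decoys Number of decoy proteins (default 5000).
#' @param n_planted Number of planted precursors (default 50).
#' @param family_motifs Named character vector of family consensus motifs;
#'   \code{x} marks variable positions. Planted precursors are assigned
#'   round-robin. Defaults to three C-terminal amide motifs.
#' @param copies_range Paracopies per precursor, (min, max); default (6, 12).
#' @param spacer_len_range Spacer length range, default (2, 10).
#' @param amidated Logical: paracopies carry a Gly amide donor before the
#'   dibasic site (default TRUE).
#' @param point_mutation_rate Per-position substitution probability on
#'   realized paracopies (default 0.05).
#' @param decoy_len_range Decoy protein length range, default (80, 400).
#' @param background \code{"uniform"} (default) or \code{"empirical"}
#'   (vertebrate-like residue frequencies) for decoy composition.
#' @param seed Integer seed for the generator's private random stream.
#' @return List of class \code{PlantSpec}.
#' @export
plant_spec <- function(n_decoys = 5000L, n_planted = 50L,
                       family_motifs = c(SFxN = "SFxN", LxF = "LxF",
                                         PxFV = "PxFV"),
                       copies_range = c(6L, 12L),
                       spacer_len_range = c(2L, 10L), amidated = TRUE,
                       point_mutation_rate = 0.05,
                       decoy_len_range = c(80L, 400L),
                       background = c("uniform", "empirical"),
                       seed = 1L) {
  background <- match.arg(background)
  stopifnot(n_decoys >= 0L, n_planted >= 0L, length(family_motifs) >= 1L,
            copies_range[1L] <= copies_range[2L], copies_range[1L] >= 2L,
            spacer_len_range[1L] <= spacer_len_range[2L],
            spacer_len_range[1L] >= 2L,
            point_mutation_rate >= 0, point_mutation_rate <= 1)
  if (any(nchar(family_motifs) < 3L))
    stop("family motifs must be at least 3 residues long")
  if (any(nchar(family_motifs) + spacer_len_range[1L] + 2L > 35L))
    stop("infeasible spec: motif longer than the spacer budget ",
         "(motif + min spacer + site must fit the 35-residue inter-site gap)")
  if (is.null(names(family_motifs)))
    names(family_motifs) <- family_motifs
  structure(list(n_decoys = as.integer(n_decoys),
                 n_planted = as.integer(n_planted),
                 family_motifs = family_motifs,
                 copies_range = as.integer(copies_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 amidated = isTRUE(amidated),
                 point_mutation_rate = point_mutation_rate,
                 decoy_len_range = as.integer(decoy_len_range),
                 background = background, seed = as.integer(seed)),
            class = "PlantSpec")
}

.BG_EMPIRICAL <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
  H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
  P = 0.039, Q = 0.034, R = 0.052, S = 0.057, T = 0.051, V = 0.073,
  W = 0.013, Y = 0.032)

.sample_res <- function(n, alphabet = PROTEIN_ALPHABET, prob = NULL)
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")

.realize_paracopy <- function(motif, mutation_rate) {
  ch <- strsplit(motif, "")[[1L]]
  ch[ch == "x"] <- sample(.SPACER_ALPHA, sum(ch == "x"), replace = TRUE)
  mut <- stats::runif(length(ch)) < mutation_rate
  if (any(mut))
    ch[mut] <- vapply(ch[mut], function(orig)
      sample(setdiff(.SPACER_ALPHA, orig), 1L), "")
  paste(ch, collapse = "")
}

.plant_precursor <- function(id, motif, family, spec) {
  hydro_len <- sample(7:10, 1L)
  signal <- paste0("M", .sample_res(hydro_len, HYDROPHOBIC), "S")
  sig_len <- nchar(signal)
  n_copies <- sample(spec$copies_range[1L]:spec$copies_range[2L], 1L)
  parts <- signal
  pos <- sig_len
  copies <- list()
  ## each paracopy sits directly between its own dibasic sites, with a
  ## spacer segment (itself flanked by sites) in front:
  ## spacer KR pep [G] KR spacer KR pep [G] KR ...
  for (i in seq_len(n_copies)) {
    spacer <- .sample_res(sample(spec$spacer_len_range[1L]:
                                   spec$spacer_len_range[2L], 1L),
                          .SPACER_ALPHA)
    pep <- .realize_paracopy(motif, spec$point_mutation_rate)
    site_a <- paste(sample(c("K", "R"), 2L, replace = TRUE), collapse = "")
    site_b <- paste(sample(c("K", "R"), 2L, replace = TRUE), collapse = "")
    block <- paste0(spacer, site_a, pep, if (spec$amidated) "G", site_b)
    pep_start <- pos + nchar(spacer) + 2L
    copies[[i]] <- list(start = pep_start, end = pep_start + nchar(pep),
                        sequence = pep, amidated = spec$amidated)
    parts <- c(parts, block)
    pos <- pos + nchar(block)
  }
  tail <- .sample_res(sample(3:8, 1L), .SPACER_ALPHA)
  seqs <- paste0(paste(parts, collapse = ""), tail)
  list(record = protein_sequence(id, seqs),
       truth = list(id = id, family = family,
                    signal_span = c(0L, sig_len),
                    paracopies = copies))
}

#' Generate a synthetic proteome with planted precursors
#'
#' Deterministic given the plant specification's seed. Returns the
#' proteins (decoys plus
#' planted precursors, shuffled) and a ground-truth record for every
#' planted precursor: signal span, paracopy spans/sequences (0-based
#' half-open, re-slicing the emitted sequences exactly), amidation flags
#' and family label.
#'
#' @param spec A \code{\link{plant_spec}}.
#' @return List with \code{proteins} (list of
#'   \code{\link{protein_sequence}}) and \code{truth} (list keyed by
#'   planted id).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  .with_seed(spec$seed, {
    prob <- if (spec$background == "empirical")
      .BG_EMPIRICAL[PROTEIN_ALPHABET] else NULL
    decoys <- lapply(seq_len(spec$n_decoys), function(i) {
      len <- sample(spec$decoy_len_range[1L]:spec$decoy_len_range[2L], 1L)
      protein_sequence(sprintf("decoy%04d", i),
                       .sample_res(len, PROTEIN_ALPHABET, prob))
    })
    motifs <- spec$family_motifs
    planted <- lapply(seq_len(spec$n_planted), function(i) {
      k <- ((i - 1L) %% length(motifs)) + 1L
      .plant_precursor(sprintf("planted%03d", i), motifs[[k]],
                       names(motifs)[k], spec)
    })
    proteins <- c(decoys, lapply(planted, `[[`, "record"))
    proteins <- proteins[sample(length(proteins))]
    truth <- lapply(planted, `[[`, "truth")
    names(truth) <- vapply(truth, `[[`, "", "id")
    list(proteins = proteins, truth = truth)
  })
}

#' Write ground truth as JSON
#'
#' @param truth Truth list from \code{\link{generate_proteome}}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## neutral mass of a planted peptide as it would be observed: fixed
## carbamidomethyl on Cys, amide when flagged
.observed_form_mass <- function(sequence, amidated) {
  mods <- modification_set()
  cam <- mods$delta[mods$name == "carbamidomethyl"]
  ami <- mods$delta[mods$name == "amide"]
  nC <- lengths(regmatches(sequence, gregexpr("C", sequence, fixed = TRUE)))
  peptide_mass(sequence) + cam * nC + if (amidated) ami else 0
}

#' Generate an observed-mass list for planted peptides
#'
#' Emulates an LC-MS precursor-mass list: the neutral monoisotopic masses
#' of the planted paracopies (carbamidomethylated Cys, amidated where
#' flagged), perturbed by Gaussian ppm noise, with a dropout fraction
#' removed and uniform-random contaminant masses added.
#'
#' @param truth Truth list from \code{\link{generate_proteome}}.
#' @param noise_ppm_sd Gaussian noise standard deviation in ppm (default 0).
#' @param dropout Fraction of planted peptides removed (default 0).
#' @param contaminants Number of contaminant masses, uniform on 400--2000
#'   Da (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns \code{id}, \code{neutral_mass},
#'   \code{source} ("planted"/"contaminant").
#' @export
generate_observed_masses <- function(truth, noise_ppm_sd = 0, dropout = 0,
                                     contaminants = 0L, seed = 1L) {
  .with_seed(seed, {
    rows <- list()
    for (t in truth) for (i in seq_along(t$paracopies)) {
      p <- t$paracopies[[i]]
      m <- .observed_form_mass(p$sequence, p$amidated)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_p%02d", t$id, i), neutral_mass = m,
        source = "planted", stringsAsFactors = FALSE)
    }
    obs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), neutral_mass = numeric(),
                 source = character(), stringsAsFactors = FALSE)
    if (nrow(obs) && noise_ppm_sd > 0)
      obs$neutral_mass <- obs$neutral_mass *
        (1 + stats::rnorm(nrow(obs), 0, noise_ppm_sd) * 1e-6)
    if (nrow(obs) && dropout > 0) {
      keep <- stats::runif(nrow(obs)) >= dropout
      obs <- obs[keep, , drop = FALSE]
    }
    if (contaminants > 0L) {
      cont <- data.frame(
        id = sprintf("contam%03d", seq_len(contaminants)),
        neutral_mass = stats::runif(contaminants, 400, 2000),
        source = "contaminant", stringsAsFactors = FALSE)
      obs <- rbind(obs, cont)
    }
    rownames(obs) <- NULL
    obs
  })
}
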