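## Orchestration: translate -> scan -> annotate -> group -> merge ->
## reciprocal -> mass-match, as a configured, logged, deterministic run.

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the discovery pipeline with their
#' screening defaults: signal-peptide score cutoff 0.34, paracopy linkage
#' threshold 0.5, minimum 2 copies, e-value cutoff 1 (precursor preset),
#' precursor mass tolerance 4.5 ppm, minimum peptide length 4 for mass
#' matching.
#'
#' @param signal_threshold Signal-peptide score cutoff (default 0.34).
#' @param linkage_threshold Paracopy similarity linkage threshold (0.5).
#' @param min_copies Minimum paracopies for an MCP call (2).
#' @param min_peptide_len Minimum peptide length considered in grouping (3).
#' @param conservation_min Consensus conservation threshold (0.5).
#' @param family_threshold Consensus similarity for family merging (0.5).
#' @param matrix Substitution matrix for searches ("BLOSUM62").
#' @param evalue_cutoff Reciprocal-search e-value cutoff (1).
#' @param tolerance_ppm Precursor mass tolerance (4.5).
#' @param min_mass_len Minimum peptide length for mass matching (4).
#' @param max_variable Max simultaneous variable modifications (3).
#' @param monobasic Monobasic cleavage rule ("fgr").
#' @param patterns Named list of \code{PrositePattern}s (default
#'   \code{\link{builtin_patterns}}).
#' @param seed Integer seed recorded in the run log.
#' @return List of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(signal_threshold = 0.34,
                            linkage_threshold = 0.5, min_copies = 2L,
                            min_peptide_len = 3L, conservation_min = 0.5,
                            family_threshold = 0.5, matrix = "BLOSUM62",
                            evalue_cutoff = 1, tolerance_ppm = 4.5,
                            min_mass_len = 4L, max_variable = 3L,
                            monobasic = "fgr", patterns = NULL,
                            seed = 1L) {
  stopifnot(signal_threshold >= 0, signal_threshold <= 1,
            linkage_threshold > 0, linkage_threshold <= 1,
            min_copies >= 2L, tolerance_ppm > 0)
  structure(list(signal_threshold = signal_threshold,
                 linkage_threshold = linkage_threshold,
                 min_copies = as.integer(min_copies),
                 min_peptide_len = as.integer(min_peptide_len),
                 conservation_min = conservation_min,
                 family_threshold = family_threshold, matrix = matrix,
                 evalue_cutoff = evalue_cutoff,
                 tolerance_ppm = tolerance_ppm,
                 min_mass_len = as.integer(min_mass_len),
                 max_variable = as.integer(max_variable),
                 monobasic = monobasic,
                 patterns = patterns %||% builtin_patterns(),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "patterns")]),
               collapse = "")
  txt <- paste0(txt, paste(vapply(config$patterns, `[[`, "", "source_text"),
                           collapse = ";"))
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}

.as_protein_list <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fasta(x, "protein"))
  stopifnot(is.list(x))
  x
}

#' Run the discovery pipeline
#'
#' Executes the full precursor-discovery pipeline over one or more protein
#' datasets: motif prefilter with the configured patterns, signal-peptide
#' gate, cleavage/peptide annotation, within-precursor paracopy grouping,
#' cross-dataset MCP-family merging, reciprocal search of the called
#' precursors against every dataset, and (when observed masses are given)
#' precursor-level mass confirmation. Fully deterministic under a fixed
#' config.
#'
#' @param datasets Named list; each element a protein FASTA path or a list
#'   of \code{\link{protein_sequence}} objects.
#' @param config A \code{\link{pipeline_config}}.
#' @param external_signal Optional external signal-prediction table
#'   (applies across datasets, matched by sequence id).
#' @param observed Optional observed-mass data frame (\code{id},
#'   \code{neutral_mass}) or named list of such per dataset.
#' @return Object of class \code{mcp_report}: list with \code{calls}
#'   (per-precursor call table), \code{annotations}, \code{groups},
#'   \code{families}, \code{presence} (family x dataset), \code{reciprocal},
#'   \code{mass_matches}, \code{log}, \code{config}.
#' @export
run_pipeline <- function(datasets, config = pipeline_config(),
                         external_signal = NULL, observed = NULL) {
  stopifnot(inherits(config, "PipelineConfig"), length(datasets) >= 1L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  datasets <- lapply(datasets, .as_protein_list)
  if (any(lengths(datasets) == 0L))
    warning("empty dataset(s): ",
            paste(names(datasets)[lengths(datasets) == 0L], collapse = ", "))
  log <- list(list(stage = "input", counts = lengths(datasets)))

  ## stage 1: motif prefilter (vectorised over each dataset)
  candidates <- lapply(names(datasets), function(ds) {
    prots <- datasets[[ds]]
    if (!length(prots)) return(prots[0])
    res <- vapply(prots, `[[`, "", "residues")
    hit <- Reduce(`|`, lapply(config$patterns, .has_motif_match, res))
    prots[hit]
  })
  names(candidates) <- names(datasets)
  log <- c(log, list(list(stage = "motif_prefilter",
                          counts = lengths(candidates))))

  ## stage 2+3: annotate candidates, keep signal-positive ones
  annotations <- lapply(names(datasets), function(ds) {
    anns <- lapply(candidates[[ds]], annotate_precursor,
                   external = external_signal,
                   threshold = config$signal_threshold,
                   monobasic = config$monobasic)
    Filter(function(a) isTRUE(a$signal$has_signal), anns)
  })
  names(annotations) <- names(datasets)
  log <- c(log, list(list(stage = "signal_gate",
                          counts = lengths(annotations))))

  ## stage 4: paracopy grouping -> per-precursor MCP calls
  groups <- list()
  call_rows <- list()
  for (ds in names(datasets)) {
    for (ann in annotations[[ds]]) {
      peps <- ann$peptides
      peps <- peps[nchar(peps$sequence) >= config$min_peptide_len, ,
                   drop = FALSE]
      g <- group_paracopies(peps, min_copies = config$min_copies,
                            threshold = config$linkage_threshold,
                            conservation_min = config$conservation_min)
      g <- lapply(g, function(x) { attr(x, "dataset") <- ds; x })
      if (length(g)) groups <- c(groups, g)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        dataset = ds, id = ann$protein$id, n_peptides = nrow(ann$peptides),
        n_groups = length(g),
        max_copies = if (length(g)) max(vapply(g, function(x)
          nrow(x$members), 0L)) else 0L,
        is_mcp = length(g) > 0L, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(dataset = character(), id = character(),
               n_peptides = integer(), n_groups = integer(),
               max_copies = integer(), is_mcp = logical(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$dataset, calls$id), , drop = FALSE]
  rownames(calls) <- NULL
  log <- c(log, list(list(stage = "mcp_call",
                          counts = c(precursors = sum(calls$is_mcp),
                                     groups = length(groups)))))

  ## stage 5: family merge across datasets
  families <- merge_families(groups, threshold = config$family_threshold,
                             conservation_min = config$conservation_min)
  presence <- .presence_table(families, names(datasets))
  log <- c(log, list(list(stage = "families",
                          counts = c(families = length(families)))))

  ## stage 6: reciprocal search of called precursors against all datasets
  pos_ids <- calls$id[calls$is_mcp]
  pos <- list()
  for (ds in names(datasets))
    for (p in datasets[[ds]]) if (p$id %in% pos_ids)
      pos[[length(pos) + 1L]] <- p
  reciprocal <- if (length(pos))
    reciprocal_search(pos, datasets, matrix = config$matrix,
                      evalue_cutoff = config$evalue_cutoff)
  else data.frame()
  log <- c(log, list(list(stage = "reciprocal",
                          counts = c(pairs = nrow(reciprocal)))))

  ## stage 7: mass confirmation
  mass_matches <- NULL
  if (!is.null(observed)) {
    obs <- if (is.data.frame(observed)) observed else
      do.call(rbind, unname(observed))
    theo <- .pipeline_theoreticals(annotations, calls, config)
    mass_matches <- match_masses(theo, obs,
                                 tolerance_ppm = config$tolerance_ppm)
    log <- c(log, list(list(stage = "mass_match",
                            counts = c(theoretical = nrow(theo),
                                       matches = nrow(mass_matches)))))
  }

  structure(list(calls = calls, annotations = annotations,
                 groups = groups, families = families,
                 presence = presence, reciprocal = reciprocal,
                 mass_matches = mass_matches,
                 log = log,
                 run_info = list(package_version =
                                   as.character(utils::packageVersion("mcpminer")),
                                 config_hash = .config_hash(config),
                                 seed = config$seed),
                 config = config),
            class = "mcp_report")
}

## all modified forms of the peptides of called precursors
.pipeline_theoreticals <- function(annotations, calls, config) {
  rows <- list()
  for (ds in names(annotations)) for (ann in annotations[[ds]]) {
    if (!ann$protein$id %in% calls$id[calls$is_mcp]) next
    peps <- ann$peptides
    for (i in seq_len(nrow(peps))) {
      pep <- as.list(peps[i, ])
      pep$protein_n_term <- i == 1L
      f <- enumerate_modified_forms(pep,
                                    max_variable = config$max_variable,
                                    min_length = config$min_mass_len)
      if (nrow(f)) {
        f$id <- sprintf("%s_%d_%d", ann$protein$id, peps$start[i],
                        peps$end[i])
        rows[[length(rows) + 1L]] <- f
      }
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(), amidated = logical(),
                      mods = character(), mass = numeric(),
                      id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.presence_table <- function(families, dataset_names) {
  m <- matrix(0L, nrow = length(families), ncol = length(dataset_names),
              dimnames = list(vapply(families, `[[`, "", "name"),
                              dataset_names))
  for (i in seq_along(families)) {
    f <- families[[i]]
    for (g in f$groups) {
      ds <- attr(g, "dataset")
      if (!is.null(ds) && ds %in% dataset_names)
        m[i, ds] <- m[i, ds] + 1L
    }
  }
  m
}

#' @export
print.mcp_report <- function(x, ...) {
  cat("MCP discovery report\n")
  for (entry in x$log)
    cat(sprintf("  %-16s %s\n", entry$stage,
                paste(names(entry$counts), entry$counts, sep = "=",
                      collapse = " ")))
  cat(sprintf("  %d MCP families: %s\n", length(x$families),
              paste(utils::head(vapply(x$families, `[[`, "", "name"), 8L),
                    collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits deterministic TSV/FASTA/JSON files: precursor call table, peptide
#' annotation table, family table with per-dataset presence, per-family
#' PFMs and alignments, reciprocal-hit table, optional mass-match table,
#' and the run log.
#'
#' @param report An \code{mcp_report}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(report$calls, "precursor_calls.tsv")
  pep_rows <- list()
  for (ds in names(report$annotations))
    for (ann in report$annotations[[ds]])
      if (nrow(ann$peptides)) {
        p <- ann$peptides
        p$dataset <- ds
        pep_rows[[length(pep_rows) + 1L]] <- p
      }
  peps <- if (length(pep_rows)) do.call(rbind, pep_rows) else
    data.frame()
  w(peps, "predicted_peptides.tsv")
  fam <- data.frame(
    family = vapply(report$families, `[[`, "", "name"),
    consensus = vapply(report$families, `[[`, "", "family_consensus"),
    amidation = vapply(report$families, `[[`, "", "amidated"),
    n_groups = vapply(report$families, function(f) length(f$groups), 0L),
    n_peptides = vapply(report$families, `[[`, 0L, "n_peptides"),
    datasets = vapply(report$families, function(f)
      paste(f$datasets, collapse = ","), ""),
    stringsAsFactors = FALSE)
  w(fam, "mcp_families.tsv")
  utils::write.table(report$presence, file.path(dir, "family_presence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (f in report$families) {
    safe <- gsub("[^A-Za-z0-9]", "_", f$name)
    write_pfm(f, file.path(dir, sprintf("pfm_%s.tsv", safe)))
    aligned <- unlist(lapply(f$groups, `[[`, "alignment"))
    ids <- unlist(lapply(f$groups, function(g)
      sprintf("%s_%d_%d", g$members$parent_id, g$members$start,
              g$members$end)))
    names(aligned) <- ids
    write_fasta(aligned, file.path(dir, sprintf("alignment_%s.fasta", safe)))
  }
  if (nrow(report$reciprocal)) w(report$reciprocal, "reciprocal_pairs.tsv")
  if (!is.null(report$mass_matches)) w(report$mass_matches,
                                       "mass_matches.tsv")
  loglines <- vapply(report$log, function(e)
    sprintf("%s\t%s", e$stage, paste(names(e$counts), e$counts, sep = "=",
                                     collapse = " ")), "")
  writeLines(c(sprintf("mcpminer\t%s", report$run_info$package_version),
               sprintf("config_hash\t%s", report$run_info$config_hash),
               sprintf("seed\t%d", report$run_info$seed),
               loglines), file.path(dir, "run_log.tsv"))
  invisible(dir)
}

#' Evaluate a pipeline run against synthetic ground truth
#'
#' Computes the benchmark quantities for a run over a dataset produced by
#' \code{\link{generate_proteome}}: planted-precursor recall, MCP-family
#' assignment accuracy (majority-label purity over merged families), and
#' the decoy false-positive rate.
#'
#' @param report An \code{mcp_report} from a run over the synthetic
#'   proteins.
#' @param truth Truth list from \code{\link{generate_proteome}}.
#' @param n_decoys Number of decoys in the dataset.
#' @return List with \code{recall}, \code{family_accuracy},
#'   \code{decoy_fpr}, \code{n_planted}, \code{n_recovered}.
#' @export
evaluate_recovery <- function(report, truth, n_decoys) {
  planted_ids <- names(truth)
  called <- report$calls$id[report$calls$is_mcp]
  recovered <- intersect(called, planted_ids)
  recall <- length(recovered) / length(planted_ids)
  decoy_fp <- setdiff(called, planted_ids)
  decoy_fpr <- length(decoy_fp) / n_decoys
  ## family purity: each planted precursor's merged family should be
  ## dominated by its own truth label
  fam_of <- list()
  for (i in seq_along(report$families))
    for (g in report$families[[i]]$groups)
      fam_of[[g$parent_id]] <- c(fam_of[[g$parent_id]], i)
  correct <- 0L; assessed <- 0L
  labels <- vapply(truth, `[[`, "", "family")
  for (id in recovered) {
    fams <- unique(fam_of[[id]])
    if (is.null(fams)) next
    ## the family holding this precursor's largest group
    fam <- fams[1L]
    members <- unlist(lapply(report$families[[fam]]$groups,
                             function(g) g$parent_id))
    member_labels <- labels[intersect(unique(members), planted_ids)]
    if (!length(member_labels)) next
    majority <- names(sort(table(member_labels), decreasing = TRUE))[1L]
    assessed <- assessed + 1L
    if (identical(majority, labels[[id]])) correct <- correct + 1L
  }
  list(recall = recall,
       family_accuracy = if (assessed) correct / assessed else NA_real_,
       decoy_fpr = decoy_fpr, n_planted = length(planted_ids),
       n_recovered = length(recovered))
}
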