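#' Write a coarse-grained model as a PDB file
#'
#' One CA and one CB atom record per residue (CB omitted where it
#' coincides with CA, e.g. glycine).
#'
#' @param model A `fold_model`.
#' @param path Output file.
#' @param sequence Optional residue codes for residue names.
#' @export
write_model_pdb <- function(model, path, sequence = NULL) {
  L <- nrow(model$ca)
  res3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
            "-" = "ALA")
  resid <- if (is.null(sequence)) rep("ALA", L) else
    unname(res3[decode_residue(sequence)])
  has_cb <- rowSums((model$cb - model$ca)^2) > 1e-9
  xyz <- numeric(0); resno <- integer(0); elety <- character(0)
  resnm <- character(0)
  for (i in seq_len(L)) {
    xyz <- c(xyz, model$ca[i, ]); resno <- c(resno, i)
    elety <- c(elety, "CA"); resnm <- c(resnm, resid[i])
    if (has_cb[i]) {
      xyz <- c(xyz, model$cb[i, ]); resno <- c(resno, i)
      elety <- c(elety, "CB"); resnm <- c(resnm, resid[i])
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resnm,
                   elety = elety, chain = "A")
  invisible(path)
}

#' Read a coarse-grained model back from PDB
#' @param path PDB file with CA (and optionally CB) records.
#' @return A `fold_model`.
#' @export
read_model_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety == "CA", ]
  new_fold_model(cbind(at$x, at$y, at$z))
}

#' Pipeline configuration
#'
#' Validated container for one end-to-end run; serialized verbatim (YAML)
#' into the output directory for reproducibility.
#'
#' @param msa Path to the alignment (FASTA/Stockholm).
#' @param ss Path to the secondary-structure track (or NULL).
#' @param reference Path to a reference PDB for evaluation (or NULL).
#' @param outdir Output directory.
#' @param theta Reweighting identity threshold.
#' @param lambda Pseudocount mass (NULL = meff).
#' @param mi_lambda Pseudocount for the MI branch.
#' @param nc_values N_C grid (NULL = [nc_grid()] of L).
#' @param n_per_bin Candidates per N_C bin.
#' @param seed Master seed.
#' @param filters Filter toggles for [select_eics()].
#' @param min_sequences Warn below this alignment depth (default 1000).
#' @param restraints A [restraint_config].
#' @param schedule An [anneal_schedule].
#' @param write_all_models Write every candidate PDB (default: top only).
#' @export
pipeline_config <- function(msa = NULL, ss = NULL, reference = NULL,
                            outdir = "dcafold_out", theta = 0.7,
                            lambda = NULL, mi_lambda = 0, nc_values = NULL,
                            n_per_bin = 20L, seed = 1L,
                            filters = c("min_separation", "ss_conflict",
                                        "conservation", "cys_exclusivity"),
                            min_sequences = 1000L,
                            restraints = restraint_config(),
                            schedule = anneal_schedule(),
                            write_all_models = FALSE) {
  cfg <- list(msa = msa, ss = ss, reference = reference, outdir = outdir,
              theta = theta, lambda = lambda, mi_lambda = mi_lambda,
              nc_values = nc_values, n_per_bin = as.integer(n_per_bin),
              seed = seed, filters = filters,
              min_sequences = as.integer(min_sequences),
              restraints = restraints, schedule = schedule,
              write_all_models = write_all_models)
  stopifnot(cfg$theta > 0, cfg$theta < 1, cfg$n_per_bin >= 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[intersect(names(x),
                                       names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
      file = path, append = TRUE)
  invisible(msg)
}

#' Stage 1: couplings
#'
#' Reads and reweights the alignment, computes DI/MI for all pairs, and
#' writes the ranked-pair TSV, the per-sequence weights, and a run log
#' (recording Meff, the effective-sequence fraction, lambda and timing).
#' Families below `min_sequences` rows produce a warning, not an error.
#'
#' @param config A [pipeline_config] (or path to its YAML).
#' @return List: `scores` (`score_table`), `walign`, `aln`, `paths`.
#' @export
run_couplings <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$outdir, "run.log")
  write_pipeline_config(config, file.path(config$outdir, "config.yml"))
  t0 <- Sys.time()
  aln <- read_alignment(config$msa)
  if (n_seq(aln) < config$min_sequences) {
    msg <- log_line(logf,
                    "WARNING: only %d sequences (recommended >= %d) - couplings may be noisy",
                    n_seq(aln), config$min_sequences)
    warn(msg)
  }
  walign <- compute_weights(aln, theta = config$theta)
  log_line(logf, "alignment: M = %d, L = %d; Meff = %.1f (%.0f%% effective)",
           n_seq(aln), n_col(aln), walign$meff,
           100 * walign$meff / n_seq(aln))
  scores <- score_all_pairs(walign, lambda = config$lambda,
                            mi_lambda = config$mi_lambda)
  log_line(logf, "scored %d pairs with lambda = %.3g in %.1f s",
           n_col(aln) * (n_col(aln) - 1) / 2, scores$lambda,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  paths <- list(scores = file.path(config$outdir, "ranked_pairs.tsv"),
                weights = file.path(config$outdir, "weights.tsv"))
  write_scores(scores, paths$scores)
  write_weights(walign, paths$weights)
  list(scores = scores, walign = walign, aln = aln, paths = paths)
}

#' Stage 2: select, fold, rank (and optionally evaluate)
#'
#' Selects EICs over the N_C grid, generates the candidate ensemble,
#' ranks it blindly (handedness + knot filter), writes the top-ranked
#' model as the blind prediction, and, when a reference structure is
#' given, evaluates contacts and the top model against it.
#'
#' @param config A [pipeline_config].
#' @param couplings Output of [run_couplings()] (re-run when NULL).
#' @return List: `eics_by_nc`, `models`, `ranking`, `top_model`,
#'   `evaluation` (NULL without reference), `paths`.
#' @export
run_fold_and_rank <- function(config, couplings = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  couplings <- couplings %||% run_couplings(config)
  logf <- file.path(config$outdir, "run.log")
  aln <- couplings$aln
  L <- n_col(aln)
  ss <- if (!is.null(config$ss)) read_ss_track(config$ss) else
    ss_track(rep("C", L))
  stopifnot(nrow(ss) == L)
  ncs <- config$nc_values %||% nc_grid(L)
  eics_by_nc <- setNames(
    lapply(ncs, function(nc)
      select_eics(couplings$scores, n_c = nc, ss = ss, aln = aln,
                  filters = config$filters)),
    ncs)
  models <- generate_ensemble(eics_by_nc, ss, L,
                              n_per_bin = config$n_per_bin,
                              seed = config$seed,
                              config = config$restraints,
                              schedule = config$schedule)
  ranking <- rank_candidates(models, ss)
  log_line(logf, "ensemble: %d models over N_C in {%s}; %d knotted",
           length(models), paste(ncs, collapse = ", "),
           sum(ranking$knotted))
  paths <- list(ranking = file.path(config$outdir, "ranking.tsv"),
                top_model = file.path(config$outdir, "top_model.pdb"))
  write.table(ranking, paths$ranking, sep = "\t", quote = FALSE,
              row.names = FALSE)
  top <- ranking$model[!is.na(ranking$rank)][1]
  top_model <- if (length(top) && !is.na(top)) models[[top]] else NULL
  if (!is.null(top_model)) {
    write_model_pdb(top_model, paths$top_model,
                    sequence = reference_codes(aln))
  }
  if (isTRUE(config$write_all_models)) {
    for (k in seq_along(models)) {
      p <- models[[k]]$provenance
      write_model_pdb(models[[k]],
                      file.path(config$outdir,
                                sprintf("model_nc%03d_r%02d.pdb",
                                        p$n_c, p$replicate)))
    }
  }
  for (nc in names(eics_by_nc)) {
    write_eics(eics_by_nc[[nc]],
               file.path(config$outdir, sprintf("eics_nc%s.tsv", nc)))
  }
  evaluation <- NULL
  if (!is.null(config$reference) && !is.null(top_model)) {
    obs <- contacts_from_reference(config$reference)
    ref <- read_model_pdb(config$reference)
    evaluation <- evaluate_prediction(tidy(couplings$scores), obs,
                                      model = top_model, reference = ref,
                                      nc_values = ncs)
    paths$evaluation <- file.path(config$outdir, "evaluation.json")
    jsonlite::write_json(
      list(contacts = as.data.frame(evaluation),
           structure = as.data.frame(structure_metrics(evaluation))),
      paths$evaluation, auto_unbox = TRUE, digits = NA)
    log_line(logf, "evaluation written (reference: %s)", config$reference)
  }
  list(eics_by_nc = eics_by_nc, models = models, ranking = ranking,
       top_model = top_model, evaluation = evaluation, paths = paths)
}

#' Full pipeline
#'
#' [run_couplings()] followed by [run_fold_and_rank()], with a manifest of
#' every output file.
#'
#' @param config A [pipeline_config].
#' @return The [run_fold_and_rank()] result, plus `couplings`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  couplings <- run_couplings(config)
  res <- run_fold_and_rank(config, couplings)
  res$couplings <- couplings
  manifest <- c(unlist(couplings$paths), unlist(res$paths))
  writeLines(manifest, file.path(config$outdir, "MANIFEST"))
  res
}
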