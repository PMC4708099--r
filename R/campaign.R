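#' Run a full detachment campaign from a config file
#'
#' Wires the whole workflow: build (or load) the complex, thread each
#' peptide sequence, run the Monte Carlo replicas, write per-peptide probe
#' tables and trajectories, then the score table, ROC summary and optional
#' bootstrap analysis. A manifest (config snapshot, seeds, checksums,
#' timestamps) is written before the first trajectory. Completed peptides
#' are detected by their finished probe tables and skipped on re-run;
#' partial outputs produced under a different config are refused unless
#' `force = TRUE`.
#'
#' Config keys (YAML or list): either `synthetic: true` with an optional
#' `toy:` block ([toy_spec()] fields) or `structure:` (PDB path) plus
#' `hierarchy:` (see [build_pmhc_hierarchy()]) and `potential:` (table
#' path); `peptides:` (list of `sequence:` + optional `class:` / `ic50:`),
#' `replicas:`, `steps:`, `base_seed:`, `probe_stride:`, `anneal:`
#' (`amplitude`, `omega`, `shift`), `respect_sequence:` (sequence-aware
#' anchors in the Go fixture), `bootstrap:` (`n_values`, `B`).
#'
#' @param config path to a YAML config file, or an equivalent list
#' @param out_dir output directory
#' @param force overwrite outputs from a mismatched earlier config
#' @param quiet suppress progress messages
#' @return (invisibly) the output directory
#' @export
run_campaign <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  cfg_path <- NULL
  if (is.character(config)) { cfg_path <- config; config <- yaml::read_yaml(config) }
  if (is.null(config$peptides) || !length(config$peptides))
    stop("run_campaign: config lists no peptides")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_digest <- digest_config(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_digest, cfg_digest) && !force)
      stop("run_campaign: existing outputs in ", out_dir,
           " were produced by a different config; use force = TRUE to overwrite")
  }
  say <- function(...) if (!quiet) message(...)

  base_seed <- config$base_seed %||% 0L
  n_rep <- config$replicas %||% 2L
  n_steps <- config$steps %||% 2000L
  stride <- config$probe_stride %||% 100L
  ann <- config$anneal %||% list()
  schedule <- anneal_schedule(amplitude = ann$amplitude %||% 600,
                              omega = ann$omega %||% 5000,
                              shift = ann$shift %||% 0,
                              total_steps = n_steps)

  peptides <- lapply(config$peptides, function(p)
    if (is.character(p)) list(sequence = p) else p)
  seqs <- vapply(peptides, `[[`, character(1), "sequence")
  seeds <- base_seed + (seq_along(seqs) - 1L) * (n_rep + 1L)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hnmmc")),
    config = config, config_digest = cfg_digest,
    base_seed = base_seed,
    peptide_seeds = stats::setNames(as.list(seeds), seqs),
    input_checksums = input_checksums(config, cfg_path),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  synthetic <- isTRUE(config$synthetic)
  if (!synthetic) {
    structure0 <- coarse_grain_structure(config$structure)
    hier_cfg <- config$hierarchy
    pot0 <- read_pair_potential(config$potential)
    probes0 <- do.call(probe_set, c(list(
      peptide_chain = hier_cfg$peptide_chain,
      receptor_chain = hier_cfg$mhc_chain),
      config$probes %||% list()))
  }

  score_rows <- list()
  rep_score_rows <- list()
  for (k in seq_along(peptides)) {
    pep <- peptides[[k]]
    tag <- sprintf("pep%02d_%s", k, pep$sequence)
    probe_file <- file.path(out_dir, paste0(tag, "_probes.tsv"))
    if (file.exists(probe_file)) {
      say("campaign: ", tag, " already complete; skipping")
      rs <- read_replica_set(probe_file)
    } else {
      say("campaign: running ", tag, " (", n_rep, " replicas x ", n_steps, " steps)")
      if (synthetic) {
        tspec <- do.call(toy_spec, c(config$toy %||% list(),
                                     list(peptide_sequence = pep$sequence,
                                          peptide_length = nchar(pep$sequence))))
        cx <- make_toy_complex(tspec)
        go <- make_go_potential(cx, respect_sequence = isTRUE(config$respect_sequence))
        st <- go$structure; pot <- go$potential
        hier <- cx$hierarchy; probes <- cx$probes
      } else {
        st <- thread_peptide(structure0, hier_cfg$peptide_chain, pep$sequence)
        pot <- pot0; probes <- probes0
        hier <- build_pmhc_hierarchy(st, hier_cfg)
      }
      rs <- run_replicas(st, hier, pot, probes, schedule, n_replicas = n_rep,
                         base_seed = seeds[k], peptide_id = pep$sequence,
                         probe_stride = stride,
                         keep_trajectories = isTRUE(config$write_trajectories))
      if (isTRUE(config$write_trajectories)) {
        trs <- attr(rs, "trajectories")
        for (i in seq_along(trs))
          write_beads_pdb(st, file.path(out_dir, sprintf("%s_rep%03d.pdb", tag, i)),
                          snapshots = trs[[i]]$snapshots)
      }
      write_replica_set(rs, probe_file)
    }
    score_rows[[k]] <- data.frame(sequence = pep$sequence,
                                  class = pep$class %||% NA_character_,
                                  ic50 = pep$ic50 %||% NA_real_,
                                  score = detachment_score(rs))
    rep_score_rows[[k]] <- replica_scores(rs)
  }
  scores <- do.call(rbind, score_rows)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (all(!is.na(scores$class)) && length(unique(scores$class)) == 2) {
    roc <- data.frame(auroc = auroc(scores$score, scores$class))
    if (all(!is.na(scores$ic50)))
      roc$pearson_log10_ic50 <- pearson_r(scores$score, scores$ic50)
    utils::write.table(roc, file.path(out_dir, "roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bs <- config$bootstrap
    if (!is.null(bs)) {
      mat <- do.call(rbind, rep_score_rows)
      res <- bootstrap_auroc_sd(mat, scores$class,
                                n_values = unlist(bs$n_values %||% c(1, min(25, n_rep), n_rep)),
                                B = bs$B %||% 500L, seed = base_seed + 7777L)
      utils::write.table(res, file.path(out_dir, "bootstrap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

digest_config <- function(config) {
  norm <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(norm, tf)
  unname(tools::md5sum(tf))
}

input_checksums <- function(config, cfg_path) {
  files <- unlist(Filter(Negate(is.null),
                         list(cfg_path, config$structure, config$potential)))
  if (!length(files)) return(list())
  files <- files[nzchar(files) & file.exists(files)]
  if (!length(files)) return(list())
  as.list(tools::md5sum(files))
}
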