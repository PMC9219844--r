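# End-to-end orchestration: configuration, staged execution with
# stage-labelled errors, seeded determinism, and the tabular data products
# (differential tables, annotation, EC layers and overlap, reaction evidence,
# pathway activity, iPath selection file, run report).

#' Pipeline configuration
#'
#' @param input_dir Directory holding the inputs (the layout written by
#'   [write_fixture()]: runs, samples, counts, registry and mapping tables).
#' @param output_dir Directory for the emitted data products.
#' @param tol_ppm Annotation mass tolerance (ppm).
#' @param q_meta Metabolite-layer FDR cutoff for the differential table.
#' @param p_meta_strict Stricter raw-p tier used for the metabolite-to-EC
#'   step and pathway scoring.
#' @param q_rna Transcript-layer FDR cutoff.
#' @param tier Minimum PFAM-to-EC confidence tier.
#' @param co_elution_window Adduct-group co-elution window (minutes).
#' @param anchor_min_presence Anchor presence fraction for RT alignment.
#' @param B Permutation count for pathway scoring.
#' @param pseudo Pseudo-intensity / pseudo-count for the Welch stages.
#' @param seed Integer seed; recorded in every output header.
#' @return Validated list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            tol_ppm = 10, q_meta = 0.05,
                            p_meta_strict = 0.001, q_rna = 0.05,
                            tier = "gold", co_elution_window = 0.2,
                            anchor_min_presence = 0.9, B = 999,
                            pseudo = 1, seed = 1) {
  cfg <- as.list(environment())
  for (th in c(q_meta, p_meta_strict, q_rna))
    if (th <= 0 || th >= 1) stop("significance thresholds must lie in (0, 1)")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  if (co_elution_window <= 0) stop("co_elution_window must be > 0")
  structure(cfg, class = "pipeline_config")
}

# Run one pipeline stage; on error, remove partial outputs and abort with the
# stage name and cause.
run_stage <- function(name, expr, cleanup = NULL) {
  tryCatch(expr, error = function(e) {
    if (!is.null(cleanup)) unlink(cleanup)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full dual-omics pipeline
#'
#' Stages: retention-time alignment of the LC-MS runs, technical-replicate
#' averaging, feature-level Welch/BH differential abundance, compound x
#' adduct annotation with co-elution grouping, count-matrix differential
#' expression, EC-set derivation from each omics layer, EC overlap, reaction
#' evidence classification, permutation pathway activity scoring, and export
#' of the tabular products plus an iPath selection file and a JSON run
#' report. Idempotent given the seed.
#'
#' @param config A `pipeline_config`.
#' @return The run report, invisibly: per-stage record counts, config echo
#'   and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$output_dir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(paste0("# seed: ", config$seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }

  inp <- run_stage("load", {
    need <- c("runs.tsv", "samples.tsv", "counts.tsv", "compounds.tsv",
              "adducts.tsv", "gene2pfam.tsv", "pfam2ec.tsv", "compound2ec.tsv",
              "ec2reaction.tsv", "reaction2pathway.tsv", "pathway_compounds.tsv")
    missing <- need[!file.exists(file.path(config$input_dir, need))]
    if (length(missing))
      stop("missing input file(s): ",
           paste(file.path(config$input_dir, missing), collapse = ", "))
    rd <- function(f) utils::read.delim(file.path(config$input_dir, f),
                                        stringsAsFactors = FALSE,
                                        comment.char = "#", check.names = FALSE)
    runs_long <- rd("runs.tsv")
    runs <- lapply(split(runs_long, runs_long$run), function(x)
      x[, c("id", "mz", "rt", "intensity")])
    samples <- rd("samples.tsv")
    list(runs = runs[samples$run], samples = samples,
         counts = read_count_matrix(file.path(config$input_dir, "counts.tsv")),
         registry = load_registry(file.path(config$input_dir, "compounds.tsv"),
                                  file.path(config$input_dir, "adducts.tsv")),
         maps = read_mapping_tables(config$input_dir),
         pathway_compounds = rd("pathway_compounds.tsv"))
  }, written)

  aligned <- run_stage("align", {
    al <- align_retention(inp$runs, mz_tol_ppm = config$tol_ppm,
                          anchor_min_presence = config$anchor_min_presence)
    merge_runs(al$runs)
  }, written)

  features <- run_stage("average", {
    rep_map <- stats::setNames(inp$samples$biological, inp$samples$run)
    run_cols <- setdiff(names(aligned), c("id", "mz", "rt"))
    avg <- average_technical_replicates(aligned[, run_cols, drop = FALSE],
                                        rep_map)
    cbind(aligned[, c("id", "mz", "rt")], as.data.frame(avg))
  }, written)

  groups_bio <- stats::setNames(inp$samples$group, inp$samples$biological)
  groups_bio <- groups_bio[!duplicated(names(groups_bio))]

  diff_tab <- run_stage("metabolomics",
    diff_features(features, groups_bio, pseudo = config$pseudo), written)

  ann <- run_stage("annotate",
    annotate_table(diff_tab, inp$registry, tol_ppm = config$tol_ppm,
                   co_elution_window = config$co_elution_window), written)

  degs <- run_stage("rnaseq", {
    grp <- stats::setNames(inp$samples$group, inp$samples$biological)
    de_test(inp$counts, grp[!duplicated(names(grp))], pseudo = config$pseudo)
  }, written)

  integration <- run_stage("integrate", {
    t_ecs <- ecs_from_degs(degs, inp$maps, tier = config$tier,
                           q_threshold = config$q_rna)
    m_ecs <- ecs_from_metabolites(ann$table, inp$maps,
                                  p_threshold = config$p_meta_strict)
    ov <- overlap_ecs(t_ecs, m_ecs)
    recs <- reactions_for_ecs(union(t_ecs, m_ecs), inp$maps, t_ecs, m_ecs)
    list(transcript_ecs = t_ecs, metabolite_ecs = m_ecs, overlap = ov,
         reactions = recs)
  }, written)

  pathways <- run_stage("enrich",
    pathway_activity(ann$table, inp$pathway_compounds,
                     sig_threshold = config$p_meta_strict, B = config$B,
                     seed = config$seed), written)

  report <- run_stage("export", {
    emit(diff_tab, "metabolite_differential.tsv")
    emit(ann$table, "metabolite_annotated.tsv")
    emit(ann$groups, "adduct_groups.tsv")
    emit(degs, "transcript_degs.tsv")
    emit(data.frame(layer = c(rep("transcript", length(integration$transcript_ecs)),
                              rep("metabolite", length(integration$metabolite_ecs)),
                              rep("overlap", length(integration$overlap))),
                    ec = c(integration$transcript_ecs,
                           integration$metabolite_ecs, integration$overlap)),
         "ec_layers.tsv")
    emit(integration$reactions, "reactions.tsv")
    emit(pathways[, setdiff(names(pathways), "members")], "pathway_activity.tsv")
    if (nrow(integration$reactions) > 0)
      export_ipath(integration$reactions,
                   file.path(outdir, "ipath_selection.txt"))
    overlap_reactions <- unique(
      inp$maps$ec2reaction$reaction[inp$maps$ec2reaction$ec %in%
                                      integration$overlap])
    report <- list(
      package_version = as.character(utils::packageVersion("duomics")),
      config = config[setdiff(names(config), c("input_dir", "output_dir"))],
      counts = list(
        runs = length(inp$runs),
        features_tested = nrow(diff_tab),
        features_significant_q = sum(diff_tab$q_value < config$q_meta,
                                     na.rm = TRUE),
        features_significant_strict = sum(diff_tab$p_value < config$p_meta_strict,
                                          na.rm = TRUE),
        features_annotated = sum(!is.na(ann$table$compound)),
        adduct_groups = nrow(ann$groups),
        genes_tested = nrow(degs),
        genes_significant = sum(degs$q_value < config$q_rna, na.rm = TRUE),
        transcript_ecs = length(integration$transcript_ecs),
        metabolite_ecs = length(integration$metabolite_ecs),
        overlap_ecs = length(integration$overlap),
        overlap_reactions = length(overlap_reactions),
        reactions = nrow(integration$reactions),
        pathways_scored = nrow(pathways)))
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, written)

  invisible(report)
}

#' Simulate a dataset and write it as a pipeline input directory
#'
#' Convenience wrapper around [simulate_dataset()] + [write_fixture()];
#' deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @param dir Output directory.
#' @param registry Compound registry; defaults to a [synthetic_registry()]
#'   sized to the config and seeded from it.
#' @return The `synthetic_dataset`, invisibly.
#' @export
simulate_fixture <- function(config, dir,
                             registry = synthetic_registry(config$n_compounds,
                                                           seed = config$seed)) {
  ds <- simulate_dataset(config, registry)
  write_fixture(ds, dir)
  invisible(ds)
}
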