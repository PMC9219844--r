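# Synthetic paired metabolomics + transcriptomics data with planted ground
# truth. Emulates a 2-group x 3-biological-replicate design with technical
# triplicate LC-MS runs, compounds emitted as 1-3 co-eluting adduct features
# with log-normal intensity noise and ppm-scale mass error, per-run linear
# retention-time warps, and negative-binomial gene counts with planted
# differentially expressed genes whose PFAM-derived ECs are coupled to the
# differential compounds' ECs so that a nonempty dual-evidence overlap exists
# by construction.

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: biological
#' triplicates per group, technical triplicate LC-MS runs averaged before
#' testing, planted differential compounds with 4-32x fold-changes,
#' log-normal intensity noise (log-sd 0.3), mass accuracy within 2 ppm
#' (lock-mass calibrated instrument), a two-cluster retention-time model
#' (hydrophilic < 5 min, hydrophobic >= 5 min over a 14-min gradient), and
#' negative-binomial counts (dispersion 0.05) with planted DE genes.
#'
#' @param n_control,n_treated Biological replicates per group.
#' @param n_technical Technical LC-MS runs per biological sample.
#' @param n_compounds Number of registry compounds to emit.
#' @param frac_differential Fraction of compounds planted as differential.
#' @param fold_change_range Multiplicative fold-change range (low > 1).
#' @param intensity_log_sd Log-normal noise sd on the natural-log scale.
#' @param mass_error_ppm Maximum absolute mass error in ppm (errors are
#'   Gaussian with sd `mass_error_ppm / 3`, truncated at the maximum).
#' @param rt_hydrophilic,rt_hydrophobic Mean/sd (minutes) of the two
#'   retention-time clusters.
#' @param frac_hydrophobic Fraction of compounds in the late-eluting cluster.
#' @param rt_jitter_sd Within-compound adduct co-elution jitter (minutes).
#' @param per_sample_rt_shift_sd Per-run retention-time offset sd (minutes);
#'   per-run slopes are drawn from N(1, `rt_slope_sd`).
#' @param rt_slope_sd Sd of the per-run linear warp slope.
#' @param n_genes Number of genes in the count matrix.
#' @param frac_de_genes Fraction of genes planted as differentially expressed.
#' @param de_lfc_range Absolute log2 fold-change range for planted DE genes.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param coupling Fraction of the differential compounds' ECs also assigned
#'   (gold tier) to planted DE genes, creating the true dual-evidence overlap.
#' @param seed Integer seed; all randomness in [simulate_dataset()] flows
#'   from it.
#' @return Validated list with class `"sim_config"`.
#' @export
sim_config <- function(n_control = 3, n_treated = 3, n_technical = 3,
                       n_compounds = 100, frac_differential = 0.2,
                       fold_change_range = c(4, 32), intensity_log_sd = 0.3,
                       mass_error_ppm = 2,
                       rt_hydrophilic = c(mean = 1.5, sd = 1.0),
                       rt_hydrophobic = c(mean = 8, sd = 2),
                       frac_hydrophobic = 0.4, rt_jitter_sd = 0.01,
                       per_sample_rt_shift_sd = 0.05, rt_slope_sd = 0.01,
                       n_genes = 2000, frac_de_genes = 0.1,
                       de_lfc_range = c(2, 4), nb_dispersion = 0.05,
                       coupling = 0.6, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_control = n_control, n_treated = n_treated,
              n_technical = n_technical, n_compounds = n_compounds,
              n_genes = n_genes)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  for (f in c(frac_differential, frac_de_genes))
    if (f <= 0 || f >= 1) stop("fractions must lie in (0, 1)")
  if (fold_change_range[1] <= 1 || diff(fold_change_range) < 0)
    stop("fold_change_range must be increasing with low > 1")
  if (intensity_log_sd < 0 || nb_dispersion <= 0 || mass_error_ppm < 0)
    stop("noise parameters must be non-negative (dispersion > 0)")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic compound registry
#'
#' Random but chemically plausible CHNOS formulas with synthetic CAS/KEGG
#' identifiers, 1-2 EC links per compound drawn from a synthetic EC universe,
#' and 1-2 pathway memberships drawn from a synthetic pathway pool. Useful
#' when a simulation needs more compounds than the packaged reference
#' registry provides.
#'
#' @param n Number of compounds.
#' @param n_ecs Size of the metabolite-side EC universe.
#' @param n_pathways Size of the pathway pool.
#' @param seed Integer seed.
#' @return A `compound_registry`.
#' @export
synthetic_registry <- function(n, n_ecs = max(4L, round(n * 0.8)),
                               n_pathways = max(3L, round(n / 6)), seed = 1) {
  withr::with_seed(seed, {
    ecs <- unique(sprintf("%d.%d.%d.%d", sample(1:6, n_ecs, TRUE),
                          sample(1:20, n_ecs, TRUE), sample(1:30, n_ecs, TRUE),
                          sample(1:99, n_ecs, TRUE)))
    paths <- sprintf("synthetic pathway %02d", seq_len(n_pathways))
    seen <- character(0)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        nc <- sample(4:40, 1)
        nh <- sample(seq(max(4, nc), 2 * nc + 2), 1)
        nn <- sample(0:4, 1)
        no <- sample(1:8, 1)
        ns <- stats::rbinom(1, 1, 0.1)
        f <- paste0("C", nc, "H", nh, if (nn) paste0("N", nn) else "",
                    "O", no, if (ns) "S" else "")
        if (!f %in% seen) break
      }
      seen <- c(seen, f)
      rows[[i]] <- data.frame(
        name = sprintf("syncpd%04d", i), formula = f,
        cas = sprintf("%d-%02d-%d", 100000 + i, sample(10:99, 1), sample(0:9, 1)),
        kegg = sprintf("C9%04d", i),
        ec_links = paste(sample(ecs, sample(1:2, 1)), collapse = ";"),
        pathways = paste(sample(paths, sample(1:2, 1)), collapse = ";"),
        verified = "TRUE", stringsAsFactors = FALSE)
    }
    comp <- do.call(rbind, rows)
  })
  comp$neutral_mass <- vapply(comp$formula, monoisotopic_mass, numeric(1))
  comp$verified <- TRUE
  structure(list(compounds = comp, adducts = default_adducts()),
            class = "compound_registry")
}

#' Simulate a paired metabolomics + transcriptomics dataset
#'
#' See [sim_config()] for the generative model. The returned object carries
#' everything a pipeline run needs (per-run feature tables, sample sheet,
#' count matrix, mapping tables) plus the planted ground truth.
#'
#' @param config A `sim_config`.
#' @param registry A `compound_registry` with at least
#'   `config$n_compounds` compounds.
#' @return List of class `"synthetic_dataset"`: `config`, `registry` (the
#'   subset used), `features` (consensus wide table: `id`, `mz`, `rt`, one
#'   intensity column per run), `runs` (named list of per-run `id`, `mz`,
#'   `rt`, `intensity` tables with warped retention times), `samples` (run ->
#'   biological sample -> group), `counts`, `maps` (gene2pfam, pfam2ec,
#'   compound2ec, ec2reaction, reaction2pathway), `pathway_compounds`,
#'   `feature_truth`, and `truth` (differential compounds with signed
#'   fold-changes, DE genes with log2 fold-changes, per-layer EC sets and
#'   their intersection).
#' @export
simulate_dataset <- function(config, registry) {
  stopifnot(inherits(config, "sim_config"))
  comp_all <- registry$compounds
  if (nrow(comp_all) < config$n_compounds)
    stop("registry smaller than n_compounds")
  n_diff <- round(config$n_compounds * config$frac_differential)
  if (n_diff < 1) stop("configuration plants zero differential compounds")
  n_de <- round(config$n_genes * config$frac_de_genes)
  if (n_de < 1) stop("configuration plants zero DE genes")

  withr::with_seed(config$seed, {
    comp <- comp_all[sample.int(nrow(comp_all), config$n_compounds), ]
    comp <- comp[order(comp$name), ]
    adducts <- registry$adducts
    primary <- "M+H[1+]"

    diff_idx <- sort(sample.int(nrow(comp), n_diff))
    ratio <- rep(1, nrow(comp))
    fc <- stats::runif(n_diff, config$fold_change_range[1],
                       config$fold_change_range[2])
    up <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
    ratio[diff_idx] <- ifelse(up, fc, 1 / fc)

    hydrophobic <- stats::runif(nrow(comp)) < config$frac_hydrophobic
    rt <- ifelse(hydrophobic,
                 pmin(pmax(stats::rnorm(nrow(comp), config$rt_hydrophobic["mean"],
                                        config$rt_hydrophobic["sd"]), 5), 14),
                 pmin(pmax(stats::rnorm(nrow(comp), config$rt_hydrophilic["mean"],
                                        config$rt_hydrophilic["sd"]), 0.3), 4.9))
    base_int <- 10^stats::runif(nrow(comp), 5, 7)

    # 1-3 adducts per compound at fixed relative abundances
    rel_ab <- c(1, 0.3, 0.1)
    other_adducts <- setdiff(adducts$name, primary)
    feat <- list()
    for (i in seq_len(nrow(comp))) {
      n_ad <- sample(1:3, 1)
      ads <- c(primary, sample(other_adducts, n_ad - 1))
      for (k in seq_len(n_ad)) {
        theo <- adduct_mz(comp$neutral_mass[i], ads[k], adducts)
        err <- stats::rnorm(1, 0, config$mass_error_ppm / 3)
        err <- max(min(err, config$mass_error_ppm), -config$mass_error_ppm)
        feat[[length(feat) + 1L]] <- data.frame(
          compound = comp$name[i], adduct = ads[k], theoretical_mz = theo,
          mz = theo * (1 + err * 1e-6),
          rt = rt[i] + stats::rnorm(1, 0, config$rt_jitter_sd),
          expected_control = base_int[i] * rel_ab[k],
          ratio = ratio[i], rel_abundance = rel_ab[k],
          stringsAsFactors = FALSE)
      }
    }
    feat <- do.call(rbind, feat)
    feat$id <- sprintf("F%04d", seq_len(nrow(feat)))

    bio <- c(paste0("ctrl", seq_len(config$n_control)),
             paste0("trt", seq_len(config$n_treated)))
    group <- rep(c("control", "treated"),
                 c(config$n_control, config$n_treated))
    samples <- data.frame(
      run = as.vector(t(outer(bio, seq_len(config$n_technical),
                              function(b, t) paste0(b, "_t", t)))),
      biological = rep(bio, each = config$n_technical),
      group = rep(group, each = config$n_technical),
      stringsAsFactors = FALSE)

    expected <- matrix(feat$expected_control, nrow(feat), nrow(samples))
    trt_cols <- samples$group == "treated"
    expected[, trt_cols] <- expected[, trt_cols] * feat$ratio
    noise <- matrix(stats::rnorm(length(expected), 0, config$intensity_log_sd),
                    nrow(expected))
    intensities <- expected * exp(noise)
    colnames(intensities) <- samples$run

    runs <- lapply(seq_len(nrow(samples)), function(j) {
      slope <- stats::rnorm(1, 1, config$rt_slope_sd)
      offset <- stats::rnorm(1, 0, config$per_sample_rt_shift_sd)
      data.frame(id = feat$id, mz = feat$mz, rt = slope * feat$rt + offset,
                 intensity = intensities[, j], stringsAsFactors = FALSE)
    })
    names(runs) <- samples$run

    features <- data.frame(id = feat$id, mz = feat$mz, rt = feat$rt,
                           stringsAsFactors = FALSE)
    features <- cbind(features, as.data.frame(intensities))

    # ---- transcript layer -------------------------------------------------
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    mu <- exp(stats::runif(config$n_genes, log(2), log(2000)))
    de_idx <- sort(sample.int(config$n_genes, n_de))
    lfc <- numeric(config$n_genes)
    lfc[de_idx] <- stats::runif(n_de, config$de_lfc_range[1],
                                config$de_lfc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
    n_samp <- config$n_control + config$n_treated
    counts <- matrix(0L, config$n_genes, n_samp,
                     dimnames = list(genes, bio))
    size <- 1 / config$nb_dispersion
    for (j in seq_len(n_samp)) {
      mu_j <- if (group[j] == "treated") mu * 2^lfc else mu
      counts[, j] <- stats::rnbinom(config$n_genes, mu = mu_j, size = size)
    }
    storage.mode(counts) <- "integer"

    # ---- mapping tables ---------------------------------------------------
    has_pfam <- stats::runif(config$n_genes) < 0.9
    gene2pfam <- data.frame(gene = genes[has_pfam],
                            pfam = sprintf("PF%05d", which(has_pfam)),
                            stringsAsFactors = FALSE)

    comp_ecs <- lapply(comp$ec_links, split_links)
    names(comp_ecs) <- comp$name
    metab_true_ecs <- sort(unique(unlist(comp_ecs[diff_idx])))
    all_metab_ecs <- sort(unique(unlist(comp_ecs)))
    extra_ecs <- unique(sprintf("%d.%d.%d.%d", sample(1:6, 400, TRUE),
                                sample(21:40, 400, TRUE), sample(1:30, 400, TRUE),
                                sample(100:199, 400, TRUE)))
    ec_universe <- unique(c(all_metab_ecs, extra_ecs))
    transcript_pool <- setdiff(ec_universe, metab_true_ecs)

    n_shared <- max(1L, round(config$coupling * length(metab_true_ecs)))
    shared <- sort(sample(metab_true_ecs, n_shared))

    de_with_pfam <- intersect(genes[de_idx], gene2pfam$gene)
    if (length(de_with_pfam) == 0L)
      stop("no planted DE gene carries a PFAM; enlarge n_genes")
    # each dual-evidence EC is carried by several DE genes (enzyme families
    # and PFAM-EC associations are many-to-many in real annotation data)
    n_carrier <- sample(2:4, length(shared), replace = TRUE)
    carrier <- unlist(lapply(n_carrier, function(k)
      sample(de_with_pfam, min(k, length(de_with_pfam)))))
    shared_rep <- rep(shared, pmin(n_carrier, length(de_with_pfam)))
    others <- setdiff(genes[has_pfam], carrier)
    n_ec_other <- sample(1:2, length(others), replace = TRUE)
    other_ecs <- lapply(seq_along(others), function(k) {
      pool <- if (others[k] %in% de_with_pfam) transcript_pool else ec_universe
      sample(pool, n_ec_other[k])
    })
    p2e <- data.frame(
      pfam = gene2pfam$pfam[match(c(carrier, rep(others, n_ec_other)),
                                  gene2pfam$gene)],
      ec = c(shared_rep, unlist(other_ecs)),
      tier = c(rep("gold", length(shared_rep)),
               ifelse(stats::runif(sum(n_ec_other)) < 0.1, "silver", "gold")),
      stringsAsFactors = FALSE)

    compound2ec <- do.call(rbind, lapply(comp$name, function(nm) {
      e <- comp_ecs[[nm]]
      if (length(e) == 0L) return(NULL)
      data.frame(compound = nm, cas = comp$cas[comp$name == nm], ec = e,
                 stringsAsFactors = FALSE)
    }))

    reactions <- sprintf("RXN%04d", seq_len(round(1.3 * length(ec_universe))))
    ec2reaction <- do.call(rbind, lapply(ec_universe, function(e)
      data.frame(ec = e, reaction = sample(reactions, sample(1:3, 1)),
                 stringsAsFactors = FALSE)))
    path_pool <- unique(c(unlist(lapply(comp$pathways, split_links)),
                          sprintf("reaction pathway %02d", 1:10)))
    used_rxn <- unique(ec2reaction$reaction)
    reaction2pathway <- do.call(rbind, lapply(used_rxn, function(r)
      data.frame(reaction = r, pathway = sample(path_pool, sample(1:2, 1)),
                 stringsAsFactors = FALSE)))

    pathway_compounds <- do.call(rbind, lapply(comp$name, function(nm) {
      p <- split_links(comp$pathways[comp$name == nm])
      if (length(p) == 0L) return(NULL)
      data.frame(pathway = p, compound = nm, stringsAsFactors = FALSE)
    }))
  })

  # ground truth derived from the constructed tables, not re-sampled
  de_genes <- genes[de_idx]
  de_pfams <- gene2pfam$pfam[gene2pfam$gene %in% de_genes]
  transcript_true_ecs <- sort(unique(
    p2e$ec[p2e$pfam %in% de_pfams & p2e$tier == "gold"]))
  truth <- list(
    differential = data.frame(
      compound = comp$name[diff_idx],
      ratio = ratio[diff_idx],
      fold_change = signed_fold_change(log2(ratio[diff_idx])),
      stringsAsFactors = FALSE),
    de_genes = data.frame(gene = de_genes, log2fc = lfc[de_idx],
                          stringsAsFactors = FALSE),
    metabolite_ecs = metab_true_ecs,
    transcript_ecs = transcript_true_ecs,
    overlap_ecs = sort(intersect(transcript_true_ecs, metab_true_ecs))
  )

  structure(list(
    config = config,
    registry = structure(list(compounds = comp, adducts = adducts),
                         class = "compound_registry"),
    features = features, runs = runs, samples = samples, counts = counts,
    maps = structure(list(gene2pfam = gene2pfam, pfam2ec = p2e,
                          compound2ec = compound2ec, ec2reaction = ec2reaction,
                          reaction2pathway = reaction2pathway),
                     class = "mapping_tables"),
    pathway_compounds = pathway_compounds,
    feature_truth = feat[, c("id", "compound", "adduct", "theoretical_mz",
                             "mz", "rt", "ratio", "rel_abundance")],
    truth = truth
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset as a fixture directory
#'
#' Emits the delimited formats the pipeline readers consume (runs, samples,
#' counts, registry and mapping tables, pathway membership) plus the ground
#' truth tables. [read_fixture()] round-trips the result.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  runs_long <- do.call(rbind, lapply(names(dataset$runs), function(r)
    cbind(run = r, dataset$runs[[r]])))
  counts_df <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  truth_ecs <- rbind(
    data.frame(layer = "metabolite", ec = dataset$truth$metabolite_ecs),
    data.frame(layer = "transcript", ec = dataset$truth$transcript_ecs),
    data.frame(layer = "overlap", ec = dataset$truth$overlap_ecs))
  paths <- c(
    features = w(dataset$features, "features.tsv"),
    runs = w(runs_long, "runs.tsv"),
    samples = w(dataset$samples, "samples.tsv"),
    counts = w(counts_df, "counts.tsv"),
    compounds = w(dataset$registry$compounds[
      , c("name", "formula", "cas", "kegg", "ec_links", "pathways", "verified")],
      "compounds.tsv"),
    adducts = w(dataset$registry$adducts, "adducts.tsv"),
    gene2pfam = w(dataset$maps$gene2pfam, "gene2pfam.tsv"),
    pfam2ec = w(dataset$maps$pfam2ec, "pfam2ec.tsv"),
    compound2ec = w(dataset$maps$compound2ec, "compound2ec.tsv"),
    ec2reaction = w(dataset$maps$ec2reaction, "ec2reaction.tsv"),
    reaction2pathway = w(dataset$maps$reaction2pathway, "reaction2pathway.tsv"),
    pathway_compounds = w(dataset$pathway_compounds, "pathway_compounds.tsv"),
    feature_truth = w(dataset$feature_truth, "truth_features.tsv"),
    truth_compounds = w(dataset$truth$differential, "truth_compounds.tsv"),
    truth_genes = w(dataset$truth$de_genes, "truth_genes.tsv"),
    truth_ecs = w(truth_ecs, "truth_ecs.tsv"))
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with elements `features`, `runs`, `samples`, `counts`,
#'   `registry`, `maps`, `pathway_compounds`, `feature_truth`, `truth`.
#' @export
read_fixture <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing fixture file: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                      check.names = FALSE)
  }
  runs_long <- rd("runs.tsv")
  runs <- lapply(split(runs_long, runs_long$run), function(x) {
    rownames(x) <- NULL
    x[, c("id", "mz", "rt", "intensity")]
  })
  samples <- rd("samples.tsv")
  runs <- runs[samples$run]
  truth_ecs <- rd("truth_ecs.tsv")
  list(
    features = rd("features.tsv"),
    runs = runs,
    samples = samples,
    counts = read_count_matrix(file.path(dir, "counts.tsv")),
    registry = load_registry(file.path(dir, "compounds.tsv"),
                             file.path(dir, "adducts.tsv")),
    maps = read_mapping_tables(dir),
    pathway_compounds = rd("pathway_compounds.tsv"),
    feature_truth = rd("truth_features.tsv"),
    truth = list(
      differential = rd("truth_compounds.tsv"),
      de_genes = rd("truth_genes.tsv"),
      metabolite_ecs = truth_ecs$ec[truth_ecs$layer == "metabolite"],
      transcript_ecs = truth_ecs$ec[truth_ecs$layer == "transcript"],
      overlap_ecs = truth_ecs$ec[truth_ecs$layer == "overlap"])
  )
}
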