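# Dual-omics EC-set integration: an EC set derived from significant genes
# via PFAM associations, an EC set derived from significant annotated
# metabolites via compound/CAS associations, their intersection, expansion to
# reactions, and per-reaction evidence classification.

#' Validate Enzyme Commission code syntax
#'
#' Four dot-separated fields; the last may be `-` for a partial code.
#' Partial codes are syntactically accepted but never match at overlap time.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_ec <- function(x) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", x)
}

ec_tiers <- c(gold = 3L, silver = 2L, bronze = 1L)

#' Read the mapping tables used for EC integration
#'
#' Expects tab-separated files in `dir`: `gene2pfam.tsv` (`gene`, `pfam`),
#' `pfam2ec.tsv` (`pfam`, `ec`, `tier` in gold/silver/bronze),
#' `compound2ec.tsv` (`compound`, `cas`, `ec`), `ec2reaction.tsv`
#' (`ec`, `reaction`), `reaction2pathway.tsv` (`reaction`, `pathway`).
#' Every EC in every table must parse.
#'
#' @param dir Directory containing the five files.
#' @return List of data frames with class `"mapping_tables"`.
#' @export
read_mapping_tables <- function(dir) {
  files <- c(gene2pfam = "gene2pfam.tsv", pfam2ec = "pfam2ec.tsv",
             compound2ec = "compound2ec.tsv", ec2reaction = "ec2reaction.tsv",
             reaction2pathway = "reaction2pathway.tsv")
  maps <- lapply(files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing mapping table: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  })
  for (tab in c("pfam2ec", "compound2ec", "ec2reaction")) {
    bad <- !is_ec(maps[[tab]]$ec)
    if (any(bad))
      stop("malformed EC code(s) in ", tab, ": ",
           paste(unique(maps[[tab]]$ec[bad]), collapse = ", "))
  }
  bad_tier <- !maps$pfam2ec$tier %in% names(ec_tiers)
  if (any(bad_tier))
    stop("unknown confidence tier(s): ",
         paste(unique(maps$pfam2ec$tier[bad_tier]), collapse = ", "))
  structure(maps, class = "mapping_tables")
}

#' EC set from differentially expressed genes
#'
#' Significant genes (q below threshold) are mapped to PFAM accessions and
#' then to EC codes, keeping associations at or above the requested
#' confidence tier. Genes without a PFAM assignment are skipped and counted
#' in a message.
#'
#' @param degs Data frame from [de_test()] (needs `gene`, `q_value`).
#' @param maps A `mapping_tables` list.
#' @param tier Minimum confidence tier: `"gold"`, `"silver"` or `"bronze"`.
#' @param q_threshold Significance cutoff on the q-value.
#' @return Sorted character vector of EC codes.
#' @export
ecs_from_degs <- function(degs, maps, tier = "gold", q_threshold = 0.05) {
  if (!tier %in% names(ec_tiers)) stop("unknown tier: ", tier)
  sig <- degs$gene[!is.na(degs$q_value) & degs$q_value < q_threshold]
  g2p <- maps$gene2pfam
  no_pfam <- sum(!sig %in% g2p$gene)
  if (no_pfam > 0)
    message(no_pfam, " significant gene(s) without a PFAM assignment skipped")
  pfams <- unique(g2p$pfam[g2p$gene %in% sig])
  p2e <- maps$pfam2ec
  keep <- p2e$pfam %in% pfams & ec_tiers[p2e$tier] >= ec_tiers[tier]
  sort(unique(p2e$ec[keep]))
}

#' EC set from significant annotated metabolites
#'
#' Rank-1-annotated features with raw p below the threshold are mapped to EC
#' codes through the compound-to-EC table, keyed by CAS number when the
#' feature's compound has one, otherwise by compound name. Unannotated
#' significant features are skipped and counted in a message.
#'
#' @param annotated Annotated differential table (the `table` element of
#'   [annotate_table()]; needs `compound`, `compound_cas`, `p_value`).
#' @param maps A `mapping_tables` list.
#' @param p_threshold Significance cutoff on the raw p-value.
#' @return Sorted character vector of EC codes.
#' @export
ecs_from_metabolites <- function(annotated, maps, p_threshold = 0.001) {
  sig <- annotated[!is.na(annotated$p_value) &
                     annotated$p_value < p_threshold, , drop = FALSE]
  n_unann <- sum(is.na(sig$compound))
  if (n_unann > 0)
    message(n_unann, " significant unannotated feature(s) skipped")
  sig <- sig[!is.na(sig$compound), , drop = FALSE]
  c2e <- maps$compound2ec
  ecs <- character(0)
  for (i in seq_len(nrow(sig))) {
    cas <- sig$compound_cas[i]
    rows <- if (!is.na(cas) && nzchar(cas) && any(c2e$cas == cas, na.rm = TRUE))
      c2e$ec[!is.na(c2e$cas) & c2e$cas == cas]
    else
      c2e$ec[c2e$compound == sig$compound[i]]
    ecs <- c(ecs, rows)
  }
  sort(unique(ecs))
}

#' Intersection of the two layer EC sets
#'
#' Exact string intersection on full four-field codes; partial codes
#' (trailing `-`) never match.
#'
#' @param transcript_ecs,metabolite_ecs Character vectors of EC codes.
#' @return Sorted character vector, a subset of both inputs.
#' @export
overlap_ecs <- function(transcript_ecs, metabolite_ecs) {
  full <- function(x) x[is_ec(x) & !endsWith(x, "-")]
  sort(intersect(full(transcript_ecs), full(metabolite_ecs)))
}

#' Reactions touched by a set of ECs, with evidence classification
#'
#' One record per distinct reaction reached from the input ECs through the
#' EC-to-reaction table. A reaction's evidence is `"both"` when its
#' supporting ECs intersect both layer sets, otherwise `"transcript_only"` or
#' `"metabolite_only"`. ECs absent from the reaction table are skipped and
#' counted in a message.
#'
#' @param ecs EC codes to expand (typically the union or overlap of the two
#'   layers).
#' @param maps A `mapping_tables` list.
#' @param transcript_ecs,metabolite_ecs The two layer EC sets.
#' @return Data frame `reaction`, `ecs` (semicolon-joined supporting ECs
#'   among the input), `evidence`, `pathways` (semicolon-joined), with the
#'   layer sets attached as attributes `transcript_ecs` / `metabolite_ecs`.
#' @export
reactions_for_ecs <- function(ecs, maps, transcript_ecs, metabolite_ecs) {
  e2r <- maps$ec2reaction
  missing <- setdiff(ecs, e2r$ec)
  if (length(missing))
    message(length(missing), " EC(s) absent from the reaction table skipped")
  hits <- e2r[e2r$ec %in% ecs, , drop = FALSE]
  r2p <- maps$reaction2pathway
  recs <- lapply(sort(unique(hits$reaction)), function(r) {
    sup <- sort(unique(hits$ec[hits$reaction == r]))
    in_t <- any(sup %in% transcript_ecs)
    in_m <- any(sup %in% metabolite_ecs)
    data.frame(
      reaction = r,
      ecs = paste(sup, collapse = ";"),
      evidence = if (in_t && in_m) "both" else if (in_t) "transcript_only"
                 else if (in_m) "metabolite_only" else "none",
      pathways = paste(sort(unique(r2p$pathway[r2p$reaction == r])),
                       collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(reaction = character(0), ecs = character(0),
               evidence = character(0), pathways = character(0),
               stringsAsFactors = FALSE)
  attr(out, "transcript_ecs") <- transcript_ecs
  attr(out, "metabolite_ecs") <- metabolite_ecs
  out
}

#' Export an iPath selection file
#'
#' One line per EC occurring in the reaction records:
#' `"<EC> <hexcolor> W<width>"`. ECs with dual-layer evidence are bold black
#' (`#000000 W20`), transcript-only ECs green (`#00ff00 W10`),
#' metabolite-only ECs blue (`#0000ff W10`). Lines are sorted by EC code.
#'
#' @param records Output of [reactions_for_ecs()] (its layer-set attributes
#'   drive the per-EC evidence classification).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
export_ipath <- function(records, path) {
  if (nrow(records) == 0L) stop("no reaction records to export")
  t_ecs <- attr(records, "transcript_ecs")
  m_ecs <- attr(records, "metabolite_ecs")
  ecs <- sort(unique(unlist(strsplit(records$ecs, ";", fixed = TRUE))))
  line <- vapply(ecs, function(e) {
    in_t <- e %in% t_ecs
    in_m <- e %in% m_ecs
    if (in_t && in_m) paste(e, "#000000 W20")
    else if (in_t) paste(e, "#00ff00 W10")
    else paste(e, "#0000ff W10")
  }, character(1))
  writeLines(unname(line), path)
  invisible(path)
}
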