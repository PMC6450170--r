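# End-to-end orchestration from a single configuration: DEG calling in two
# tissues -> cross-tissue overlap -> hot-spot scans and their overlap ->
# over-connectivity against both DEG sets (shared significant genes) ->
# one-step expansion and hub ranking -> enrichment -> qPCR (optional) ->
# multi-criterion prioritization. Every stage writes a TSV and the run ends
# with a JSON summary carrying the effective thresholds and the row count at
# each gate.

default_thresholds <- function() {
  list(p_max_deg = 0.05, fc_min = 1.1, min_degs = 5, p_max_hotspot = 0.001,
       p_max_conn = 0.05, q_max_enrich = 0.05, hub_quantile = 0.9)
}

#' Validate a pipeline run configuration
#'
#' A config is a named list (or a JSON file encoding one) with entries:
#' `expression_a`, `groups_a`, `case_a`, `control_a` (and the `_b`
#' counterparts), `gene_map`, `network`, `gene_sets`, `universe` (optional
#' path to a one-symbol-per-line platform list; defaults to the expression
#' genes), `ct`, `ct_meta` (optional), `annotations`, `out_dir`, and any of
#' the thresholds `p_max_deg`, `fc_min`, `min_degs`, `p_max_hotspot`,
#' `p_max_conn`, `q_max_enrich`, `hub_quantile` (defaulting to 0.05, 1.1, 5,
#' 0.001, 0.05, 0.05, 0.9). All referenced files must exist at validation
#' time, before any compute.
#'
#' @param config named list or path to a JSON config file.
#' @return the normalized config list, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_validation("config file does not exist: ", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("expression_a", "groups_a", "case_a", "control_a",
                "expression_b", "groups_b", "case_b", "control_b",
                "gene_map", "network", "gene_sets", "annotations", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort_validation("config is missing required entrie(s): ",
                     paste(missing, collapse = ", "))
  }
  paths <- c("expression_a", "groups_a", "expression_b", "groups_b",
             "gene_map", "network", "gene_sets", "annotations")
  if (!is.null(config$ct)) paths <- c(paths, "ct", "ct_meta")
  if (!is.null(config$universe)) paths <- c(paths, "universe")
  for (p in paths) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      abort_validation("config entry '", p, "' does not name an existing file: ",
                       config[[p]] %||% "<missing>")
    }
  }
  th <- default_thresholds()
  for (nm in names(th)) {
    if (!is.null(config[[nm]])) th[[nm]] <- config[[nm]]
  }
  if (th$p_max_deg <= 0 || th$p_max_deg > 1 || th$fc_min < 1 ||
        th$min_degs < 1 || th$p_max_hotspot <= 0 || th$p_max_conn <= 0 ||
        th$q_max_enrich <= 0 || th$hub_quantile < 0 || th$hub_quantile > 1) {
    abort_validation("a threshold is out of its valid range")
  }
  config$thresholds <- th
  invisible(config)
}

#' Run the full triage pipeline from a configuration
#'
#' Executes every stage in order, writing each intermediate table as TSV
#' under `out_dir` plus a machine-readable `run_summary.json` with the counts
#' at each gate and all effective thresholds. Re-running with an identical
#' config produces byte-identical outputs (the pipeline itself draws no
#' random numbers).
#'
#' @param config named list or JSON path; see [validate_config()].
#' @return the run summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  th <- config$thresholds
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  em_a <- stage("read_expression_a",
                read_expression_matrix(config$expression_a, config$groups_a,
                                       config$probe_map_a))
  em_b <- stage("read_expression_b",
                read_expression_matrix(config$expression_b, config$groups_b,
                                       config$probe_map_b))
  degs_a <- stage("deg_a", call_degs(em_a, config$case_a, config$control_a,
                                     th$p_max_deg, th$fc_min, tissue = "A"))
  degs_b <- stage("deg_b", call_degs(em_b, config$case_b, config$control_b,
                                     th$p_max_deg, th$fc_min, tissue = "B"))
  write_degs(degs_a, file.path(out_dir, "degs_a.tsv"))
  write_degs(degs_b, file.path(out_dir, "degs_b.tsv"))

  ovl <- stage("overlap", overlap_profiles(degs_a, degs_b))
  ovl_df <- data.frame(
    gene = ovl$common,
    concordance = ifelse(ovl$common %in% ovl$same_direction,
                         "same", "opposite"), stringsAsFactors = FALSE)
  utils::write.table(ovl_df, file.path(out_dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  map <- stage("read_gene_map", read_gene_map(config$gene_map))
  hs_a <- stage("hotspots_a", scan_hotspots(map, degs_a$gene, th$min_degs,
                                            th$p_max_hotspot))
  hs_b <- stage("hotspots_b", scan_hotspots(map, degs_b$gene, th$min_degs,
                                            th$p_max_hotspot))
  write_hotspots(hs_a, file.path(out_dir, "hotspots_a.tsv"))
  write_hotspots(hs_b, file.path(out_dir, "hotspots_b.tsv"))
  hs_ovl <- stage("hotspot_overlap", overlap_hotspots(hs_a, hs_b))
  hs_ovl_out <- hs_ovl
  hs_ovl_out$shared_genes <- collapse_genes(hs_ovl_out$shared_genes)
  utils::write.table(hs_ovl_out, file.path(out_dir, "hotspot_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net <- stage("read_network", read_network(config$network))
  universe <- if (!is.null(config$universe)) {
    canonical_symbol(readLines(config$universe))
  } else {
    sort(unique(c(rownames(em_a$values), rownames(em_b$values))))
  }
  background <- intersect(net$nodes, universe)
  conn_a <- stage("overconnect_a",
                  overconnected_genes(net, degs_a$gene, background,
                                      candidates = ovl$common, p_max = 1))
  conn_b <- stage("overconnect_b",
                  overconnected_genes(net, degs_b$gene, background,
                                      candidates = ovl$common, p_max = 1))
  utils::write.table(conn_a, file.path(out_dir, "connectivity_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conn_b, file.path(out_dir, "connectivity_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shared_over <- intersect(conn_a$gene[conn_a$p <= th$p_max_conn],
                           conn_b$gene[conn_b$p <= th$p_max_conn])

  seeds <- if (length(shared_over)) shared_over else ovl$common
  expanded <- stage("expand", expand_network(net, seeds))
  hubs <- stage("hub_rank", hub_rank(expanded))
  utils::write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sets <- stage("read_gene_sets", read_gene_sets(config$gene_sets))
  enr <- stage("enrich", enrich(degs_b[, c("gene", "direction")], sets,
                                universe))
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))

  qp <- NULL
  if (!is.null(config$ct)) {
    ct <- stage("read_ct", read_ct_table(config$ct, config$ct_meta,
                                         config$housekeeping %||% "ACTB",
                                         config$reference_sample))
    qp <- stage("qpcr", qpcr_fold_changes(ct))
    utils::write.table(qp$summary, file.path(out_dir, "qpcr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ann <- stage("read_annotations", read_annotations(config$annotations))
  scores <- stage("prioritize",
                  score_candidates(ovl, degs_a = degs_a, degs_b = degs_b,
                                   qpcr = qp, enrichment = enr,
                                   conn_a = conn_a, conn_b = conn_b,
                                   hubs = hubs, hotspot_overlap = hs_ovl,
                                   annotations = ann,
                                   q_max = th$q_max_enrich,
                                   p_max_conn = th$p_max_conn,
                                   hub_quantile = th$hub_quantile))
  utils::write.table(scores, file.path(out_dir, "ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  receptors <- filter_receptors(scores$gene, ann)
  drugs <- attach_drugs(scores$gene, ann)
  utils::write.table(drugs, file.path(out_dir, "drug_links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary <- list(
    thresholds = th,
    counts = list(degs_a = nrow(degs_a), degs_b = nrow(degs_b),
                  common = length(ovl$common),
                  same_direction = length(ovl$same_direction),
                  opposite_direction = length(ovl$opposite_direction),
                  hotspots_a = nrow(hs_a), hotspots_b = nrow(hs_b),
                  hotspot_overlaps = nrow(hs_ovl),
                  shared_overconnected = length(shared_over),
                  expanded_nodes = length(expanded$nodes),
                  enriched_sets = sum(enr$q <= th$q_max_enrich),
                  qpcr_genes = if (is.null(qp)) 0L else nrow(qp$summary),
                  candidates = nrow(scores),
                  membrane_receptors = length(receptors),
                  drug_links = nrow(drugs)),
    top_candidate = if (nrow(scores)) scores$gene[1] else NA_character_,
    membrane_receptors = receptors)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
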