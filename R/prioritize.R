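# Multi-criterion drug-target triage. Each candidate gene is scored against
# seven boolean criteria assembled from the upstream evidence tables:
#   (a) DEG in both tissues            (cross-tissue overlap)
#   (b) qPCR-concordant                (sign agreement with the microarray FC)
#   (c) member of >= 1 enriched set    (BH q <= q_max)
#   (d) over-connected in both tissues (p <= p_max against each DEG set)
#   (e) network hub                    (top quantile of expanded-subnetwork degree)
#   (f) inside an overlapping cross-tissue hot spot
#   (g) targeted by >= 1 drug
# The checklist-to-score formalization (score = count of true criteria,
# ranked by score, then mean over-connectivity z, then symbol) is this
# package's addition; absent evidence channels evaluate to FALSE and are
# flagged as not evaluated rather than silently passing.

criteria_names <- c("a_deg_both", "b_qpcr_concordant", "c_enriched",
                    "d_overconnected_both", "e_hub", "f_hotspot_overlap",
                    "g_drug_target")

#' Score candidate genes against the seven triage criteria
#'
#' @param overlap an `OverlapReport` from [overlap_profiles()] (required);
#'   default candidates are its `common` genes.
#' @param degs_a,degs_b the per-tissue DEG tables (used for qPCR concordance
#'   directions).
#' @param qpcr optional `FoldChangeResult`; concordance compares the sign of
#'   the qPCR case/control mean ratio with the microarray direction in
#'   `qpcr_tissue` (no significance gate, matching the use of expression
#'   trends as confirmation).
#' @param enrichment optional [enrich()] output; criterion (c) is membership
#'   in the overlap of any set with `q <= q_max`.
#' @param conn_a,conn_b optional unfiltered [overconnected_genes()] outputs
#'   (one per tissue DEG set); criterion (d) requires `p <= p_max_conn` in
#'   both.
#' @param hubs optional [hub_rank()] output for the expanded subnetwork;
#'   criterion (e) is degree at or above the `hub_quantile` quantile.
#' @param hotspot_overlap optional [overlap_hotspots()] output; criterion (f)
#'   is membership in any pair's `shared_genes`.
#' @param annotations optional `ProteinAnnotation`; criterion (g) is >= 1
#'   drug link.
#' @param candidates candidate symbols (default: cross-tissue common DEGs).
#' @param qpcr_tissue which DEG table carries the microarray direction to
#'   compare qPCR against: `"b"` (default) or `"a"`.
#' @param q_max BH threshold for criterion (c), default 0.05.
#' @param p_max_conn over-connectivity threshold for criterion (d), default
#'   0.05.
#' @param hub_quantile degree quantile defining a hub, default 0.9 (top
#'   decile).
#' @return data.frame with one row per candidate: the seven criterion
#'   columns, `score`, `mean_z`, `rank`, and `n_evaluated` (how many evidence
#'   channels were supplied); sorted by rank. Attribute `evaluated` records
#'   which channels were present.
#' @export
score_candidates <- function(overlap, degs_a = NULL, degs_b = NULL,
                             qpcr = NULL, enrichment = NULL,
                             conn_a = NULL, conn_b = NULL, hubs = NULL,
                             hotspot_overlap = NULL, annotations = NULL,
                             candidates = NULL, qpcr_tissue = c("b", "a"),
                             q_max = 0.05, p_max_conn = 0.05,
                             hub_quantile = 0.9) {
  qpcr_tissue <- match.arg(qpcr_tissue)
  if (!inherits(overlap, "OverlapReport")) {
    abort_domain("overlap must be an OverlapReport")
  }
  candidates <- if (is.null(candidates)) overlap$common
                else unique(canonical_symbol(candidates))
  crit <- matrix(FALSE, nrow = length(candidates), ncol = 7,
                 dimnames = list(candidates, criteria_names))

  crit[, "a_deg_both"] <- candidates %in% overlap$common

  if (!is.null(qpcr)) {
    deg_dir <- if (qpcr_tissue == "b") degs_b else degs_a
    if (is.null(deg_dir)) {
      abort_domain("qPCR concordance needs the matching tissue DEG table")
    }
    dirs <- stats::setNames(deg_dir$direction, deg_dir$gene)
    s <- qpcr$summary
    qdir <- stats::setNames(ifelse(s$case_mean >= s$control_mean, "UP", "DOWN"),
                            s$gene)
    both <- candidates[candidates %in% names(qdir) &
                         candidates %in% names(dirs)]
    crit[both, "b_qpcr_concordant"] <- qdir[both] == dirs[both]
  }

  if (!is.null(enrichment)) {
    sig <- enrichment[enrichment$q <= q_max, , drop = FALSE]
    enriched_genes <- unique(unlist(sig$overlap, use.names = FALSE))
    crit[, "c_enriched"] <- candidates %in% enriched_genes
  }

  if (!is.null(conn_a) && !is.null(conn_b)) {
    sig_a <- conn_a$gene[conn_a$p <= p_max_conn]
    sig_b <- conn_b$gene[conn_b$p <= p_max_conn]
    crit[, "d_overconnected_both"] <- candidates %in% intersect(sig_a, sig_b)
  }

  if (!is.null(hubs)) {
    cutoff <- stats::quantile(hubs$degree, hub_quantile, names = FALSE)
    hub_genes <- hubs$gene[hubs$degree >= cutoff]
    crit[, "e_hub"] <- candidates %in% hub_genes
  }

  if (!is.null(hotspot_overlap)) {
    shared <- unique(unlist(hotspot_overlap$shared_genes, use.names = FALSE))
    crit[, "f_hotspot_overlap"] <- candidates %in% shared
  }

  if (!is.null(annotations)) {
    crit[, "g_drug_target"] <- candidates %in% unique(annotations$drugs$gene)
  }

  evaluated <- c(a_deg_both = TRUE,
                 b_qpcr_concordant = !is.null(qpcr),
                 c_enriched = !is.null(enrichment),
                 d_overconnected_both = !is.null(conn_a) && !is.null(conn_b),
                 e_hub = !is.null(hubs),
                 f_hotspot_overlap = !is.null(hotspot_overlap),
                 g_drug_target = !is.null(annotations))

  z_tab <- function(conn) {
    if (is.null(conn)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(conn$z, conn$gene)
  }
  za <- z_tab(conn_a); zb <- z_tab(conn_b)
  mean_z <- vapply(candidates, function(g) {
    zs <- c(za[g], zb[g])
    zs <- zs[is.finite(zs)]
    if (length(zs)) mean(zs) else -Inf
  }, numeric(1))

  out <- data.frame(gene = candidates, crit, score = rowSums(crit),
                    mean_z = unname(mean_z), stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  ord <- order(-out$score, -out$mean_z, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$n_evaluated <- sum(evaluated)
  rownames(out) <- NULL
  attr(out, "evaluated") <- evaluated
  out
}

#' Restrict genes to membrane-localized receptors
#'
#' Keeps genes annotated as protein class `receptor` with
#' `membrane_localized = TRUE` (the conjunction is required: an intracellular
#' receptor is excluded). Unannotated genes are excluded with a warning.
#'
#' @param genes character vector of symbols.
#' @param annotations a `ProteinAnnotation`.
#' @return character vector, sorted.
#' @export
filter_receptors <- function(genes, annotations) {
  genes <- unique(canonical_symbol(genes))
  cls <- annotations$classes
  unknown <- setdiff(genes, cls$gene)
  if (length(unknown)) {
    warning(length(unknown), " unannotated gene(s) excluded: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- cls$gene[cls$protein_class == "receptor" & cls$membrane_localized]
  sort(intersect(genes, keep))
}

#' Flatten drug links for a gene list
#'
#' @param genes character vector of symbols.
#' @param annotations a `ProteinAnnotation`.
#' @return data.frame with columns `gene`, `drug`, `stage`, deduplicated; 0
#'   rows for genes without links.
#' @export
attach_drugs <- function(genes, annotations) {
  genes <- unique(canonical_symbol(genes))
  rows <- annotations$drugs[annotations$drugs$gene %in% genes, , drop = FALSE]
  rows <- rows[!duplicated(rows), , drop = FALSE]
  rows <- rows[order(rows$gene, rows$drug), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
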