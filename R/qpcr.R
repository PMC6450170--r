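# Relative quantification from qPCR cycle thresholds by the 2^-ddCt method:
# technical replicates are averaged on the Ct scale, each sample is
# normalized against its housekeeping gene (dCt), expression is expressed
# relative to one control sample taken as unity (2^-ddCt), and the case vs
# control comparison is tested on the dCt scale, where the noise is
# approximately additive.

#' Housekeeping-normalized Ct differences
#'
#' Averages technical replicates on the Ct scale, then computes
#' `dCt(sample, gene) = mean Ct(sample, gene) - mean Ct(sample, housekeeping)`.
#' (Sample, gene) pairs with no target measurement are omitted with a warning
#' when another sample has them.
#'
#' @param ct a `CtTable` from [read_ct_table()] or [ct_table()].
#' @return data.frame with columns `sample`, `gene`, `delta_ct`.
#' @export
delta_ct <- function(ct) {
  d <- ct$data
  agg <- stats::aggregate(ct ~ sample + gene, data = d, FUN = mean)
  hk <- agg[agg$gene == ct$housekeeping, c("sample", "ct")]
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  tgt <- agg[agg$gene != ct$housekeeping, , drop = FALSE]
  out <- data.frame(sample = tgt$sample, gene = tgt$gene,
                    delta_ct = tgt$ct - unname(hk_ct[tgt$sample]),
                    stringsAsFactors = FALSE)
  expected <- expand.grid(sample = unique(d$sample),
                          gene = setdiff(unique(d$gene), ct$housekeeping),
                          stringsAsFactors = FALSE)
  miss <- nrow(expected) - nrow(out)
  if (miss > 0) {
    warning(miss, " (sample, gene) measurement(s) missing; omitted")
  }
  out[order(out$gene, out$sample), , drop = FALSE]
}

#' Relative expression and group summaries by the 2^-ddCt method
#'
#' For each gene, `ddCt(s) = dCt(s) - dCt(reference)` and relative expression
#' `2^-ddCt(s)` (reference sample = 1 exactly). Group means and standard
#' errors are computed on the 2^-ddCt scale; the case-vs-control p-value is
#' from Welch's two-sided t-test on the dCt values.
#'
#' @param delta_cts output of [delta_ct()].
#' @param reference_sample sample whose relative expression defines unity.
#' @param groups named character vector sample -> `case`/`control`.
#' @return list of class `FoldChangeResult` with elements `summary`
#'   (data.frame gene, control_mean, control_sem, case_mean, case_sem, p) and
#'   `per_sample` (data.frame sample, gene, group, rel_expr).
#' @export
fold_changes <- function(delta_cts, reference_sample, groups) {
  per_gene <- split(delta_cts, delta_cts$gene)
  per_sample <- list()
  summary_rows <- list()
  for (g in names(per_gene)) {
    dg <- per_gene[[g]]
    ref <- dg$delta_ct[dg$sample == reference_sample]
    if (!length(ref)) {
      abort_validation("reference sample ", reference_sample,
                       " has no dCt for gene ", g)
    }
    rel <- 2^(-(dg$delta_ct - ref))
    grp <- unname(groups[dg$sample])
    per_sample[[g]] <- data.frame(sample = dg$sample, gene = g, group = grp,
                                  rel_expr = rel, stringsAsFactors = FALSE)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    ca <- dg$delta_ct[grp == "case"]
    co <- dg$delta_ct[grp == "control"]
    p <- if (length(ca) >= 2 && length(co) >= 2) test_gene(ca, co)$p
         else NA_real_
    summary_rows[[g]] <- data.frame(
      gene = g,
      control_mean = mean(rel[grp == "control"]),
      control_sem = sem(rel[grp == "control"]),
      case_mean = mean(rel[grp == "case"]),
      case_sem = sem(rel[grp == "case"]),
      p = p, stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 per_sample = do.call(rbind, c(per_sample,
                                               list(make.row.names = FALSE)))),
            class = "FoldChangeResult")
}

#' Run the full qPCR quantification for a Ct table
#'
#' Convenience wrapper: [delta_ct()] then [fold_changes()] with the table's
#' configured reference sample and groups.
#'
#' @param ct a `CtTable`.
#' @return a `FoldChangeResult`.
#' @export
qpcr_fold_changes <- function(ct) {
  fold_changes(delta_ct(ct), ct$reference_sample, ct$groups)
}

#' @export
print.FoldChangeResult <- function(x, ...) {
  cat("FoldChangeResult for", nrow(x$summary), "gene(s)\n")
  print(x$summary)
  invisible(x)
}
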