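# Two-group differential expression on log2 intensities. The gates mirror the
# study design: a deliberately permissive first filter (p <= 0.05, |FC| >= 1.1,
# no multiplicity correction) so that downstream high-stringency statistics
# (hot spots, over-connectivity) operate on a large significant pool.

# Vectorized Welch (unequal-variance) two-sample t-test over matrix rows.
# Returns the signed linear fold change alongside the two-sided p-value.
welch_rows <- function(x, idx_a, idx_b) {
  a <- x[, idx_a, drop = FALSE]
  b <- x[, idx_b, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    # zero variance in both groups: identical means -> null, else certainty
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  }
  d <- m1 - m2
  fc <- ifelse(d >= 0, 2^d, -(2^(-d)))
  list(fc = unname(fc), p = unname(p), delta_log2 = unname(d))
}

#' Test one gene for differential expression between two groups
#'
#' Welch's unequal-variance two-sample t-test on log2 values, with the fold
#' change reported as a signed linear ratio: for mean log2 difference
#' `d = mean(a) - mean(b)`, `fc = 2^d` when `d >= 0` and `-(2^-d)` otherwise,
#' so down-regulation appears as a negative reciprocal and no value lies
#' strictly between -1 and 1.
#'
#' @param values_a,values_b numeric vectors of log2 intensities (>= 2 finite
#'   values each).
#' @return list with elements `fc` (signed linear fold change) and `p`
#'   (two-sided p-value).
#' @examples
#' test_gene(c(5, 5.1, 4.9), c(4, 4.1, 3.9))
#' @export
test_gene <- function(values_a, values_b) {
  for (v in list(values_a, values_b)) {
    if (length(v) < 2 || !all(is.finite(v))) {
      abort_domain("each group needs at least 2 finite log2 values")
    }
  }
  res <- welch_rows(rbind(c(values_a, values_b)),
                    seq_along(values_a),
                    length(values_a) + seq_along(values_b))
  list(fc = res$fc, p = res$p)
}

#' Apply the DEG gates to a table of fold changes and p-values
#'
#' Thresholds are closed: a record at exactly `p == p_max` and
#' `|fc| == fc_min` is retained. Direction is UP iff `fc >= 1`.
#'
#' @param records data.frame with numeric columns `fc` and `p`.
#' @param p_max maximum p-value (default 0.05).
#' @param fc_min minimum absolute linear fold change (default 1.1).
#' @return the retained rows with a `direction` column, sorted by `p`.
#' @export
gate_degs <- function(records, p_max = 0.05, fc_min = 1.1) {
  if (p_max <= 0 || fc_min <= 0) abort_domain("thresholds must be positive")
  keep <- records$p <= p_max & abs(records$fc) >= fc_min
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$fc >= 1, "UP", "DOWN")
  out <- out[order(out$p, -abs(out$fc), out$gene %||% seq_len(nrow(out))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed genes from an expression matrix
#'
#' Tests every row with [test_gene()]'s statistic, collapses probes to one
#' record per gene symbol (smallest p; ties: larger |fc|, then
#' lexicographically first probe id) and applies the closed gates
#' `p <= p_max`, `|fc| >= fc_min`.
#'
#' @param em an [expression_matrix()].
#' @param case_group,control_group group labels; fold change is case over
#'   control.
#' @param p_max,fc_min gate thresholds (defaults 0.05 and 1.1).
#' @param tissue label recorded on every output row.
#' @return data.frame with columns `gene`, `probe`, `fc`, `p`, `direction`,
#'   `tissue`, sorted by p ascending.
#' @export
call_degs <- function(em, case_group, control_group,
                      p_max = 0.05, fc_min = 1.1, tissue = NA_character_) {
  if (!inherits(em, "ExpressionMatrix")) {
    abort_domain("em must be an ExpressionMatrix")
  }
  for (g in c(case_group, control_group)) {
    if (!g %in% em$groups) abort_domain("unknown group label: ", g)
  }
  idx_a <- which(em$groups == case_group)
  idx_b <- which(em$groups == control_group)
  res <- welch_rows(em$values, idx_a, idx_b)
  probes <- rownames(em$values)
  genes <- if (is.null(em$probe_to_gene)) canonical_symbol(probes)
           else canonical_symbol(em$probe_to_gene[probes])
  if (anyNA(genes)) {
    abort_validation("probe missing from probe_to_gene map: ",
                     probes[is.na(genes)][1])
  }
  tab <- data.frame(gene = genes, probe = probes, fc = res$fc, p = res$p,
                    stringsAsFactors = FALSE)
  # probe collapse: smallest p, then larger |fc|, then first probe id
  tab <- tab[order(tab$gene, tab$p, -abs(tab$fc), tab$probe), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  out <- gate_degs(tab, p_max = p_max, fc_min = fc_min)
  out$tissue <- tissue
  out[, c("gene", "probe", "fc", "p", "direction", "tissue")]
}
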