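# Gene-set over-representation: one-sided hypergeometric test of a DEG list
# against each set of a collection, conditioned on the platform universe, with
# Benjamini-Hochberg adjustment across the tested sets. The up/down
# composition of each overlap is reported alongside.

#' Over-representation analysis of a DEG list against a gene-set collection
#'
#' For each set S, with universe U, DEG list D and overlap k = |D & S & U|,
#' `p = P(X >= k)` where `X ~ Hypergeometric(|U|, |S & U|, |D & U|)`.
#' One-sided (over-representation) only. q-values are Benjamini-Hochberg
#' across all tested sets.
#'
#' @param degs either a character vector of DEG symbols or a data.frame with
#'   columns `gene` and `direction` (enables the `k_up`/`k_down` breakdown).
#'   DEGs outside the universe are dropped with a warning.
#' @param collection a `GeneSetCollection` from [read_gene_sets()].
#' @param universe character vector of platform genes (non-empty).
#' @return data.frame with columns `set`, `description`, `n_set`, `k`,
#'   `k_up`, `k_down`, `p`, `q` and a list column `overlap`, sorted by p.
#' @export
enrich <- function(degs, collection, universe) {
  universe <- unique(canonical_symbol(universe))
  if (!length(universe)) abort_domain("universe is empty")
  if (is.data.frame(degs)) {
    genes <- canonical_symbol(degs$gene)
    directions <- stats::setNames(degs$direction, genes)
  } else {
    genes <- unique(canonical_symbol(degs))
    directions <- stats::setNames(rep(NA_character_, length(genes)), genes)
  }
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(length(outside), " DEG(s) outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  U <- length(universe)
  nD <- length(genes)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    ov <- sort(intersect(genes, members))
    k <- length(ov)
    p <- stats::phyper(k - 1, length(members), U - length(members), nD,
                       lower.tail = FALSE)
    dirs <- directions[ov]
    data.frame(set = nm, description = collection$descriptions[[nm]],
               n_set = length(members), k = k,
               k_up = sum(dirs == "UP", na.rm = TRUE),
               k_down = sum(dirs == "DOWN", na.rm = TRUE),
               p = p, overlap = I(list(ov)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set),
             c("set", "description", "n_set", "k", "k_up", "k_down",
               "p", "q", "overlap")]
  rownames(out) <- NULL
  out
}

#' Serialize enrichment results as TSV
#'
#' @param results output of [enrich()].
#' @param path output TSV path.
#' @return `results`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$overlap <- collapse_genes(out$overlap)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
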