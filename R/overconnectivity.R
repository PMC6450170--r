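# Interactome over-connectivity: for a focal gene, is its neighborhood
# enriched in an experimental DEG set beyond what its background degree
# predicts? The null is hypergeometric: the n experimental genes are a random
# draw from the N background genes, of which R are neighbors of the focal
# gene. Conventions (documented, not inferred from any upstream tool): the
# focal gene is excluded from its own n and N; neighbors are the union of in-
# and out-neighbors; self-loops never count; edge direction and effect sign
# are ignored for counting and retained only for display.

# Named list: node -> character vector of distinct neighbors (in or out,
# self excluded). Nodes with no edges map to character(0).
neighbor_list <- function(net) {
  e <- net$edges
  nb <- split(c(e$target, e$source), c(e$source, e$target))
  nb <- lapply(nb, unique)
  empty <- setdiff(net$nodes, names(nb))
  c(nb, stats::setNames(rep(list(character(0)), length(empty)), empty))
}

connectivity_one <- function(neighbors, gene, deg_set, background) {
  nb <- intersect(neighbors, background)
  N <- length(setdiff(background, gene))
  R <- length(setdiff(nb, gene))
  deg <- setdiff(deg_set, gene)
  n <- length(deg)
  Actual <- length(intersect(nb, deg))
  Expected <- if (N > 0) n * R / N else 0
  sd_ <- if (N > 1) sqrt(n * (R / N) * (1 - R / N) * (N - n) / (N - 1)) else 0
  z <- if (sd_ > 0) (Actual - Expected) / sd_
       else if (Actual == Expected) 0 else NaN
  p <- if (n == 0 || R == 0) 1
       else stats::phyper(Actual - 1, R, N - R, n, lower.tail = FALSE)
  data.frame(gene = gene, Actual = Actual, n = n, R = R, N = N,
             Expected = Expected,
             Ratio = if (Expected > 0) Actual / Expected else NA_real_,
             z = z, p = p, stringsAsFactors = FALSE)
}

#' Over-connectivity statistics for one focal gene
#'
#' Computes the record (Actual, n, R, N, Expected, Ratio, z, p): `Actual` is
#' the number of the focal gene's network neighbors inside the experimental
#' set, `n` the experimental-set size, `R` the gene's background degree, `N`
#' the background size (all excluding the focal gene itself), `Expected =
#' n R / N` the hypergeometric mean, `z = (Actual - Expected) / sd` with the
#' hypergeometric standard deviation, and `p = P(X >= Actual)` the upper-tail
#' probability.
#'
#' @param net an [interaction_network()].
#' @param deg_set character vector, the experimental (DEG) gene set; must lie
#'   within `background` (violators are dropped with a warning).
#' @param background character vector of background genes (e.g., network
#'   nodes present on the expression platform).
#' @param gene focal gene symbol; must belong to `background`.
#' @return one-row data.frame with columns `gene`, `Actual`, `n`, `R`, `N`,
#'   `Expected`, `Ratio` (NA when `Expected == 0`), `z`, `p`.
#' @export
connectivity_stats <- function(net, deg_set, background, gene) {
  gene <- canonical_symbol(gene)
  background <- unique(canonical_symbol(background))
  deg_set <- unique(canonical_symbol(deg_set))
  if (!gene %in% background) {
    abort_domain("focal gene ", gene, " is not in the background")
  }
  stray <- setdiff(background, net$nodes)
  if (length(stray)) {
    abort_domain("background gene not in network: ", stray[1])
  }
  outside <- setdiff(deg_set, background)
  if (length(outside)) {
    warning(length(outside), " experimental gene(s) outside the background dropped")
    deg_set <- intersect(deg_set, background)
  }
  nb <- neighbor_list(net)
  connectivity_one(nb[[gene]] %||% character(0), gene, deg_set, background)
}

#' Rank candidate genes by over-connectivity to an experimental set
#'
#' Runs [connectivity_stats()] for every candidate, keeps records with
#' `p <= p_max` and sorts by z descending, ties by p ascending then symbol.
#'
#' @inheritParams connectivity_stats
#' @param candidates genes to score (default: the `deg_set` itself);
#'   candidates outside the background are dropped with a warning.
#' @param p_max significance gate (default 0.05).
#' @return data.frame of retained ConnectivityResult rows, ranked.
#' @export
overconnected_genes <- function(net, deg_set, background,
                                candidates = NULL, p_max = 0.05) {
  background <- unique(canonical_symbol(background))
  deg_set <- unique(canonical_symbol(deg_set))
  stray <- setdiff(background, net$nodes)
  if (length(stray)) {
    abort_domain("background gene not in network: ", stray[1])
  }
  outside <- setdiff(deg_set, background)
  if (length(outside)) {
    warning(length(outside), " experimental gene(s) outside the background dropped")
    deg_set <- intersect(deg_set, background)
  }
  candidates <- if (is.null(candidates)) deg_set
                else unique(canonical_symbol(candidates))
  off <- setdiff(candidates, background)
  if (length(off)) {
    warning(length(off), " candidate(s) outside the background dropped")
    candidates <- intersect(candidates, background)
  }
  nb <- neighbor_list(net)
  rows <- lapply(candidates, function(g) {
    connectivity_one(nb[[g]] %||% character(0), g, deg_set, background)
  })
  out <- do.call(rbind, c(rows, list(connectivity_one(character(0), "ZZZ",
                                                      character(0), "ZZZ")[0, ])))
  out <- out[out$p <= p_max, , drop = FALSE]
  out <- out[order(-out$z, out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-step network expansion around seed genes
#'
#' Augments the seed set with every node one directed edge away in either
#' direction ("auto-expand by one interaction, both up- and downstream") and
#' induces the subnetwork: edges are retained iff both endpoints are in the
#' expanded node set. Seeds absent from the network are reported and skipped.
#'
#' @param net an [interaction_network()].
#' @param seeds character vector of seed symbols.
#' @return an `InteractionNetwork` on the expanded node set.
#' @export
expand_network <- function(net, seeds) {
  seeds <- unique(canonical_symbol(seeds))
  absent <- setdiff(seeds, net$nodes)
  if (length(absent)) {
    warning(length(absent), " seed(s) absent from the network skipped")
    seeds <- intersect(seeds, net$nodes)
  }
  if (!length(seeds)) {
    return(interaction_network(net$edges[0, , drop = FALSE], nodes = character(0)))
  }
  nb <- neighbor_list(net)
  keep <- sort(unique(c(seeds, unlist(nb[seeds], use.names = FALSE))))
  e <- net$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  interaction_network(e, nodes = keep)
}

#' Rank network nodes by total degree
#'
#' Degree is the number of distinct neighbors over in- and out-edges with
#' self-loops excluded, so the handshake identity holds: degrees sum to twice
#' the number of connected node pairs. Ties break alphabetically.
#'
#' @param net a non-empty `InteractionNetwork`.
#' @return data.frame with columns `gene` and `degree`, descending.
#' @export
hub_rank <- function(net) {
  if (!length(net$nodes)) abort_domain("network has no nodes")
  nb <- neighbor_list(net)
  deg <- vapply(net$nodes, function(g) length(nb[[g]] %||% character(0)),
                integer(1))
  out <- data.frame(gene = net$nodes, degree = unname(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
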