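# Chromosomal "hot spot" scan: stretches of consecutive genes along a
# chromosome that contain more DEGs than a random draw from the platform
# would predict. The null is a hypergeometric draw of w consecutive genes
# from a platform of G genes carrying K DEGs; every candidate stretch whose
# first and last genes are DEGs is evaluated (any significant stretch trims
# to such a run without losing DEGs), significant runs are merged when they
# overlap or are book-ended, and the best constituent window's (w, k, p) is
# reported per merged hot spot.

#' Hypergeometric upper-tail p-value for a window of genes
#'
#' Probability of observing at least `k` DEGs among `w` consecutive genes when
#' `K` DEGs are scattered over a platform of `G` genes:
#' `P(X >= k)` with `X ~ Hypergeometric(G, K, w)`. Vectorized over its
#' arguments.
#'
#' @param w window size in genes.
#' @param k DEG count in the window.
#' @param K total DEGs mapped on the platform.
#' @param G total genes on the platform.
#' @return upper-tail probability; `1` when `k == 0`.
#' @examples
#' window_pvalue(4, 4, 5, 10)  # 5 / choose(10, 4)
#' @export
window_pvalue <- function(w, k, K, G) {
  n <- max(length(w), length(k), length(K), length(G))
  w <- rep_len(w, n); k <- rep_len(k, n)
  K <- rep_len(K, n); G <- rep_len(G, n)
  if (any(k < 0 | w < k | G < w | K < k | G < K)) {
    abort_domain("require 0 <= k <= w <= G and k <= K <= G")
  }
  stats::phyper(k - 1, K, G - K, w, lower.tail = FALSE)
}

# Order a gene map into the canonical genome layout: within each chromosome
# strictly by (start, end, symbol); both strands share one positional order.
genome_layout <- function(gene_map) {
  map <- gene_map[!duplicated(gene_map$gene), , drop = FALSE]
  map[order(map$chrom, map$start, map$end, map$gene), , drop = FALSE]
}

#' Scan a genome layout for DEG hot spots
#'
#' Evaluates, per chromosome, every contiguous run of consecutive genes whose
#' first and last members are DEGs; keeps runs with at least `min_degs` DEGs
#' and [window_pvalue()] at most `p_max`; merges overlapping or book-ended
#' significant runs into maximal hot spots. DEG symbols absent from the map
#' are reported via the `unmapped` attribute (and a message), never silently
#' dropped.
#'
#' @param gene_map data.frame as from [read_gene_map()]; the platform
#'   universe `G` is the number of distinct mapped genes.
#' @param deg_genes character vector of DEG symbols.
#' @param min_degs minimum DEG count per stretch (default 5).
#' @param p_max scan significance gate (default 0.001).
#' @return data.frame of hot spots with columns `chromosome`, `start`, `end`
#'   (bp span of member genes, half-open), `n_genes`, `n_degs`, `w`, `k`, `p`
#'   (best constituent window) and list columns `genes`, `deg_genes`; ordered
#'   by (chromosome, start). Attribute `unmapped` lists DEGs missing from the
#'   map; attributes `G` and `K` record the null's totals.
#' @export
scan_hotspots <- function(gene_map, deg_genes, min_degs = 5, p_max = 0.001) {
  deg_genes <- unique(canonical_symbol(deg_genes))
  layout <- genome_layout(gene_map)
  G <- nrow(layout)
  unmapped <- setdiff(deg_genes, layout$gene)
  if (length(unmapped)) {
    message(length(unmapped), " DEG(s) not present in the gene map")
  }
  K <- sum(layout$gene %in% deg_genes)

  spots <- list()
  for (chrom in unique(layout$chrom)) {
    sub <- layout[layout$chrom == chrom, , drop = FALSE]
    is_deg <- sub$gene %in% deg_genes
    pos <- which(is_deg)
    m <- length(pos)
    if (m < min_degs) next
    # all DEG-endpoint runs with at least min_degs DEGs, vectorized
    ij <- which(outer(seq_len(m), seq_len(m),
                      function(i, j) j - i + 1L >= min_degs & j >= i),
                arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    w <- pos[j] - pos[i] + 1L
    k <- j - i + 1L
    p <- window_pvalue(w, k, K, G)
    sig <- which(p <= p_max)
    if (!length(sig)) next
    runs <- data.frame(lo = pos[i[sig]], hi = pos[j[sig]],
                       w = w[sig], k = k[sig], p = p[sig])
    runs <- runs[order(runs$lo, runs$hi), , drop = FALSE]
    # merge overlapping or book-ended (gene-adjacent) significant runs
    grp <- integer(nrow(runs)); grp[1] <- 1L; hi <- runs$hi[1]
    for (r in seq_len(nrow(runs))[-1]) {
      if (runs$lo[r] <= hi + 1L) {
        grp[r] <- grp[r - 1L]
        hi <- max(hi, runs$hi[r])
      } else {
        grp[r] <- grp[r - 1L] + 1L
        hi <- runs$hi[r]
      }
    }
    for (g in unique(grp)) {
      block <- runs[grp == g, , drop = FALSE]
      lo <- min(block$lo); hi2 <- max(block$hi)
      best <- block[which.min(block$p), ]
      members <- sub$gene[lo:hi2]
      spots[[length(spots) + 1L]] <- data.frame(
        chromosome = chrom,
        start = sub$start[lo], end = sub$end[hi2],
        n_genes = hi2 - lo + 1L, n_degs = sum(is_deg[lo:hi2]),
        w = best$w, k = best$k, p = best$p,
        genes = I(list(members)),
        deg_genes = I(list(members[members %in% deg_genes])),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(spots)) do.call(rbind, spots)
         else data.frame(chromosome = character(0), start = numeric(0),
                         end = numeric(0), n_genes = integer(0),
                         n_degs = integer(0), w = integer(0), k = integer(0),
                         p = numeric(0), genes = I(list()),
                         deg_genes = I(list()))
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  attr(out, "G") <- G
  attr(out, "K") <- K
  out
}

#' Intersect hot spots from two tissues
#'
#' Pairs of hot spots on the same chromosome whose base-pair spans intersect
#' by at least 1 bp under half-open semantics; `[100,200)` and `[200,300)` do
#' not overlap.
#'
#' @param hotspots_a,hotspots_b outputs of [scan_hotspots()] on the same
#'   genome build.
#' @return data.frame with one row per overlapping pair: `chromosome`,
#'   `start_a`, `end_a`, `start_b`, `end_b` and a list column `shared_genes`
#'   (the DEG symbols common to the paired hot spots).
#' @export
overlap_hotspots <- function(hotspots_a, hotspots_b) {
  rows <- list()
  for (i in seq_len(nrow(hotspots_a))) {
    a <- hotspots_a[i, ]
    cand <- which(hotspots_b$chromosome == a$chromosome &
                    hotspots_b$start < a$end & a$start < hotspots_b$end)
    for (j in cand) {
      b <- hotspots_b[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = a$chromosome,
        start_a = a$start, end_a = a$end,
        start_b = b$start, end_b = b$end,
        shared_genes = I(list(sort(intersect(a$deg_genes[[1]],
                                             b$deg_genes[[1]])))),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chromosome = character(0), start_a = numeric(0),
                         end_a = numeric(0), start_b = numeric(0),
                         end_b = numeric(0), shared_genes = I(list()))
  rownames(out) <- NULL
  out
}

#' Serialize hot spots as TSV (list columns comma-joined)
#'
#' @param hotspots output of [scan_hotspots()].
#' @param path output TSV path.
#' @return `hotspots`, invisibly.
#' @export
write_hotspots <- function(hotspots, path) {
  out <- hotspots
  out$genes <- collapse_genes(out$genes)
  out$deg_genes <- collapse_genes(out$deg_genes)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hotspots)
}

#' Read hot spots written by [write_hotspots()]
#'
#' @param path TSV path.
#' @return hot-spot data.frame with restored list columns.
#' @export
read_hotspots <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  df$genes <- I(split_genes(df$genes))
  df$deg_genes <- I(split_genes(df$deg_genes))
  df
}
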