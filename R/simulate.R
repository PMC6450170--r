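# Seeded generators for every input type, with the planted truth returned
# alongside. Defaults encode the validation design the pipeline is tested
# against: two groups of 5 log2-scale samples, a planted DEG effect of 1 log2
# unit with sigma = 0.25, qPCR with 5 + 5 biological replicates in technical
# duplicate with sigma = 0.3 Ct cycles, and a background interactome of mean
# degree 10. Noise is Gaussian on the log2 / Ct scale (an idealization of
# microarray and qPCR error). All generators are bit-reproducible from
# (parameters, seed).

gene_names <- function(G) sprintf("G%05d", seq_len(G))

#' Simulate a two-group log2 expression matrix with planted DEGs
#'
#' Gene baselines are uniform on log2 4..12; planted DEGs shift the case-group
#' mean by `+effect_log2` (first half, UP) or `-effect_log2` (second half,
#' DOWN); Gaussian noise of sd `noise_sd` is added to every cell.
#'
#' @param G number of genes (default 2000).
#' @param n_case,n_control samples per group (default 5 each).
#' @param deg_fraction fraction of genes planted as DEGs (default 0.1);
#'   ignored when `deg_genes` is given.
#' @param effect_log2 absolute planted effect in log2 units (default 1).
#' @param noise_sd log2-scale noise sd (default 0.25).
#' @param seed RNG seed.
#' @param deg_genes optional explicit character vector of genes to plant
#'   (must be a subset of the generated names).
#' @param up_genes optional subset of `deg_genes` forced UP (the rest are
#'   DOWN); default: first half UP.
#' @return list with elements `matrix` (an [expression_matrix()]) and `truth`
#'   (list: `deg_genes`, named `effects` in log2 units).
#' @export
simulate_expression <- function(G = 2000, n_case = 5, n_control = 5,
                                deg_fraction = 0.1, effect_log2 = 1,
                                noise_sd = 0.25, seed = 1,
                                deg_genes = NULL, up_genes = NULL) {
  if (G < 1 || n_case < 2 || n_control < 2) {
    abort_domain("need G >= 1 and at least 2 samples per group")
  }
  if (deg_fraction < 0 || deg_fraction > 1) {
    abort_domain("deg_fraction must be in [0, 1]")
  }
  if (effect_log2 < 0 || noise_sd < 0) {
    abort_domain("effect_log2 and noise_sd must be non-negative")
  }
  set.seed(seed)
  genes <- gene_names(G)
  if (is.null(deg_genes)) {
    n_deg <- round(G * deg_fraction)
    deg_genes <- sort(sample(genes, n_deg))
  } else {
    deg_genes <- sort(canonical_symbol(deg_genes))
    if (!all(deg_genes %in% genes)) {
      abort_domain("deg_genes must be among the generated gene names")
    }
  }
  if (is.null(up_genes)) {
    up_genes <- deg_genes[seq_len(ceiling(length(deg_genes) / 2))]
  }
  effects <- stats::setNames(rep(0, G), genes)
  effects[deg_genes] <- ifelse(deg_genes %in% up_genes,
                               effect_log2, -effect_log2)
  baseline <- stats::runif(G, 4, 12)
  samples <- c(sprintf("CASE%02d", seq_len(n_case)),
               sprintf("CTRL%02d", seq_len(n_control)))
  groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                            samples)
  mu <- outer(baseline, rep(1, n_case + n_control)) +
    outer(effects, c(rep(1, n_case), rep(0, n_control)))
  vals <- mu + matrix(stats::rnorm(G * (n_case + n_control), sd = noise_sd),
                      nrow = G)
  dimnames(vals) <- list(genes, samples)
  list(matrix = expression_matrix(vals, groups),
       truth = list(deg_genes = deg_genes, effects = effects[deg_genes]))
}

#' Simulate a gene map with planted positional DEG clusters
#'
#' Genes are laid out on `n_chromosomes` chromosomes in ascending
#' non-overlapping intervals (10 kb spacing, 5 kb gene width). Each cluster
#' spec plants the requested number of DEG symbols at positions drawn inside
#' a window of consecutive ordinals; remaining DEGs are scattered uniformly
#' over the unused positions.
#'
#' @param G total genes; gene names follow [simulate_expression()].
#' @param n_chromosomes chromosome count (default 4); genes are split evenly.
#' @param cluster_spec list of `list(chrom =, start_ordinal =, size =,
#'   n_deg =)` entries (ordinals are within-chromosome, 1-based).
#' @param deg_set character vector of DEG symbols to place.
#' @param seed RNG seed.
#' @return list with elements `map` (BED-convention data.frame) and `truth`
#'   (list of planted clusters, each with `chrom`, `ordinals`, `genes`).
#' @export
simulate_genome_map <- function(G, n_chromosomes = 4, cluster_spec = list(),
                                deg_set = character(0), seed = 1) {
  set.seed(seed)
  genes <- gene_names(G)
  deg_set <- sort(intersect(canonical_symbol(deg_set), genes))
  chrom_of <- rep(sprintf("chr%d", seq_len(n_chromosomes)),
                  length.out = G)[order(rep(seq_len(n_chromosomes),
                                            length.out = G))]
  # slot index: position along the full layout (chromosomes concatenated)
  chrom_sizes <- table(factor(chrom_of, levels = unique(chrom_of)))
  slot_chrom <- rep(names(chrom_sizes), chrom_sizes)
  within <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)

  assignment <- rep(NA_character_, G)
  used_degs <- character(0)
  truth <- list()
  for (cs in cluster_spec) {
    rows <- which(slot_chrom == cs$chrom & within >= cs$start_ordinal &
                    within < cs$start_ordinal + cs$size)
    if (length(rows) < cs$size) {
      abort_domain("cluster on ", cs$chrom, " exceeds chromosome capacity")
    }
    if (any(!is.na(assignment[rows]))) {
      abort_domain("overlapping cluster specs on ", cs$chrom)
    }
    avail <- setdiff(deg_set, used_degs)
    if (length(avail) < cs$n_deg) {
      abort_domain("not enough unplaced DEGs for cluster on ", cs$chrom)
    }
    picked <- avail[seq_len(cs$n_deg)]
    # anchor the run at DEG endpoints so the planted k-of-size window exists
    inner <- if (cs$n_deg > 2 && cs$size > cs$n_deg) {
      sort(sample(rows[-c(1, length(rows))], cs$n_deg - 2))
    } else if (cs$n_deg > 2) rows[2:(cs$n_deg - 1)] else integer(0)
    deg_rows <- unique(c(rows[1], inner, rows[length(rows)]))[seq_len(cs$n_deg)]
    assignment[deg_rows] <- picked
    filler_rows <- setdiff(rows, deg_rows)
    used_degs <- c(used_degs, picked)
    truth[[length(truth) + 1L]] <- list(chrom = cs$chrom,
                                        ordinals = range(within[deg_rows]),
                                        genes = picked)
    # non-DEG filler for the remaining window slots is assigned later
  }
  remaining_degs <- setdiff(deg_set, used_degs)
  free <- which(is.na(assignment))
  deg_slots <- sort(sample(free, length(remaining_degs)))
  assignment[deg_slots] <- remaining_degs
  free <- which(is.na(assignment))
  assignment[free] <- sample(setdiff(genes, c(used_degs, remaining_degs)))

  start <- (within - 1L) * 10000
  map <- data.frame(gene = assignment, chrom = slot_chrom,
                    start = start, end = start + 5000,
                    strand = sample(c("+", "-"), G, replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  list(map = map, truth = list(clusters = truth))
}

#' Simulate an interaction network with planted over-connected hubs
#'
#' A background Erdos-Renyi graph with the requested mean total degree; each
#' planted hub additionally gains edges to uniformly chosen members of
#' `deg_set`. Edge directions and effect signs are assigned at random (they
#' are cosmetic for connectivity counting but exercise the readers).
#'
#' @param G node count; node names follow [simulate_expression()].
#' @param mean_degree mean total (undirected) degree of the background graph
#'   (default 10).
#' @param hub_spec list of `list(gene =, n_deg_edges =)` entries.
#' @param deg_set character vector of experimental genes the hubs wire into.
#' @param seed RNG seed.
#' @return list with elements `network` (an [interaction_network()]) and
#'   `truth` (list: `hubs`).
#' @export
simulate_network <- function(G, mean_degree = 10, hub_spec = list(),
                             deg_set = character(0), seed = 1) {
  set.seed(seed)
  nodes <- gene_names(G)
  deg_set <- intersect(canonical_symbol(deg_set), nodes)
  m <- round(G * mean_degree / 2)
  if (m > choose(G, 2)) abort_domain("requested mean degree exceeds simple-graph capacity")
  # sample m distinct unordered pairs by rejection
  pairs <- matrix(integer(0), ncol = 2)
  while (nrow(pairs) < m) {
    need <- m - nrow(pairs)
    i <- sample.int(G, 2 * need + 10, replace = TRUE)
    j <- sample.int(G, 2 * need + 10, replace = TRUE)
    ok <- i != j
    cand <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
    pairs <- unique(rbind(pairs, cand))
  }
  pairs <- pairs[seq_len(m), , drop = FALSE]
  hub_rows <- list()
  for (hs in hub_spec) {
    hub_idx <- match(canonical_symbol(hs$gene), nodes)
    if (is.na(hub_idx)) abort_domain("hub gene not among generated nodes")
    targets <- match(sample(deg_set, hs$n_deg_edges), nodes)
    hub_rows[[length(hub_rows) + 1L]] <-
      cbind(pmin(hub_idx, targets), pmax(hub_idx, targets))
  }
  if (length(hub_rows)) {
    pairs <- unique(rbind(pairs, do.call(rbind, hub_rows)))
  }
  flip <- stats::runif(nrow(pairs)) < 0.5
  src <- ifelse(flip, pairs[, 2], pairs[, 1])
  tgt <- ifelse(flip, pairs[, 1], pairs[, 2])
  effect <- sample(c("positive", "negative", "unspecified"),
                   nrow(pairs), replace = TRUE)
  net <- interaction_network(
    data.frame(source = nodes[src], target = nodes[tgt], effect = effect,
               stringsAsFactors = FALSE),
    nodes = nodes)
  list(network = net,
       truth = list(hubs = vapply(hub_spec, function(h)
         canonical_symbol(h$gene), character(1))))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The housekeeping gene (ACTB) sits at a constant base Ct across samples up
#' to noise; each target gene's Ct is lowered by `log2(planted_fc)` cycles in
#' case samples (one cycle = factor 2). Every (sample, gene) measurement is
#' run in technical duplicate with independent Gaussian Ct noise.
#'
#' @param planted_fc named numeric vector of linear fold changes (> 0) per
#'   target gene.
#' @param n_case,n_control biological replicates per group (default 5 each).
#' @param noise_sd Ct noise sd in cycles (default 0.3).
#' @param seed RNG seed.
#' @return list with elements `ct` (a [ct_table()], reference = first
#'   control) and `truth` (list: `planted_fc`).
#' @export
simulate_ct <- function(planted_fc, n_case = 5, n_control = 5,
                        noise_sd = 0.3, seed = 1) {
  if (any(!is.finite(planted_fc) | planted_fc <= 0)) {
    abort_domain("planted fold changes must be positive")
  }
  if (is.null(names(planted_fc))) abort_domain("planted_fc must be named by gene")
  set.seed(seed)
  genes <- canonical_symbol(names(planted_fc))
  samples <- c(sprintf("LE%02d", seq_len(n_case)),
               sprintf("CR%02d", seq_len(n_control)))
  groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                            samples)
  base_ct <- stats::setNames(stats::runif(length(genes), 20, 26), genes)
  hk_ct <- 18
  rows <- list()
  for (s in samples) {
    is_case <- groups[[s]] == "case"
    for (g in c("ACTB", genes)) {
      mu <- if (g == "ACTB") hk_ct
            else base_ct[[g]] - if (is_case) log2(planted_fc[[g]]) else 0
      for (rep_i in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = g, replicate = rep_i,
          ct = mu + stats::rnorm(1, sd = noise_sd), stringsAsFactors = FALSE)
      }
    }
  }
  data <- do.call(rbind, rows)
  list(ct = ct_table(data, groups, housekeeping = "ACTB",
                     reference_sample = samples[n_case + 1]),
       truth = list(planted_fc = stats::setNames(unname(planted_fc), genes)))
}

#' Simulate a complete pipeline input bundle with one all-criteria target
#'
#' Generates two tissue expression matrices sharing a common DEG core, a gene
#' map with a planted cross-tissue positional cluster, an interactome in
#' which one planted gene is wired into both DEG sets, a gene-set collection
#' with one DEG-loaded set, a qPCR Ct table concordant with the microarray
#' directions, and an annotation table in which the planted gene is the only
#' membrane receptor with a drug link. The planted gene satisfies all seven
#' triage criteria by construction; the other common DEGs satisfy subsets.
#'
#' @param seed RNG seed (sub-seeds for the component generators are derived
#'   from it).
#' @param G genes on the platform (default 500).
#' @param n_common size of the cross-tissue common DEG core (default 50).
#' @param n_unique tissue-specific DEGs per tissue (default 50).
#' @return list with `expression_a`, `expression_b` (generator outputs),
#'   `map`, `network`, `sets` (`GeneSetCollection`), `ct`, `annotations`,
#'   and `truth` (with `target`, the planted all-criteria gene).
#' @export
simulate_bundle <- function(seed = 1, G = 500, n_common = 50, n_unique = 50) {
  if (n_common < 8) abort_domain("bundle needs n_common >= 8")
  set.seed(seed)
  sub <- sample.int(2^20, 8)
  genes <- gene_names(G)
  target <- genes[1]
  common <- sort(c(target, sample(genes[-1], n_common - 1)))
  pool <- setdiff(genes, common)
  uniq_a <- sort(sample(pool, n_unique))
  uniq_b <- sort(sample(setdiff(pool, uniq_a), n_unique))
  deg_a <- sort(c(common, uniq_a))
  deg_b <- sort(c(common, uniq_b))
  # common DEGs are planted UP in both tissues -> direction-concordant
  ea <- simulate_expression(G = G, seed = sub[1], deg_genes = deg_a,
                            up_genes = c(common, uniq_a[seq_len(n_unique / 2)]))
  eb <- simulate_expression(G = G, seed = sub[2], deg_genes = deg_b,
                            up_genes = c(common, uniq_b[seq_len(n_unique / 2)]))
  # one contiguous positional cluster of 7 common DEGs (target among them);
  # contiguity keeps the scan p-value well below the 0.001 gate even if the
  # DEG caller drops one or two members
  cluster_genes <- common[1:7]  # common is sorted; the target sorts first
  mp <- simulate_genome_map(
    G, n_chromosomes = 4,
    cluster_spec = list(list(chrom = "chr3", start_ordinal = 20, size = 7,
                             n_deg = 7)),
    deg_set = common, seed = sub[3])
  nw <- simulate_network(
    G, mean_degree = 10,
    hub_spec = list(list(gene = target,
                         n_deg_edges = max(5, round(0.7 * (n_common - 1))))),
    deg_set = setdiff(common, target), seed = sub[4])
  # one enriched set loaded with common DEGs (incl. target), one decoy set
  set.seed(sub[5])
  enriched_members <- c(common[seq_len(min(20, n_common))],
                        sample(setdiff(genes, common), 5))
  decoy_members <- sample(setdiff(genes, common), 25)
  sets <- structure(list(
    sets = list(LUPUS_CORE = sort(unique(enriched_members)),
                DECOY = sort(decoy_members)),
    descriptions = c(LUPUS_CORE = "planted disease set",
                     DECOY = "random set")), class = "GeneSetCollection")
  qpcr_genes <- c(target, setdiff(common, target)[1:3])
  ct <- simulate_ct(stats::setNames(c(4, 2, 2, 2), qpcr_genes),
                    noise_sd = 0.1, seed = sub[6])
  n_ann <- min(9, n_common - 1)
  ann_genes <- c(target, setdiff(common, target)[seq_len(n_ann)])
  ann <- structure(list(
    classes = data.frame(
      gene = ann_genes,
      protein_class = c("receptor", rep_len(c("kinase", "enzyme", "other"),
                                            n_ann)),
      membrane_localized = c(TRUE, rep(FALSE, n_ann)),
      stringsAsFactors = FALSE),
    drugs = data.frame(gene = target,
                       drug = c("AGENT1", "AGENT2"),
                       stage = c("phase II", "preclinical"),
                       stringsAsFactors = FALSE)),
    class = "ProteinAnnotation")
  list(expression_a = ea, expression_b = eb, map = mp, network = nw,
       sets = sets, ct = ct, annotations = ann,
       truth = list(target = target, common = common,
                    deg_a = deg_a, deg_b = deg_b,
                    cluster_genes = cluster_genes))
}

#' Write a simulated bundle to disk and return a pipeline config
#'
#' Serializes every component of a [simulate_bundle()] result in its standard
#' on-disk format under `dir` (plus a `truth.json`) and returns the config
#' list that [run_pipeline()] accepts, with outputs directed to
#' `file.path(dir, "out")`.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir directory to populate (created if needed).
#' @return config list for [run_pipeline()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(bundle$expression_a$matrix, p("expr_a.tsv"),
                          p("groups_a.tsv"))
  write_expression_matrix(bundle$expression_b$matrix, p("expr_b.tsv"),
                          p("groups_b.tsv"))
  write_gene_map(bundle$map$map, p("genes.bed"))
  write_network(bundle$network$network, p("network.sif"))
  write_gene_sets(bundle$sets, p("sets.gmt"))
  write_ct_table(bundle$ct$ct, p("ct.csv"), p("ct_meta.csv"))
  write_annotations(bundle$annotations, p("annotations.tsv"))
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  list(expression_a = p("expr_a.tsv"), groups_a = p("groups_a.tsv"),
       case_a = "case", control_a = "control",
       expression_b = p("expr_b.tsv"), groups_b = p("groups_b.tsv"),
       case_b = "case", control_b = "control",
       gene_map = p("genes.bed"), network = p("network.sif"),
       gene_sets = p("sets.gmt"), ct = p("ct.csv"),
       ct_meta = p("ct_meta.csv"), annotations = p("annotations.tsv"),
       out_dir = file.path(dir, "out"))
}
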