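# Readers and writers for the plain-text formats the pipeline touches:
# TSV expression matrices, BED gene maps, SIF-style edge lists, GMT gene-set
# collections, CSV Ct tables and TSV protein/drug annotations. All readers
# validate the type invariants; all writers emit files their reader accepts
# (round-trip identity on valid data).

#' Construct a validated expression matrix
#'
#' Container for log2-scale intensities of genes (or probes) by samples, with
#' a group label per sample and an optional probe-to-gene map. Probe collapse
#' happens in [call_degs()], not here.
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples; all
#'   values finite, on log2 scale.
#' @param groups named character vector mapping each sample (column name) to a
#'   group label; every group must contain at least 2 samples.
#' @param probe_to_gene optional named character vector mapping row names
#'   (probe ids) to gene symbols.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, groups, probe_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_validation("values must have row (gene) and column (sample) names")
  }
  if (anyDuplicated(rownames(values))) {
    abort_validation("duplicate gene/probe identifier: ",
                     rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    abort_validation("duplicate sample identifier: ",
                     colnames(values)[duplicated(colnames(values))][1])
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort_validation("non-finite value at gene ", rownames(values)[bad[1]],
                     ", sample ", colnames(values)[bad[2]])
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    abort_validation("sample missing from group map: ", missing[1])
  }
  groups <- groups[colnames(values)]
  tab <- table(groups)
  if (any(tab < 2)) {
    abort_validation("group '", names(tab)[tab < 2][1],
                     "' has fewer than 2 samples")
  }
  if (!is.null(probe_to_gene)) {
    probe_to_gene <- stats::setNames(canonical_symbol(probe_to_gene),
                                     names(probe_to_gene))
  }
  structure(list(values = values, groups = groups,
                 probe_to_gene = probe_to_gene),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$groups)), "groups\n")
  invisible(x)
}

#' Read a TSV expression matrix with a sample group map
#'
#' @param path TSV file: header row of sample ids, first column gene/probe
#'   ids, numeric log2 intensities.
#' @param group_map_path TSV with columns `sample` and `group`.
#' @param probe_map_path optional TSV with columns `probe` and `gene`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_map_path, probe_map_path = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort_format("duplicate sample id in header: ",
                 samples[duplicated(samples)][1])
  }
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      abort_format("non-numeric cell at gene ", genes[bad[1, 1]],
                   ", sample ", samples[bad[1, 2]])
    }
  }
  dimnames(num) <- list(genes, samples)
  gm <- utils::read.delim(group_map_path, header = TRUE,
                          colClasses = "character")
  if (!all(c("sample", "group") %in% names(gm))) {
    abort_format("group map must have columns 'sample' and 'group'")
  }
  groups <- stats::setNames(gm$group, gm$sample)
  p2g <- NULL
  if (!is.null(probe_map_path)) {
    pm <- utils::read.delim(probe_map_path, header = TRUE,
                            colClasses = "character")
    if (!all(c("probe", "gene") %in% names(pm))) {
      abort_format("probe map must have columns 'probe' and 'gene'")
    }
    p2g <- stats::setNames(pm$gene, pm$probe)
  }
  expression_matrix(num, groups, p2g)
}

#' Write an expression matrix and its group map as TSV
#'
#' @param em an `ExpressionMatrix`.
#' @param path output TSV for values.
#' @param group_map_path output TSV for the sample-to-group map.
#' @return `em`, invisibly.
#' @export
write_expression_matrix <- function(em, path, group_map_path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(sample = names(em$groups), group = unname(em$groups),
                   stringsAsFactors = FALSE)
  utils::write.table(gm, group_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(em)
}

#' Read a BED gene map
#'
#' BED convention throughout: 0-based, half-open intervals. Columns are
#' chrom, start, end, name and optionally score and strand. Duplicate gene
#' names are collapsed to the first occurrence with a warning; strand is
#' stored but ignored by the hot-spot scan.
#'
#' @param path BED file (>= 4 columns).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 4) abort_format("BED gene map needs at least 4 columns")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end)) {
    abort_format("non-numeric coordinate at line ",
                 which(is.na(start) | is.na(end))[1])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort_validation("start >= end at line ", bad[1])
  }
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("+", nrow(raw))
  map <- data.frame(gene = canonical_symbol(raw[[4]]), chrom = raw[[1]],
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  dup <- duplicated(map$gene)
  if (any(dup)) {
    warning("duplicate gene(s) in map, keeping first occurrence: ",
            paste(unique(map$gene[dup]), collapse = ", "))
    map <- map[!dup, , drop = FALSE]
  }
  rownames(map) <- NULL
  map
}

#' Write a gene map as BED
#'
#' @param map data.frame as returned by [read_gene_map()].
#' @param path output BED path.
#' @return `map`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  bed <- data.frame(map$chrom, format(map$start, scientific = FALSE, trim = TRUE),
                    format(map$end, scientific = FALSE, trim = TRUE),
                    map$gene, 0L, map$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(map)
}

#' Construct a validated interaction network
#'
#' Directed edges between canonical gene symbols with an effect label.
#' Duplicate (source, target) pairs are collapsed to the first occurrence and
#' self-loops are recorded separately: they never contribute to degree or
#' connectivity counts.
#'
#' @param edges data.frame with columns `source`, `target`, `effect`
#'   (`positive`, `negative` or `unspecified`).
#' @param nodes optional character vector of node symbols; defaults to the
#'   union of edge endpoints. Endpoints outside `nodes` are an error.
#' @return an object of class `InteractionNetwork` with elements `nodes`,
#'   `edges` and `self_loops`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  effects <- c("positive", "negative", "unspecified")
  edges$source <- canonical_symbol(edges$source)
  edges$target <- canonical_symbol(edges$target)
  if (!all(edges$effect %in% effects)) {
    abort_validation("unknown edge effect: ",
                     setdiff(unique(edges$effect), effects)[1])
  }
  nodes <- if (is.null(nodes)) sort(unique(c(edges$source, edges$target)))
           else sort(unique(canonical_symbol(nodes)))
  stray <- setdiff(c(edges$source, edges$target), nodes)
  if (length(stray)) abort_validation("edge endpoint not in node set: ", stray[1])
  edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  loop <- edges$source == edges$target
  structure(list(nodes = nodes,
                 edges = edges[!loop, , drop = FALSE],
                 self_loops = edges[loop, , drop = FALSE]),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", nrow(x$self_loops), "self-loop(s)\n")
  invisible(x)
}

#' Read a SIF-style interaction network
#'
#' Tab-separated triples `source<TAB>relation<TAB>target` with relation in
#' `activates` (positive), `inhibits` (negative), `interacts` (unspecified).
#'
#' @param path SIF file.
#' @return an [interaction_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(!lengths(fields) %in% c(1L, 3L))
  if (length(bad)) {
    abort_format("malformed SIF line ", bad[1], ": expected 3 tab-separated fields")
  }
  # a bare node name on its own line declares an isolated node (SIF rule)
  isolated <- unlist(fields[lengths(fields) == 1L], use.names = FALSE)
  fields <- fields[lengths(fields) == 3L]
  rel_map <- c(activates = "positive", inhibits = "negative",
               interacts = "unspecified")
  m <- if (length(fields)) do.call(rbind, fields) else
    matrix(character(0), ncol = 3)
  rel <- rel_map[m[, 2]]
  if (anyNA(rel)) {
    abort_format("unknown relation '", m[is.na(rel), 2][1], "' in SIF file")
  }
  interaction_network(data.frame(source = m[, 1], target = m[, 3],
                                 effect = unname(rel),
                                 stringsAsFactors = FALSE),
                      nodes = c(m[, 1], m[, 3], canonical_symbol(isolated)))
}

#' Write an interaction network in SIF dialect
#'
#' @param net an `InteractionNetwork`.
#' @param path output path.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path) {
  rel_map <- c(positive = "activates", negative = "inhibits",
               unspecified = "interacts")
  all_edges <- rbind(net$edges, net$self_loops)
  lines <- sprintf("%s\t%s\t%s", all_edges$source,
                   rel_map[all_edges$effect], all_edges$target)
  isolated <- setdiff(net$nodes, c(all_edges$source, all_edges$target))
  # SIF convention: a bare node name on its own line declares an isolated node
  writeLines(c(lines, isolated), path)
  invisible(net)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`; member
#' symbols are canonicalized to uppercase.
#'
#' @param path GMT file.
#' @return a list of class `GeneSetCollection` with elements `sets` (named
#'   list of symbol vectors) and `descriptions` (named character).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort_format("GMT line ", bad[1], " has fewer than 3 fields")
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    abort_validation("duplicate gene-set name: ", names_[duplicated(names_)][1])
  }
  sets <- lapply(fields, function(f) unique(canonical_symbol(f[-(1:2)])))
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  structure(list(sets = stats::setNames(sets, names_),
                 descriptions = stats::setNames(descriptions, names_)),
            class = "GeneSetCollection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `collection`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a qPCR Ct table with sample metadata
#'
#' The Ct CSV has columns `sample`, `gene`, `replicate`, `ct`; the metadata
#' CSV has columns `sample`, `group` with groups `case` and `control`. The
#' housekeeping gene must be measured in every sample and the reference
#' sample (defaulting to the first control) must belong to the control group.
#'
#' @param path Ct CSV.
#' @param meta_path sample metadata CSV.
#' @param housekeeping housekeeping gene symbol (default `"ACTB"`).
#' @param reference_sample reference sample id whose relative expression is
#'   defined as 1; default: first control sample in the metadata.
#' @return a list of class `CtTable`.
#' @export
read_ct_table <- function(path, meta_path, housekeeping = "ACTB",
                          reference_sample = NULL) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort_format("Ct table must have columns ", paste(need, collapse = ", "))
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta))) {
    abort_format("Ct metadata must have columns 'sample' and 'group'")
  }
  groups <- stats::setNames(meta$group, meta$sample)
  ct_table(ct, groups, housekeeping, reference_sample)
}

#' Construct a validated Ct table
#'
#' @param data data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param groups named character vector sample -> `case`/`control`.
#' @inheritParams read_ct_table
#' @return a list of class `CtTable`.
#' @export
ct_table <- function(data, groups, housekeeping = "ACTB",
                     reference_sample = NULL) {
  data$gene <- canonical_symbol(data$gene)
  housekeeping <- canonical_symbol(housekeeping)
  if (!all(unique(data$sample) %in% names(groups))) {
    abort_validation("sample missing from metadata: ",
                     setdiff(unique(data$sample), names(groups))[1])
  }
  if (!all(groups %in% c("case", "control"))) {
    abort_validation("groups must be 'case' or 'control'")
  }
  if (any(!is.finite(data$ct) | data$ct <= 0)) {
    abort_validation("Ct values must be positive finite numbers")
  }
  samples <- unique(data$sample)
  has_hk <- vapply(samples, function(s) {
    any(data$gene[data$sample == s] == housekeeping)
  }, logical(1))
  if (!all(has_hk)) {
    abort_validation("housekeeping gene ", housekeeping,
                     " missing for sample ", samples[!has_hk][1])
  }
  if (is.null(reference_sample)) {
    controls <- names(groups)[groups == "control"]
    reference_sample <- intersect(samples, controls)[1]
    if (is.na(reference_sample)) {
      abort_validation("no control sample available as reference")
    }
  }
  if (!identical(unname(groups[reference_sample]), "control")) {
    abort_validation("reference sample ", reference_sample,
                     " is not in the control group")
  }
  structure(list(data = data, groups = groups, housekeeping = housekeeping,
                 reference_sample = reference_sample),
            class = "CtTable")
}

#' Write a Ct table and metadata as CSV
#'
#' @param ct a `CtTable`.
#' @param path output Ct CSV.
#' @param meta_path output metadata CSV.
#' @return `ct`, invisibly.
#' @export
write_ct_table <- function(ct, path, meta_path) {
  utils::write.csv(ct$data, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(sample = names(ct$groups), group = unname(ct$groups),
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(ct)
}

#' Read a protein class / drug annotation table
#'
#' TSV with columns `gene`, `protein_class`, `membrane_localized`, `drugs`.
#' `drugs` is a semicolon-separated list of `drug:stage` pairs with stage in
#' the closed vocabulary preclinical, phase I, phase II, phase III, approved;
#' empty for genes without drug links.
#'
#' @param path annotation TSV.
#' @return a list of class `ProteinAnnotation` with elements `classes`
#'   (data.frame gene/protein_class/membrane_localized) and `drugs`
#'   (data.frame gene/drug/stage).
#' @export
read_annotations <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("gene", "protein_class", "membrane_localized", "drugs")
  if (!all(need %in% names(raw))) {
    abort_format("annotation table must have columns ",
                 paste(need, collapse = ", "))
  }
  classes_vocab <- c("ligand", "protease", "receptor", "kinase",
                     "transcription factor", "enzyme", "other")
  if (!all(raw$protein_class %in% classes_vocab)) {
    abort_validation("unknown protein class: ",
                     setdiff(unique(raw$protein_class), classes_vocab)[1])
  }
  stages <- c("preclinical", "phase I", "phase II", "phase III", "approved")
  genes <- canonical_symbol(raw$gene)
  if (anyDuplicated(genes)) {
    abort_validation("duplicate annotation for gene: ",
                     genes[duplicated(genes)][1])
  }
  drug_rows <- lapply(seq_along(genes), function(i) {
    s <- raw$drugs[i]
    if (is.na(s) || !nzchar(s)) return(NULL)
    pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- which(lengths(pairs) != 2L)
    if (length(bad)) abort_format("malformed drug entry for gene ", genes[i])
    data.frame(gene = genes[i],
               drug = vapply(pairs, `[[`, character(1), 1L),
               stage = vapply(pairs, `[[`, character(1), 2L),
               stringsAsFactors = FALSE)
  })
  drugs <- do.call(rbind, c(drug_rows,
                            list(data.frame(gene = character(0),
                                            drug = character(0),
                                            stage = character(0)))))
  if (nrow(drugs) && !all(drugs$stage %in% stages)) {
    abort_validation("unknown drug development stage: ",
                     setdiff(unique(drugs$stage), stages)[1])
  }
  drugs <- drugs[!duplicated(drugs), , drop = FALSE]
  rownames(drugs) <- NULL
  structure(list(classes = data.frame(gene = genes,
                                      protein_class = raw$protein_class,
                                      membrane_localized =
                                        toupper(raw$membrane_localized) == "TRUE",
                                      stringsAsFactors = FALSE),
                 drugs = drugs),
            class = "ProteinAnnotation")
}

#' Write a protein annotation table as TSV
#'
#' @param ann a `ProteinAnnotation`.
#' @param path output TSV.
#' @return `ann`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  drugs <- vapply(ann$classes$gene, function(g) {
    rows <- ann$drugs[ann$drugs$gene == g, , drop = FALSE]
    if (!nrow(rows)) return("")
    paste(sprintf("%s:%s", rows$drug, rows$stage), collapse = ";")
  }, character(1))
  out <- data.frame(gene = ann$classes$gene,
                    protein_class = ann$classes$protein_class,
                    membrane_localized = ann$classes$membrane_localized,
                    drugs = drugs, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Read / write DEG record tables
#'
#' TSV with columns `gene`, `fc`, `p`, `direction`, `tissue`, as produced by
#' [call_degs()].
#'
#' @param path TSV path.
#' @return data.frame of DEG records.
#' @export
read_degs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "fc", "p", "direction", "tissue")
  if (!all(need %in% names(df))) {
    abort_format("DEG table must have columns ", paste(need, collapse = ", "))
  }
  df$gene <- canonical_symbol(df$gene)
  df
}

#' @rdname read_degs
#' @param degs data.frame of DEG records.
#' @export
write_degs <- function(degs, path) {
  utils::write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(degs)
}
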