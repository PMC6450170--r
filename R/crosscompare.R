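# Cross-tissue comparison of DEG lists: symbol intersection partitioned by
# direction concordance. Joins are on the canonical gene symbol, never on
# probe ids; probe collapse belongs upstream in call_degs().

#' Intersect two tissue DEG lists and partition by direction concordance
#'
#' @param degs_a,degs_b data.frames with columns `gene` and `direction`
#'   (`UP`/`DOWN`), one row per symbol.
#' @return a list of class `OverlapReport` with elements `common`,
#'   `same_direction`, `opposite_direction` (character vectors, sorted) and
#'   `unique_a`, `unique_b` (symbols found in only one list).
#' @export
overlap_profiles <- function(degs_a, degs_b) {
  for (nm in c("a", "b")) {
    d <- if (nm == "a") degs_a else degs_b
    if (anyDuplicated(d$gene)) {
      abort_validation("duplicate symbol in list ", nm, ": ",
                       d$gene[duplicated(d$gene)][1],
                       " (collapse probes upstream)")
    }
  }
  common <- sort(intersect(degs_a$gene, degs_b$gene))
  dir_a <- stats::setNames(degs_a$direction, degs_a$gene)[common]
  dir_b <- stats::setNames(degs_b$direction, degs_b$gene)[common]
  same <- common[dir_a == dir_b]
  structure(list(common = common,
                 same_direction = same,
                 opposite_direction = setdiff(common, same),
                 unique_a = sort(setdiff(degs_a$gene, common)),
                 unique_b = sort(setdiff(degs_b$gene, common))),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport:", length(x$common), "common (",
      length(x$same_direction), "same direction,",
      length(x$opposite_direction), "opposite );",
      length(x$unique_a), "unique to A,", length(x$unique_b), "unique to B\n")
  invisible(x)
}
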