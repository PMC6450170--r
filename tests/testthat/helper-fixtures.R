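# In-code fixtures: tiny files written to tempdir at test time, plus
# enumeration oracles shared by several test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 3-gene x 4-sample expression fixture (two groups of two)
fixture_expression_files <- function() {
  mat <- write_lines_tmp(c(
    "gene\tS1\tS2\tS3\tS4",
    "GENEA\t5.0\t5.2\t7.1\t7.3",
    "GENEB\t6.0\t6.1\t6.0\t5.9",
    "GENEC\t8.0\t8.2\t4.0\t4.1"), ".tsv")
  grp <- write_lines_tmp(c(
    "sample\tgroup",
    "S1\tcase", "S2\tcase", "S3\tcontrol", "S4\tcontrol"), ".tsv")
  list(matrix = mat, groups = grp)
}

fixture_network_file <- function() {
  write_lines_tmp(c(
    "A\tactivates\tB",
    "B\tinhibits\tC",
    "C\tinteracts\tD"), ".sif")
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw `draws` items from a population of size `total` containing `successes`
# marked items; P(at least k marked) by enumerating all combinations.
enum_hyper_tail <- function(k, successes, total, draws) {
  combos <- utils::combn(total, draws)
  marked <- seq_len(successes)
  hits <- colSums(matrix(combos %in% marked, nrow = draws))
  mean(hits >= k)
}

# brute-force hot-spot oracle: evaluate every O(G^2) contiguous window on one
# chromosome and return the windows passing both gates (no merging).
brute_force_windows <- function(is_deg, K, G, min_degs, p_max) {
  n <- length(is_deg)
  out <- list()
  for (lo in seq_len(n)) {
    for (hi in lo:n) {
      k <- sum(is_deg[lo:hi])
      if (k < min_degs) next
      p <- phyper(k - 1, K, G - K, hi - lo + 1, lower.tail = FALSE)
      if (p <= p_max) out[[length(out) + 1L]] <- c(lo = lo, hi = hi, p = p)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# random DEG tables for property tests
random_deg_table <- function(genes, tissue = "X") {
  fc <- sample(c(-2, -1.5, 1.5, 2), length(genes), replace = TRUE)
  data.frame(gene = genes, fc = fc,
             p = runif(length(genes), 0, 0.05),
             direction = ifelse(fc >= 1, "UP", "DOWN"),
             tissue = tissue, stringsAsFactors = FALSE)
}
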