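# small helper: a single-chromosome map with genes at 10kb spacing
toy_map <- function(G, chrom = "chr1") {
  data.frame(gene = sprintf("T%03d", seq_len(G)), chrom = chrom,
             start = (seq_len(G) - 1) * 10000,
             end = (seq_len(G) - 1) * 10000 + 5000,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("window_pvalue matches closed forms and enumeration", {
  expect_equal(window_pvalue(4, 0, 5, 10), 1)
  expect_equal(window_pvalue(4, 4, 5, 10), 5 / choose(10, 4))
  expect_equal(window_pvalue(6, 6, 6, 40), 1 / choose(40, 6))
  expect_error(window_pvalue(4, 5, 6, 10), class = "targettriage_domain_error")

  # exhaustive-enumeration oracle on small universes
  set.seed(5)
  for (i in 1:10) {
    G <- sample(8:20, 1)
    K <- sample(2:(G - 2), 1)
    w <- sample(2:(G - 1), 1)
    k <- sample(0:min(w, K), 1)
    expect_equal(window_pvalue(w, k, K, G), enum_hyper_tail(k, K, G, w),
                 tolerance = 1e-12)
  }
})

test_that("window_pvalue is non-increasing in k", {
  for (w in c(5, 10, 20)) {
    p <- window_pvalue(w, 0:min(w, 30), 30, 100)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("scan recovers a single planted run with the exact closed-form p", {
  map <- toy_map(20)
  degs <- map$gene[5:10]
  hs <- scan_hotspots(map, degs, min_degs = 5, p_max = 0.001)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$k, 6L)
  expect_equal(hs$w, 6L)
  expect_equal(hs$p, 1 / choose(20, 6))
  expect_setequal(hs$deg_genes[[1]], degs)
  expect_equal(hs$start, map$start[5])
  expect_equal(hs$end, map$end[10])
})

test_that("scan agrees with the brute-force all-window oracle", {
  set.seed(9)
  for (i in 1:10) {
    G <- 60
    map <- toy_map(G)
    degs <- sample(map$gene, 14)
    hs <- scan_hotspots(map, degs, min_degs = 4, p_max = 0.01)
    bf <- brute_force_windows(map$gene %in% degs, K = 14, G = G,
                              min_degs = 4, p_max = 0.01)
    if (is.null(bf)) {
      expect_equal(nrow(hs), 0L)
    } else {
      # every reported hot spot carries the best brute-force window p, and
      # every significant brute-force window, trimmed to its DEG endpoints
      # (which only shrinks w and hence p), lies inside some hot spot
      expect_equal(min(hs$p), min(bf[, "p"]))
      deg_pos <- which(map$gene %in% degs)
      covered <- vapply(seq_len(nrow(bf)), function(r) {
        inside <- deg_pos[deg_pos >= bf[r, "lo"] & deg_pos <= bf[r, "hi"]]
        any(hs$start <= map$start[min(inside)] &
              hs$end >= map$end[max(inside)])
      }, logical(1))
      expect_true(all(covered))
      # post-hoc invariants
      expect_true(all(hs$k >= 4 & hs$p <= 0.01))
    }
  }
})

test_that("chromosomes without DEGs yield no hot spots; unmapped DEGs reported", {
  map <- toy_map(20)
  hs <- scan_hotspots(map, character(0))
  expect_equal(nrow(hs), 0L)
  expect_message(hs2 <- scan_hotspots(map, c(map$gene[1:6], "ABSENT")),
                 "not present")
  expect_equal(attr(hs2, "unmapped"), "ABSENT")
})

test_that("scan output is invariant to gene-map row order", {
  set.seed(21)
  map <- toy_map(50)
  degs <- map$gene[c(10:15, 40)]
  shuffled <- map[sample(nrow(map)), ]
  a <- scan_hotspots(map, degs, min_degs = 5, p_max = 0.01)
  b <- scan_hotspots(shuffled, degs, min_degs = 5, p_max = 0.01)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("overlapping or book-ended significant runs merge", {
  map <- toy_map(40)
  # two dense DEG runs separated by a single non-DEG gene: each run is
  # significant on its own and they book-end after trimming, so the scan also
  # evaluates the spanning run; all merge into one hot spot
  degs <- map$gene[c(5:9, 11:15)]
  hs <- scan_hotspots(map, degs, min_degs = 5, p_max = 0.001)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_degs, 10L)
  expect_equal(hs$start, map$start[5])
  expect_equal(hs$end, map$end[15])
})

test_that("hot-spot overlap uses half-open spans and intersects DEG sets", {
  mk <- function(chrom, start, end, degs) {
    data.frame(chromosome = chrom, start = start, end = end,
               n_genes = length(degs), n_degs = length(degs),
               w = length(degs), k = length(degs), p = 1e-5,
               genes = I(list(degs)), deg_genes = I(list(degs)),
               stringsAsFactors = FALSE)
  }
  a <- mk("chr1", 100, 200, c("A", "B", "C"))
  b <- mk("chr1", 200, 300, c("B", "C", "D"))
  expect_equal(nrow(overlap_hotspots(a, b)), 0L)

  a2 <- mk("chr1", 100, 250, c("A", "B", "C"))
  ov <- overlap_hotspots(a2, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$shared_genes[[1]], c("B", "C"))

  # same span, different chromosome: no overlap
  b2 <- mk("chr2", 100, 250, c("B", "C"))
  expect_equal(nrow(overlap_hotspots(a2, b2)), 0L)
})

test_that("a planted cross-tissue co-cluster is recovered as exactly one pair", {
  set.seed(31)
  common <- sprintf("G%05d", 1:8)
  mp <- simulate_genome_map(400, n_chromosomes = 4,
                            cluster_spec = list(list(chrom = "chr2",
                                                     start_ordinal = 10,
                                                     size = 8, n_deg = 6)),
                            deg_set = common, seed = 13)
  hs_a <- scan_hotspots(mp$map, common, min_degs = 5, p_max = 0.001)
  hs_b <- scan_hotspots(mp$map, common, min_degs = 5, p_max = 0.001)
  ov <- overlap_hotspots(hs_a, hs_b)
  expect_equal(nrow(ov), 1L)
  # the planted cluster is recovered; a scattered DEG that happens to land
  # adjacent to the run may legitimately join the merged span
  expect_true(all(mp$truth$clusters[[1]]$genes %in% ov$shared_genes[[1]]))
})

test_that("hot spots round-trip through TSV", {
  map <- toy_map(20)
  hs <- scan_hotspots(map, map$gene[5:10], min_degs = 5, p_max = 0.001)
  path <- tempfile(fileext = ".tsv")
  write_hotspots(hs, path)
  back <- read_hotspots(path)
  expect_equal(back$chromosome, hs$chromosome)
  expect_equal(back$p, hs$p, tolerance = 1e-9)
  expect_equal(back$deg_genes[[1]], hs$deg_genes[[1]])
})
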