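# builds a minimal consistent evidence bundle around explicit criterion flags
mk_evidence <- function() {
  common <- c("TOPG", "PART1", "PART2")
  degs_a <- data.frame(gene = c(common, "ONLYA"), fc = 1.5, p = 0.01,
                       direction = "UP", tissue = "A", stringsAsFactors = FALSE)
  degs_b <- data.frame(gene = c(common, "ONLYB"), fc = 1.5, p = 0.01,
                       direction = "UP", tissue = "B", stringsAsFactors = FALSE)
  ovl <- overlap_profiles(degs_a, degs_b)
  qpcr <- structure(list(summary = data.frame(
    gene = c("TOPG", "PART1"),
    control_mean = c(1, 1), control_sem = 0.1,
    case_mean = c(4, 0.5), case_sem = 0.1,  # PART1 discordant (qPCR DOWN)
    p = 0.01, stringsAsFactors = FALSE)), class = "FoldChangeResult")
  enr <- data.frame(set = c("S1", "S2"), description = "", n_set = 10L,
                    k = 2L, k_up = 2L, k_down = 0L, p = c(1e-5, 0.5),
                    q = c(2e-5, 0.5),
                    overlap = I(list(c("TOPG", "PART2"), "PART1")),
                    stringsAsFactors = FALSE)
  conn <- function(p_top) data.frame(
    gene = common, Actual = c(10L, 2L, 1L), n = 3L, R = 12L, N = 100L,
    Expected = 0.4, Ratio = 2, z = c(8, 1, 0.5), p = c(p_top, 0.5, 0.9),
    stringsAsFactors = FALSE)
  hubs <- data.frame(gene = c("TOPG", "PART1", "PART2", "X1", "X2", "X3",
                              "X4", "X5", "X6", "X7"),
                     degree = c(30L, 2:10), stringsAsFactors = FALSE)
  hso <- data.frame(chromosome = "chr3", start_a = 0, end_a = 100,
                    start_b = 50, end_b = 150,
                    shared_genes = I(list(c("TOPG", "PART2"))),
                    stringsAsFactors = FALSE)
  ann <- structure(list(
    classes = data.frame(gene = c("TOPG", "PART1"),
                         protein_class = c("receptor", "kinase"),
                         membrane_localized = c(TRUE, FALSE),
                         stringsAsFactors = FALSE),
    drugs = data.frame(gene = "TOPG", drug = c("DRUG1", "DRUG1"),
                       stage = c("phase II", "phase II"),
                       stringsAsFactors = FALSE)), class = "ProteinAnnotation")
  list(ovl = ovl, degs_a = degs_a, degs_b = degs_b, qpcr = qpcr, enr = enr,
       conn_a = conn(1e-6), conn_b = conn(1e-6), hubs = hubs, hso = hso,
       ann = ann)
}

score_all <- function(ev) {
  score_candidates(ev$ovl, degs_a = ev$degs_a, degs_b = ev$degs_b,
                   qpcr = ev$qpcr, enrichment = ev$enr,
                   conn_a = ev$conn_a, conn_b = ev$conn_b, hubs = ev$hubs,
                   hotspot_overlap = ev$hso, annotations = ev$ann)
}

test_that("a gene satisfying all seven criteria scores 7 and ranks first", {
  ev <- mk_evidence()
  sc <- score_all(ev)
  top <- sc[sc$gene == "TOPG", ]
  expect_equal(top$score, 7)
  expect_equal(top$rank, 1L)
  crit_cols <- grep("^[a-g]_", names(sc), value = TRUE)
  expect_length(crit_cols, 7L)
  expect_true(all(unlist(top[crit_cols])))
  expect_equal(sc$score, rowSums(sc[crit_cols]), ignore_attr = TRUE)
})

test_that("failing one criterion ranks strictly below a full-score gene", {
  ev <- mk_evidence()
  # degrade TOPG's over-connectivity in dataset B only -> fails (d)
  ev$conn_b$p[ev$conn_b$gene == "TOPG"] <- 0.9
  sc <- score_all(ev)
  expect_equal(sc[sc$gene == "TOPG", "score"], 6)
  expect_equal(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$score) <= 0))
})

test_that("making a false criterion true never lowers a gene's rank", {
  ev <- mk_evidence()
  base <- score_all(ev)
  # PART1 currently lacks a drug link; grant one
  ev2 <- ev
  ev2$ann$drugs <- rbind(ev2$ann$drugs,
                         data.frame(gene = "PART1", drug = "DRUGX",
                                    stage = "preclinical"))
  after <- score_all(ev2)
  expect_lte(after$rank[after$gene == "PART1"],
             base$rank[base$gene == "PART1"])
  # superset domination: TOPG's criteria are a strict superset of PART2's
  expect_lt(after$rank[after$gene == "TOPG"],
            after$rank[after$gene == "PART2"])
})

test_that("absent evidence channels evaluate to FALSE and are flagged", {
  ev <- mk_evidence()
  sc <- score_candidates(ev$ovl, degs_a = ev$degs_a, degs_b = ev$degs_b)
  expect_true(all(!sc$b_qpcr_concordant))
  expect_true(all(!sc$g_drug_target))
  expect_equal(unique(sc$n_evaluated), 1L)
  evaluated <- attr(sc, "evaluated")
  expect_false(evaluated[["g_drug_target"]])
  expect_true(evaluated[["a_deg_both"]])
})

test_that("scoring is deterministic given the evidence bundle", {
  ev <- mk_evidence()
  expect_identical(score_all(ev), score_all(ev))
})

test_that("a planted all-criteria gene wins across random partial satisfiers", {
  wins <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    genes <- c("WINNER", sprintf("P%02d", 1:50))
    degs <- data.frame(gene = genes, fc = 1.5, p = 0.01, direction = "UP",
                       tissue = "A", stringsAsFactors = FALSE)
    ovl <- overlap_profiles(degs, transform(degs, tissue = "B"))
    pick <- function(n) sample(genes[-1], n)
    qp <- structure(list(summary = data.frame(
      gene = c("WINNER", pick(20)), control_mean = 1, control_sem = 0.1,
      case_mean = 3, case_sem = 0.1, p = 0.02, stringsAsFactors = FALSE)),
      class = "FoldChangeResult")
    enr <- data.frame(set = "S", description = "", n_set = 20L, k = 10L,
                      k_up = 10L, k_down = 0L, p = 1e-6, q = 1e-6,
                      overlap = I(list(c("WINNER", pick(15)))),
                      stringsAsFactors = FALSE)
    conn <- function() data.frame(
      gene = c("WINNER", pick(25)), Actual = 5L, n = 10L, R = 20L, N = 200L,
      Expected = 1, Ratio = 5, z = c(9, runif(25, 0, 5)),
      p = c(1e-8, runif(25, 0, 0.2)), stringsAsFactors = FALSE)
    hubs <- data.frame(gene = genes,
                       degree = c(50L, sample(1:10, 50, replace = TRUE)),
                       stringsAsFactors = FALSE)
    hso <- data.frame(chromosome = "chr1", start_a = 0, end_a = 10,
                      start_b = 5, end_b = 15,
                      shared_genes = I(list(c("WINNER", pick(5)))),
                      stringsAsFactors = FALSE)
    ann <- structure(list(
      classes = data.frame(gene = genes, protein_class = "receptor",
                           membrane_localized = TRUE, stringsAsFactors = FALSE),
      drugs = data.frame(gene = c("WINNER", pick(10)), drug = "D",
                         stage = "approved", stringsAsFactors = FALSE)),
      class = "ProteinAnnotation")
    sc <- score_candidates(ovl, degs_a = degs,
                           degs_b = transform(degs, tissue = "B"),
                           qpcr = qp, enrichment = enr, conn_a = conn(),
                           conn_b = conn(), hubs = hubs,
                           hotspot_overlap = hso, annotations = ann)
    wins <- wins + (sc$gene[1] == "WINNER")
  }
  expect_equal(wins, n_seeds)
})

test_that("receptor filtering requires the membrane conjunction", {
  ann <- structure(list(
    classes = data.frame(
      gene = c("CCR2", "STAT1", "NUCREC"),
      protein_class = c("receptor", "transcription factor", "receptor"),
      membrane_localized = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE),
    drugs = data.frame(gene = character(0), drug = character(0),
                       stage = character(0))), class = "ProteinAnnotation")
  expect_equal(filter_receptors(c("CCR2", "STAT1", "NUCREC"), ann), "CCR2")
  expect_warning(res <- filter_receptors("UNKNOWN", ann), "unannotated")
  expect_length(res, 0L)
})

test_that("drug links flatten and deduplicate", {
  ann <- structure(list(
    classes = data.frame(gene = "CCR2", protein_class = "receptor",
                         membrane_localized = TRUE, stringsAsFactors = FALSE),
    drugs = data.frame(gene = "CCR2",
                       drug = c("CCX915", "CCX140", "TAK779", "MLN1202",
                                "CCX140"),
                       stage = c("phase I", "phase II", "preclinical",
                                 "phase II", "phase II"),
                       stringsAsFactors = FALSE)), class = "ProteinAnnotation")
  rows <- attach_drugs("CCR2", ann)
  expect_equal(nrow(rows), 4L)
  expect_equal(nrow(attach_drugs("NODRUG", ann)), 0L)
})
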