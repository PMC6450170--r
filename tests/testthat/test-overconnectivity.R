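# helper: build a network from an undirected edge list given as 2-col matrix
net_from_pairs <- function(pairs, nodes = NULL) {
  interaction_network(data.frame(source = pairs[, 1], target = pairs[, 2],
                                 effect = "unspecified",
                                 stringsAsFactors = FALSE), nodes = nodes)
}

test_that("connectivity stats match the enumeration example and invariants", {
  # focal gene F with 5 neighbors in a background of 10 others; experimental
  # set = 4 of those neighbors -> Actual = 4, Expected = 2 exactly
  nodes <- c("F", sprintf("B%02d", 1:10))
  pairs <- cbind("F", sprintf("B%02d", 1:5))
  net <- net_from_pairs(pairs, nodes = nodes)
  res <- connectivity_stats(net, deg_set = sprintf("B%02d", 1:4),
                            background = nodes, gene = "F")
  expect_equal(res$N, 10L)
  expect_equal(res$R, 5L)
  expect_equal(res$n, 4L)
  expect_equal(res$Actual, 4L)
  expect_equal(res$Expected, 2)
  expect_equal(res$Expected * res$N, res$n * res$R)
  expect_equal(res$Ratio, 2)
  expect_equal(res$p, 5 / choose(10, 4))
  # against the exhaustive subset-enumeration oracle
  expect_equal(res$p, enum_hyper_tail(4, 5, 10, 4), tolerance = 1e-12)
})

test_that("degenerate and symmetric cases behave per definition", {
  nodes <- c("F", "X", "Y")
  net <- net_from_pairs(cbind("X", "Y"), nodes = nodes)
  res <- connectivity_stats(net, deg_set = c("X", "Y"), background = nodes,
                            gene = "F")
  expect_equal(res$Actual, 0L)
  expect_equal(res$Expected, 0)
  expect_equal(res$p, 1)
  expect_true(is.na(res$Ratio))
  expect_equal(res$z, 0)

  # Actual == Expected by construction: F adjacent to all of the background
  nodes2 <- c("F", "A", "B")
  net2 <- net_from_pairs(rbind(c("F", "A"), c("F", "B")), nodes = nodes2)
  res2 <- connectivity_stats(net2, deg_set = "A", background = nodes2,
                             gene = "F")
  expect_equal(res2$Actual, 1L)
  expect_equal(res2$Expected, 1)
  expect_equal(res2$z, 0)

  expect_error(connectivity_stats(net, "X", c("X", "Y"), "NOPE"),
               class = "targettriage_domain_error")
  # empty experimental set -> degenerate null result
  res3 <- connectivity_stats(net, character(0), nodes, "F")
  expect_equal(res3$Actual, 0L)
  expect_equal(res3$p, 1)
})

test_that("hypergeometric tail matches a 20,000-draw permutation null", {
  set.seed(77)
  G <- 50
  nodes <- sprintf("N%02d", 1:G)
  pairs <- t(combn(G, 2))
  pairs <- pairs[runif(nrow(pairs)) < 0.12, , drop = FALSE]
  net <- net_from_pairs(cbind(nodes[pairs[, 1]], nodes[pairs[, 2]]),
                        nodes = nodes)
  deg_set <- sample(nodes[-1], 10)
  focal <- nodes[1]
  res <- connectivity_stats(net, deg_set, nodes, focal)
  # empirical null: random n-subsets of the background (excluding the focal)
  nb <- setdiff(unique(c(net$edges$target[net$edges$source == focal],
                         net$edges$source[net$edges$target == focal])), focal)
  bg <- setdiff(nodes, focal)
  draws <- replicate(20000, sum(sample(bg, res$n) %in% nb))
  p_emp <- mean(draws >= res$Actual)
  se <- sqrt(p_emp * (1 - p_emp) / 20000)
  expect_lte(abs(res$p - p_emp), 3 * se + 1e-9)
})

test_that("a hub wired to the whole experimental set ranks first", {
  nodes <- c("HUB", sprintf("D%02d", 1:10), sprintf("B%02d", 1:89))
  degs <- sprintf("D%02d", 1:10)
  pairs <- rbind(cbind("HUB", degs),
                 cbind(sprintf("B%02d", 1:20), sprintf("B%02d", 41:60)))
  net <- net_from_pairs(pairs, nodes = nodes)
  ranked <- overconnected_genes(net, degs, nodes,
                                candidates = c("HUB", sprintf("B%02d", 1:20)))
  expect_equal(ranked$gene[1], "HUB")
  expect_equal(ranked$Actual[1], 10L)

  # filter semantics: impossible threshold empties the list
  none <- overconnected_genes(net, degs, nodes, candidates = "B01",
                              p_max = 1e-12)
  expect_equal(nrow(none), 0L)
})

test_that("planted hubs are recovered at rank 1 across seeds", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    deg_set <- sprintf("G%05d", sample(500, 40))
    sim <- simulate_network(500, mean_degree = 10,
                            hub_spec = list(list(gene = "G00500",
                                                 n_deg_edges = 30)),
                            deg_set = setdiff(deg_set, "G00500"), seed = s)
    ranked <- overconnected_genes(sim$network, setdiff(deg_set, "G00500"),
                                  sprintf("G%05d", 1:500),
                                  candidates = c("G00500", deg_set))
    hits <- hits + (nrow(ranked) > 0 && ranked$gene[1] == "G00500")
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("one-step expansion matches enumerable cases and its property", {
  chain <- interaction_network(data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "D"),
    effect = "positive", stringsAsFactors = FALSE))
  ex <- expand_network(chain, "B")
  expect_setequal(ex$nodes, c("A", "B", "C"))
  expect_equal(nrow(ex$edges), 2L)
  expect_setequal(paste(ex$edges$source, ex$edges$target),
                  c("A B", "B C"))

  # seed set = all nodes -> identity
  full <- expand_network(chain, chain$nodes)
  expect_setequal(full$nodes, chain$nodes)
  expect_equal(nrow(full$edges), nrow(chain$edges))

  expect_warning(empty <- expand_network(chain, "NOPE"), "absent")
  expect_length(empty$nodes, 0L)

  # property: every non-seed node in the expansion touches a seed
  set.seed(12)
  for (i in 1:20) {
    G <- 30
    nodes <- sprintf("N%02d", 1:G)
    pairs <- t(combn(G, 2))
    pairs <- pairs[runif(nrow(pairs)) < 0.08, , drop = FALSE]
    if (!nrow(pairs)) next
    net <- net_from_pairs(cbind(nodes[pairs[, 1]], nodes[pairs[, 2]]),
                          nodes = nodes)
    seeds <- sample(nodes, 3)
    ex <- expand_network(net, seeds)
    nb <- targettriage:::neighbor_list(ex)
    for (v in setdiff(ex$nodes, seeds)) {
      expect_true(length(intersect(nb[[v]], seeds)) >= 1)
    }
  }
})

test_that("hub ranking orders by degree with alphabetical ties and handshake", {
  star <- net_from_pairs(cbind("CTR", sprintf("L%d", 1:5)))
  hr <- hub_rank(star)
  expect_equal(hr$gene[1], "CTR")
  expect_equal(hr$degree[1], 5L)

  tie <- net_from_pairs(rbind(c("B", "A"), c("C", "D")))
  expect_equal(hub_rank(tie)$gene, c("A", "B", "C", "D"))

  set.seed(4)
  for (i in 1:10) {
    G <- 25
    nodes <- sprintf("N%02d", 1:G)
    pairs <- t(combn(G, 2))
    pairs <- pairs[runif(nrow(pairs)) < 0.1, , drop = FALSE]
    net <- net_from_pairs(cbind(nodes[pairs[, 1]], nodes[pairs[, 2]]),
                          nodes = nodes)
    expect_equal(sum(hub_rank(net)$degree), 2 * nrow(pairs))
  }
})
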