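test_that("select_features returns the sorted union and rejects emptiness", {
  expect_identical(select_features(c("a", "b", "c"), c("c", "d")),
                   c("a", "b", "c", "d"))
  expect_identical(select_features(character(0), c("m2", "m1")),
                   c("m1", "m2"))
  expect_length(select_features(letters[1:10], letters[11:20]), 20)
  expect_error(select_features(character(0), character(0)),
               class = "sncnm_pipeline_error")
})

test_that("interval discretization assigns equal-width bins, last closed", {
  x <- matrix(c(0, 0.5, 1.0, 1.5, 3.0), nrow = 1,
              dimnames = list("g1", paste0("c", 1:5)))
  d <- discretize_interval(x, 3)
  expect_equal(unname(d$values[, "g1"]), c(0, 0, 1, 1, 2))
  expect_equal(d$breaks$g1, c(0, 1, 2, 3))
  # the maximum lands in the top bin; two-bin threshold at the midpoint
  x2 <- matrix(c(0, 0.49, 0.51, 1), nrow = 1,
               dimnames = list("g", paste0("c", 1:4)))
  d2 <- discretize_interval(x2, 2)
  expect_equal(unname(d2$values[, "g"]), c(0, 0, 1, 1))
  # constant gene collapses to one flagged level
  x3 <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(x3) <- paste0("c", 1:3)
  d3 <- discretize_interval(x3, 3)
  expect_true(d3$constant["g2"])
  expect_equal(d3$nlev[["g2"]], 1)
  expect_true(all(d3$values[, "g2"] == 0))
})

test_that("bde score matches the hand-derived single-node case", {
  d <- tiny_disc(matrix(c(0L, 0L, 1L), ncol = 1,
                        dimnames = list(NULL, "A")), nlev = 2)
  expect_equal(bde_score(d, make_dag("A")), log(1 / 16), tolerance = 1e-12)
  # zero rows score 0
  d0 <- tiny_disc(matrix(integer(0), ncol = 1, dimnames = list(NULL, "A")),
                  nlev = 2)
  expect_equal(bde_score(d0, make_dag("A")), 0)
})

test_that("bde scorer equals the brute-force marginal likelihood oracle", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(10:100, 1)
    vals <- cbind(A = sample(0:2, n, TRUE), B = sample(0:2, n, TRUE),
                  C = sample(0:2, n, TRUE))
    d <- tiny_disc(vals, nlev = c(3, 3, 3))
    dag <- all_dags(c("A", "B", "C"))[[sample(25, 1)]]
    expect_equal(bde_score(d, dag),
                 brute_bde(d$values, as.list(d$nlev), dag_edges(dag)),
                 tolerance = 1e-9)
  }
})

test_that("likelihood equivalence holds across every 3-node equivalence class", {
  dags <- all_dags(c("A", "B", "C"))
  expect_length(dags, 25)
  set.seed(23)
  for (rep in 1:5) {
    n <- 40
    vals <- cbind(A = sample(0:2, n, TRUE), B = sample(0:2, n, TRUE),
                  C = sample(0:2, n, TRUE))
    d <- tiny_disc(vals, nlev = c(3, 3, 3))
    scores <- vapply(dags, function(g) bde_score(d, g), numeric(1))
    classes <- vapply(dags, mec_signature, character(1))
    for (cl in unique(classes)) {
      expect_lt(diff(range(scores[classes == cl])), 1e-9)
    }
  }
})

test_that("cyclic graphs are rejected before scoring", {
  expect_error(make_dag(c("A", "B"),
                        data.frame(from = c("A", "B"), to = c("B", "A"))),
               class = "sncnm_cyclic_graph")
  expect_error(make_dag("A", data.frame(from = "A", to = "A")),
               class = "sncnm_cyclic_graph")
})

test_that("hill climbing finds the empty graph on independent data", {
  set.seed(41)
  vals <- cbind(A = sample(0:1, 500, TRUE), B = sample(0:1, 500, TRUE))
  d <- tiny_disc(vals, nlev = c(2, 2))
  g <- hill_climb(d)
  expect_equal(nrow(dag_edges(g)), 0)
  # cross-check with exhaustive scoring of the three 2-node DAGs
  empty <- bde_score(d, make_dag(c("A", "B")))
  ab <- bde_score(d, make_dag(c("A", "B"), data.frame(from = "A", to = "B")))
  expect_gt(empty, ab)
})

test_that("hill climbing recovers a strong pairwise dependence", {
  set.seed(42)
  a <- sample(0:1, 500, TRUE)
  b <- ifelse(runif(500) < 0.95, a, 1L - a)
  d <- tiny_disc(cbind(A = a, B = b, C = sample(0:1, 500, TRUE)),
                 nlev = c(2, 2, 2))
  g <- hill_climb(d)
  e <- dag_edges(g)
  found <- any((e$from == "A" & e$to == "B") | (e$from == "B" & e$to == "A"))
  expect_true(found)
  # exhaustive confirmation that the arc is score-optimal
  with_arc <- bde_score(d, make_dag(c("A", "B", "C"),
                                    data.frame(from = "A", to = "B")))
  without <- bde_score(d, make_dag(c("A", "B", "C")))
  expect_gt(with_arc, without)
})

test_that("hill climbing is deterministic, monotone and locally optimal", {
  set.seed(44)
  n <- 300
  a <- sample(0:2, n, TRUE)
  b <- (a + sample(0:1, n, TRUE, prob = c(0.8, 0.2))) %% 3L
  c_ <- (b + sample(0:1, n, TRUE, prob = c(0.7, 0.3))) %% 3L
  d <- tiny_disc(cbind(A = a, B = b, C = c_, D = sample(0:2, n, TRUE)),
                 nlev = rep(3, 4))
  g1 <- hill_climb(d)
  g2 <- hill_climb(d)
  expect_identical(g1$amat, g2$amat)
  trace <- attr(g1, "score_trace")
  if (length(trace) > 1) expect_true(all(diff(trace) > 0))
  # local optimum: no single arc addition, deletion or reversal improves
  final <- bde_score(d, g1)
  expect_equal(final, attr(g1, "score"), tolerance = 1e-9)
  nodes <- g1$nodes
  for (p in nodes) for (ch in nodes) {
    if (p == ch) next
    amat2 <- g1$amat
    if (amat2[p, ch]) {
      amat2[p, ch] <- FALSE                       # deletion
      alt <- try(make_dag(nodes, which_edges(amat2)), silent = TRUE)
      expect_lte(bde_score(d, alt), final + 1e-9)
      amat2[ch, p] <- TRUE                        # reversal
      alt <- try(make_dag(nodes, which_edges(amat2)), silent = TRUE)
      if (!inherits(alt, "try-error")) {
        expect_lte(bde_score(d, alt), final + 1e-9)
      }
    } else if (!g1$amat[ch, p]) {
      amat2[p, ch] <- TRUE                        # addition
      alt <- try(make_dag(nodes, which_edges(amat2)), silent = TRUE)
      if (!inherits(alt, "try-error")) {
        expect_lte(bde_score(d, alt), final + 1e-9)
      }
    }
  }
})

test_that("max_in_degree bounds the learned graph", {
  set.seed(46)
  n <- 400
  base <- sample(0:2, n, TRUE)
  vals <- sapply(1:5, function(i) (base + sample(0:1, n, TRUE)) %% 3L)
  colnames(vals) <- paste0("G", 1:5)
  d <- tiny_disc(vals, nlev = rep(3, 5))
  g <- hill_climb(d, max_in_degree = 1)
  expect_true(all(colSums(g$amat) <= 1))
})

test_that("bootstrap strengths and directions are coherent frequencies", {
  set.seed(51)
  a <- sample(0:1, 400, TRUE)
  b <- ifelse(runif(400) < 0.95, a, 1L - a)
  d <- tiny_disc(cbind(A = a, B = b), nlev = c(2, 2))
  bs <- bootstrap_strength(d, n_boot = 25, sample_frac = 0.5, seed = 7)
  st <- strength_table(bs)
  expect_true(all(st$strength >= 0 & st$strength <= 1))
  expect_true(all(st$direction >= 0 & st$direction <= 1))
  # direction(A->B) + direction(B->A) = 1 for pairs with strength > 0
  ab <- st[st$from == "A" & st$to == "B", ]
  ba <- st[st$from == "B" & st$to == "A", ]
  expect_equal(ab$direction + ba$direction, 1)
  expect_equal(ab$strength, ba$strength)
  # a near-deterministic arc is found in every replicate
  expect_equal(ab$strength, 1)
  # seeded reproducibility
  bs2 <- bootstrap_strength(d, n_boot = 25, sample_frac = 0.5, seed = 7)
  expect_identical(bs$counts, bs2$counts)
})

test_that("averaged_network applies thresholds, ties and cycle repair", {
  mk_bs <- function(counts, nodes, n = 100) {
    structure(list(nodes = nodes, counts = counts, n_replicates = n),
              class = "bootstrap_strength")
  }
  nodes <- c("A", "B", "C")
  cnt <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt["A", "B"] <- 90                      # strength 0.9, direction 1
  cnt["B", "C"] <- 48; cnt["C", "B"] <- 32 # strength 0.8: below threshold
  av <- averaged_network(mk_bs(cnt, nodes), 0.85, 0.5)
  expect_equal(nrow(av$edges), 1)
  expect_equal(av$edges$from, "A")
  # direction 0.6/0.4 orients toward the majority
  cnt2 <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt2["B", "A"] <- 60; cnt2["A", "B"] <- 40
  av2 <- averaged_network(mk_bs(cnt2, nodes), 0.85, 0.5)
  expect_equal(av2$edges$from, "B")
  expect_equal(av2$edges$direction, 0.6)
  # exact tie: lexicographic orientation, flagged, warning raised
  cnt3 <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt3["B", "A"] <- 50; cnt3["A", "B"] <- 50
  expect_warning(av3 <- averaged_network(mk_bs(cnt3, nodes), 0.85, 0.5),
                 "0.5/0.5")
  expect_equal(av3$edges$from, "A")
  expect_true(av3$edges$tie)
  # a directed cycle is repaired by dropping the weakest arc
  cnt4 <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt4["A", "B"] <- 100; cnt4["B", "C"] <- 95; cnt4["C", "A"] <- 88
  expect_warning(av4 <- averaged_network(mk_bs(cnt4, nodes), 0.85, 0.5),
                 "cycle repair")
  expect_equal(nrow(av4$edges), 2)
  expect_false(any(av4$edges$from == "C" & av4$edges$to == "A"))
})

test_that("condition merging assigns provenance and control weights", {
  av <- function(edges, nodes = c("A", "B", "C", "D")) {
    structure(list(nodes = nodes, edges = edges), class = "avg_network")
  }
  e_nt <- data.frame(from = c("A", "B"), to = c("B", "C"),
                     strength = c(0.9, 0.88), direction = c(1, 0.9),
                     tie = FALSE)
  e_hd <- data.frame(from = c("A", "C"), to = c("B", "D"),
                     strength = c(0.95, 0.86), direction = c(1, 0.8),
                     tie = FALSE)
  deg <- data.frame(gene = c("A", "B", "C", "D"),
                    significant = c(TRUE, TRUE, FALSE, FALSE),
                    direction = c("up", "down", "up", "down"))
  m <- merge_condition_networks(av(e_nt), av(e_hd), deg,
                                labels = c("NT", "HD"))
  eAB <- m$edges[m$edges$from == "A" & m$edges$to == "B", ]
  expect_equal(eAB$provenance, "both")
  expect_equal(eAB$weight, 0.9)   # control strength wins when both
  expect_equal(m$edges$provenance[m$edges$to == "C"], "NT")
  expect_equal(m$edges$provenance[m$edges$to == "D"], "HD")
  expect_equal(m$nodes$provenance[m$nodes$node == "D"], "HD")
  expect_equal(m$nodes$regulation[m$nodes$node == "A"], "up")
  expect_equal(m$nodes$regulation[m$nodes$node == "C"], "ns")
  # identical networks: everything is "both"
  m2 <- merge_condition_networks(av(e_nt), av(e_nt))
  expect_true(all(m2$edges$provenance == "both"))
  expect_true(all(m2$nodes$provenance == "both"))
  # disjoint edges: nothing is "both"
  m3 <- merge_condition_networks(av(e_nt[1, ]), av(e_hd[2, ]))
  expect_false(any(m3$edges$provenance == "both"))
})

test_that("key drivers require strictly more than the out-degree threshold", {
  star_edges <- function(hub, n_out, offset = 0) {
    data.frame(from = hub, to = sprintf("t%02d", offset + seq_len(n_out)),
               provenance = "both", weight = 0.9)
  }
  e <- rbind(star_edges("H1", 11), star_edges("H2", 12, 20),
             data.frame(from = c("H1", "X"), to = c("X", "H2"),
                        provenance = "both", weight = 0.9),
             star_edges("M", 10, 40))
  nodes <- unique(c(e$from, e$to))
  net <- structure(list(
    nodes = data.frame(node = nodes, provenance = "both", regulation = "ns"),
    edges = e), class = "merged_network")
  kd <- find_key_drivers(net, hub_out_degree = 10)
  expect_setequal(kd$gene[kd$role == "hub"], c("H1", "H2"))
  expect_false("M" %in% kd$gene)             # exactly 10 out-edges: not a hub
  expect_equal(kd$gene[kd$role == "connector"], "X")
  # undirected reading accepts adjacency in either orientation
  e2 <- rbind(star_edges("H1", 11), star_edges("H2", 12, 20),
              data.frame(from = c("H1", "H2"), to = c("Y", "Y"),
                         provenance = "both", weight = 0.9))
  nodes2 <- unique(c(e2$from, e2$to))
  net2 <- structure(list(
    nodes = data.frame(node = nodes2, provenance = "both",
                       regulation = "ns"),
    edges = e2), class = "merged_network")
  kd_dir <- find_key_drivers(net2, 10)
  expect_false("Y" %in% kd_dir$gene)
  kd_undir <- find_key_drivers(net2, 10, undirected_connector = TRUE)
  expect_true("Y" %in% kd_undir$gene)
})
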