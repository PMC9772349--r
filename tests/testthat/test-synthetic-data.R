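test_that("generate_dag respects bounds, determinism and degenerate cases", {
  expect_error(generate_dag(0, 2), class = "sncnm_invalid_design")
  expect_equal(nrow(generate_dag(1, 0)$edges), 0)
  expect_equal(nrow(generate_dag(5, 0, seed = 3)$edges), 0)
  d1 <- generate_dag(20, 3, seed = 7)
  d2 <- generate_dag(20, 3, seed = 7)
  expect_identical(d1, d2)
  # in-degree bound and acyclicity for a few seeds
  for (s in 1:5) {
    d <- generate_dag(15, 3, seed = s)
    indeg <- tabulate(d$edges[, 2], 15)
    expect_true(all(indeg <= 3))
    expect_silent(sncnm:::topological_order(d))
  }
})

test_that("planted ground truth is internally consistent", {
  des <- synthetic_design(n_genes = 800, cell_types = c(A = 30, B = 30),
                          n_modules = 3, module_size = 40, dag_genes = 12,
                          n_deg = 40, rescue_frac = 0.5, n_cag_genes = 30,
                          seed = 4)
  tr <- plant_ground_truth(des)
  expect_equal(sum(tr$module_labels > 0), 120)
  expect_true(all(table(tr$module_labels[tr$module_labels > 0]) == 40))
  expect_true(all(tr$rescued_genes %in% names(tr$deg_effects)))
  expect_equal(length(tr$rescued_genes), 20)
  # HD DAG is a subset of the NT DAG
  key <- function(e) paste(e$parent, e$child)
  expect_true(all(key(tr$dag_hd) %in% key(tr$dag_nt)))
  # module, DAG, DEG, CAG and mito gene blocks are disjoint
  blocks <- list(names(tr$module_labels)[tr$module_labels > 0],
                 tr$dag_nodes, names(tr$deg_effects),
                 names(tr$cag_slopes), tr$mito_genes)
  expect_equal(length(unique(unlist(blocks))),
               sum(lengths(blocks)))
})

test_that("hd_edge_loss_frac removes the exact fraction of edges", {
  des <- synthetic_design(n_genes = 500, cell_types = c(A = 10),
                          dag_genes = 15, dag_max_parents = 2,
                          hd_edge_loss_frac = 0.5, seed = 9)
  tr <- plant_ground_truth(des)
  expect_equal(nrow(tr$dag_hd), nrow(tr$dag_nt) - round(0.5 * nrow(tr$dag_nt)))
})

test_that("latent means encode the planted effects", {
  des <- synthetic_design(n_genes = 600, cell_types = c(A = 200),
                          n_modules = 1, module_size = 30, dag_genes = 5,
                          n_deg = 20, deg_lfc = 1, rescue_frac = 1,
                          n_cag_genes = 10, seed = 2)
  tr <- plant_ground_truth(des)
  cag <- rep(mean(des$donors$cag), 200)   # at the reference: no CAG term
  lat_nt <- simulate_latent_expression(des, tr, "NT", "vehicle", "A", 200,
                                       cag, seed = 11)
  lat_hd <- simulate_latent_expression(des, tr, "HD", "vehicle", "A", 200,
                                       cag, seed = 11)
  lat_tb <- simulate_latent_expression(des, tr, "HD", "TB", "A", 200,
                                       cag, seed = 11)
  degs <- names(tr$deg_effects)
  # deg_lfc of 1 (log2) shifts latent natural-log means by ln 2
  shift <- colMeans(lat_hd[, degs]) - colMeans(lat_nt[, degs])
  expect_equal(unname(shift), unname(tr$deg_effects * log(2)),
               tolerance = 1e-6)
  # full rescue: treated HD means return to NT means for every DEG gene
  expect_equal(colMeans(lat_tb[, degs]), colMeans(lat_nt[, degs]),
               tolerance = 1e-6)
  # unknown arm label
  expect_error(
    simulate_latent_expression(des, tr, "HD", "placebo", "A", 10, cag[1:10]),
    class = "sncnm_invalid_arm")
})

test_that("module factor drives within-module correlation", {
  des <- synthetic_design(n_genes = 400, cell_types = c(A = 500),
                          n_modules = 2, module_size = 30,
                          module_factor_sd = 1, dag_genes = 0, n_deg = 0,
                          n_cag_genes = 0, seed = 6)
  tr <- plant_ground_truth(des)
  lat <- simulate_latent_expression(des, tr, "NT", "vehicle", "A", 500,
                                    rep(35.5, 500), seed = 3)
  m1 <- names(tr$module_labels)[tr$module_labels == 1]
  m2 <- names(tr$module_labels)[tr$module_labels == 2]
  within <- cor(lat[, m1])
  between <- cor(lat[, m1], lat[, m2])
  expect_gt(mean(within[upper.tri(within)]), mean(between) + 0.2)

  # sd = 0 disables the correlation entirely on the latent scale
  des0 <- synthetic_design(n_genes = 400, cell_types = c(A = 500),
                           n_modules = 2, module_size = 30,
                           module_factor_sd = 0, dag_genes = 0, n_deg = 0,
                           n_cag_genes = 0, seed = 6)
  lat0 <- simulate_latent_expression(des0, plant_ground_truth(des0), "NT",
                                     "vehicle", "A", 500, rep(35.5, 500),
                                     seed = 3)
  # with zero factor variance each module gene is flat across cells: no
  # correlation structure beyond the baseline remains
  expect_true(all(apply(lat0[, m1], 2, sd) == 0))
})

test_that("sample_counts is seeded, zero-preserving and near-Poisson at high dispersion", {
  lat <- matrix(rnorm(200, 1, 0.2), 100, 2,
                dimnames = list(NULL, c("g1", "g2")))
  c1 <- sample_counts(lat, c(0, 0.1), 5, seed = 42)
  c2 <- sample_counts(lat, c(0, 0.1), 5, seed = 42)
  expect_identical(c1, c2)
  # zero latent mean gives all-zero counts
  zero <- sample_counts(matrix(-Inf, 50, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        c(0, 0.1), 5, seed = 1)
  expect_equal(sum(zero), 0)
  # NB -> Poisson limit: variance/mean ~ 1 for a fixed-latent gene
  lat_big <- matrix(log(20), 6000, 1, dimnames = list(NULL, "g"))
  cb <- sample_counts(lat_big, c(0, 0), 1e6, seed = 8)
  vm <- var(as.numeric(cb)) / mean(as.numeric(cb))
  expect_equal(vm, 1, tolerance = 0.2)
})

test_that("generate_dataset has the right shape and is bit-reproducible", {
  des <- synthetic_design(n_genes = 500, cell_types = c(A = 40, B = 40),
                          n_modules = 2, module_size = 25, dag_genes = 8,
                          n_deg = 20, n_cag_genes = 10, seed = 5)
  ds <- generate_dataset(des)
  expect_equal(dim(ds$counts), c(500, 2 * 2 * 2 * 40))
  expect_equal(nrow(ds$metadata), ncol(ds$counts))
  expect_identical(colnames(ds$counts), ds$metadata$barcode)
  expect_true(all(ds$metadata$mito_frac >= 0 & ds$metadata$mito_frac <= 1))
  ds2 <- generate_dataset(des)
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$metadata, ds2$metadata)
  # rescue_frac = 0 means nothing is rescued
  des0 <- synthetic_design(n_genes = 500, cell_types = c(A = 10),
                           rescue_frac = 0, n_deg = 20, n_cag_genes = 10,
                           n_modules = 2, module_size = 25, dag_genes = 8,
                           seed = 5)
  expect_length(plant_ground_truth(des0)$rescued_genes, 0)
})

test_that("planted DEG log2 fold changes are recovered empirically", {
  des <- synthetic_design(n_genes = 800, cell_types = c(A = 500),
                          n_modules = 0, module_size = 0, dag_genes = 0,
                          n_deg = 30, deg_lfc = 1.5, n_cag_genes = 0,
                          seed = 10)
  ds <- generate_dataset(des)
  m <- ds$metadata
  hd <- m$barcode[m$genotype == "HD" & m$treatment == "vehicle"]
  nt <- m$barcode[m$genotype == "NT" & m$treatment == "vehicle"]
  degs <- names(ds$truth$deg_effects)
  mean_cnt <- function(cells) Matrix::rowMeans(ds$counts[degs, cells])
  lfc <- log2(mean_cnt(hd) / mean_cnt(nt))
  expect_true(all(abs(lfc - ds$truth$deg_effects) < 0.25))
})

test_that("invalid designs are rejected", {
  expect_error(synthetic_design(n_genes = 10), class = "sncnm_invalid_design")
  expect_error(synthetic_design(rescue_frac = 1.5),
               class = "sncnm_invalid_design")
  expect_error(synthetic_design(cell_types = c(100)),
               class = "sncnm_invalid_design")
})
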