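#' Describe a synthetic single-nucleus RNA-seq study design
#'
#' Builds the design object consumed by [generate_dataset()]. The generator
#' emulates a two-genotype (NT control vs HD model), two-treatment (vehicle vs
#' thiamine+biotin) single-nucleus study and plants every statistical
#' structure the downstream pipeline stages assume:
#'
#' * correlated gene modules driven by per-cell latent factors,
#' * a causal DAG among a dedicated gene subset, with a fraction of edges
#'   lost in the HD condition,
#' * genotype differential expression with a configurable log2 effect,
#' * a fraction of differential genes whose effect is erased ("rescued")
#'   under treatment,
#' * donor-level expression slopes along CAG repeat length,
#' * designated mitochondrial genes plus a subset of high-mito cells so the
#'   QC filter has true positives.
#'
#' Counts are negative binomial with variance `mu + mu^2/nb_dispersion` on a
#' lognormal per-cell library-size factor. All randomness is derived from
#' `seed` via named substreams ([derive_seed()]).
#'
#' @param n_genes Total number of genes.
#' @param cell_types Named integer vector: cells per cell type within each
#'   genotype-by-treatment arm.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules.
#' @param module_factor_sd Standard deviation of the per-cell module latent
#'   factor (log scale); 0 disables module correlation.
#' @param dag_genes Number of genes carrying the planted causal DAG.
#' @param dag_max_parents Maximum in-degree of the planted DAG.
#' @param edge_effect Structural coefficient of each DAG edge on the latent
#'   log scale.
#' @param dag_noise_sd Standard deviation of the structural-equation noise
#'   term on the latent log scale.
#' @param hd_edge_loss_frac Fraction of DAG edges removed in the HD condition.
#' @param n_deg Number of planted genotype differential genes.
#' @param deg_lfc Absolute planted log2 fold change (HD vs NT).
#' @param rescue_frac Fraction of planted differential genes whose effect is
#'   zeroed in HD cells under treatment.
#' @param n_cag_genes Number of genes with CAG-length-dependent expression.
#' @param cag_slope Scale of the per-gene CAG slopes (log units per repeat);
#'   gene slopes are drawn uniformly in `[-cag_slope, cag_slope]`.
#' @param donors Data frame with columns `donor`, `genotype`, `cag`, `age`,
#'   `sex`; defaults to 4 NT and 4 HD donors with CAG 18 and 43-58.
#' @param regions Character vector of region labels cells are split across.
#' @param nb_dispersion Negative binomial dispersion theta.
#' @param libsize_lognormal_params Length-2 numeric `(mu, sigma)` of the
#'   lognormal per-cell library-size factor.
#' @param mito_gene_frac Fraction of genes designated mitochondrial.
#' @param frac_bad_mito Fraction of cells planted with mito fraction above
#'   the 2 percent QC threshold.
#' @param seed Integer root seed.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 2000,
                             cell_types = c(MSN = 150, OL = 150,
                                            Astro = 150, MG = 150),
                             n_modules = 4,
                             module_size = 50,
                             module_factor_sd = 1,
                             dag_genes = 20,
                             dag_max_parents = 2,
                             edge_effect = 0.8,
                             dag_noise_sd = 1,
                             hd_edge_loss_frac = 0.5,
                             n_deg = 100,
                             deg_lfc = 1.5,
                             rescue_frac = 0.5,
                             n_cag_genes = 100,
                             cag_slope = 0.03,
                             donors = NULL,
                             regions = c("striatum", "cortex"),
                             nb_dispersion = 10,
                             libsize_lognormal_params = c(0, 0.3),
                             mito_gene_frac = 0.01,
                             frac_bad_mito = 0.05,
                             seed = 1L) {
  check_scalar(n_genes, "n_genes", 1, Inf, integer = TRUE)
  check_scalar(n_modules, "n_modules", 0, Inf, integer = TRUE)
  check_scalar(module_size, "module_size", 0, Inf, integer = TRUE)
  check_scalar(module_factor_sd, "module_factor_sd", 0)
  check_scalar(dag_genes, "dag_genes", 0, Inf, integer = TRUE)
  check_scalar(dag_max_parents, "dag_max_parents", 0, Inf, integer = TRUE)
  check_scalar(hd_edge_loss_frac, "hd_edge_loss_frac", 0, 1)
  check_scalar(n_deg, "n_deg", 0, Inf, integer = TRUE)
  check_scalar(rescue_frac, "rescue_frac", 0, 1)
  check_scalar(n_cag_genes, "n_cag_genes", 0, Inf, integer = TRUE)
  check_scalar(nb_dispersion, "nb_dispersion", 1e-8)
  check_scalar(mito_gene_frac, "mito_gene_frac", 0, 1)
  check_scalar(frac_bad_mito, "frac_bad_mito", 0, 1)
  check_scalar(seed, "seed", 0, 2^31 - 1, integer = TRUE)
  if (length(cell_types) < 1 || is.null(names(cell_types)) ||
      any(cell_types < 1)) {
    stop_sncnm("`cell_types` must be a named vector of positive cell counts",
               "sncnm_invalid_design")
  }
  if (is.null(donors)) {
    donors <- data.frame(
      donor = paste0("D", 1:8),
      genotype = rep(c("NT", "HD"), each = 4),
      cag = c(18, 18, 18, 18, 43, 48, 53, 58),
      age = c(62, 58, 65, 60, 55, 49, 61, 52),
      sex = rep(c("M", "F"), 4),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("donor", "genotype", "cag", "age", "sex") %in% names(donors)),
            all(c("NT", "HD") %in% donors$genotype))
  n_mito <- ceiling(mito_gene_frac * n_genes)
  n_special <- n_modules * module_size + dag_genes + n_deg + n_cag_genes + n_mito
  if (n_special > n_genes) {
    stop_sncnm(sprintf(
      "design needs %d genes for modules/DAG/DEG/CAG/mito but n_genes = %d",
      n_special, n_genes), "sncnm_invalid_design")
  }
  structure(list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_factor_sd = module_factor_sd, dag_genes = as.integer(dag_genes),
    dag_max_parents = as.integer(dag_max_parents), edge_effect = edge_effect,
    dag_noise_sd = dag_noise_sd, hd_edge_loss_frac = hd_edge_loss_frac, n_deg = as.integer(n_deg),
    deg_lfc = deg_lfc, rescue_frac = rescue_frac,
    n_cag_genes = as.integer(n_cag_genes), cag_slope = cag_slope,
    donors = donors, regions = regions, nb_dispersion = nb_dispersion,
    libsize_lognormal_params = libsize_lognormal_params,
    mito_gene_frac = mito_gene_frac, frac_bad_mito = frac_bad_mito,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' Generate a random DAG with bounded in-degree
#'
#' Draws a random topological order, then gives each node a number of parents
#' chosen uniformly between 0 and `min(max_parents, rank - 1)`, sampled from
#' the nodes earlier in the order. The result is acyclic by construction and
#' deterministic given the seed.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param max_parents Maximum in-degree (>= 0).
#' @param seed Integer seed.
#' @return A list of class `planted_dag` with elements `n_nodes` and `edges`
#'   (2-column integer matrix, parent then child, possibly 0 rows).
#' @export
generate_dag <- function(n_nodes, max_parents, seed = 1L) {
  check_scalar(n_nodes, "n_nodes", 1, Inf, integer = TRUE)
  check_scalar(max_parents, "max_parents", 0, Inf, integer = TRUE)
  edges <- with_seed(seed, {
    ord <- sample.int(n_nodes)
    out <- list()
    for (i in seq_len(n_nodes)[-1]) {
      k <- sample.int(min(max_parents, i - 1L) + 1L, 1L) - 1L
      if (k > 0) {
        parents <- ord[sample.int(i - 1L, k)]
        out[[length(out) + 1L]] <- cbind(parents, rep(ord[i], k))
      }
    }
    if (length(out)) do.call(rbind, out) else matrix(integer(), ncol = 2)
  })
  dimnames(edges) <- list(NULL, c("parent", "child"))
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "planted_dag")
}

# topological order of a planted_dag; errors if cyclic (cannot happen by
# construction, but the invariant is cheap to keep checked)
topological_order <- function(dag) {
  n <- dag$n_nodes
  indeg <- tabulate(dag$edges[, 2], n)
  kids <- split(dag$edges[, 2], factor(dag$edges[, 1], levels = seq_len(n)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != n) stop_sncnm("graph is cyclic", "sncnm_cyclic_graph")
  ord
}

# deterministic per-gene baseline log-means and cell-type offsets for a design
gene_baselines <- function(design) {
  truth_idx <- gene_index_blocks(design)
  with_seed(derive_seed(design$seed, "baseline"), {
    base <- rnorm(design$n_genes, 0, 0.7)
    # boost structured genes so their signal survives count noise
    base[truth_idx$module] <- base[truth_idx$module] + 1.0
    base[truth_idx$dag] <- base[truth_idx$dag] + 2.5
    base[truth_idx$deg] <- base[truth_idx$deg] + 0.5
    base[truth_idx$cag] <- base[truth_idx$cag] + 0.5
    ct_offset <- matrix(rnorm(design$n_genes * length(design$cell_types), 0, 0.3),
                        nrow = design$n_genes,
                        dimnames = list(NULL, names(design$cell_types)))
    list(base = base, ct_offset = ct_offset)
  })
}

# disjoint gene index blocks: modules, dag, deg, cag from the front,
# mito genes from the back
gene_index_blocks <- function(design) {
  n_mod_genes <- design$n_modules * design$module_size
  i <- 0L
  module <- seq_len(n_mod_genes); i <- n_mod_genes
  dag <- i + seq_len(design$dag_genes); i <- i + design$dag_genes
  deg <- i + seq_len(design$n_deg); i <- i + design$n_deg
  cag <- i + seq_len(design$n_cag_genes)
  n_mito <- ceiling(design$mito_gene_frac * design$n_genes)
  mito <- design$n_genes - seq_len(n_mito) + 1L
  list(module = module, dag = dag, deg = as.integer(deg),
       cag = as.integer(cag), mito = as.integer(sort(mito)))
}

gene_names_for <- function(design) {
  idx <- gene_index_blocks(design)
  nm <- sprintf("Gene%04d", seq_len(design$n_genes))
  nm[idx$mito] <- sprintf("mt-Gene%04d", idx$mito)
  nm
}

#' Plant the ground truth for a synthetic design
#'
#' Draws the module labels, the NT and HD causal DAGs, the signed differential
#' effects, the rescued-gene subset and the per-gene CAG slopes. Deterministic
#' given the design seed.
#'
#' @param design A [synthetic_design()].
#' @return A list of class `ground_truth` with fields `module_labels`
#'   (integer per gene, 0 = unassigned), `dag_nt` / `dag_hd` (edge data frames
#'   with gene-name columns `parent`, `child`), `deg_effects` (named signed
#'   log2 effects), `rescued_genes`, `cag_slopes` (named numeric),
#'   `mito_genes`, `dag_nodes` and `gene_names`.
#' @export
plant_ground_truth <- function(design) {
  idx <- gene_index_blocks(design)
  genes <- gene_names_for(design)
  labels <- integer(design$n_genes)
  if (design$n_modules > 0) {
    labels[idx$module] <- rep(seq_len(design$n_modules),
                              each = design$module_size)
  }
  names(labels) <- genes

  dag <- generate_dag(max(design$dag_genes, 1L), design$dag_max_parents,
                      derive_seed(design$seed, "dag"))
  if (design$dag_genes == 0L) dag$edges <- dag$edges[0, , drop = FALSE]
  n_drop <- round(design$hd_edge_loss_frac * nrow(dag$edges))
  dropped <- with_seed(derive_seed(design$seed, "dag_hd"),
                       if (n_drop > 0) sample.int(nrow(dag$edges), n_drop)
                       else integer(0))
  hd_edges <- dag$edges[setdiff(seq_len(nrow(dag$edges)), dropped), ,
                        drop = FALSE]
  dag_nodes <- genes[idx$dag]
  edge_df <- function(e) data.frame(parent = dag_nodes[e[, 1]],
                                    child = dag_nodes[e[, 2]],
                                    stringsAsFactors = FALSE)

  effects <- with_seed(derive_seed(design$seed, "deg"), {
    sgn <- rep_len(c(1, -1), design$n_deg)
    sgn * design$deg_lfc
  })
  names(effects) <- genes[idx$deg]
  n_resc <- round(design$rescue_frac * design$n_deg)
  rescued <- with_seed(derive_seed(design$seed, "rescue"),
                       if (n_resc > 0) sample(names(effects), n_resc)
                       else character(0))

  slopes <- with_seed(derive_seed(design$seed, "cag"),
                      runif(design$n_cag_genes, -1, 1) * design$cag_slope)
  names(slopes) <- genes[idx$cag]

  structure(list(
    module_labels = labels,
    dag_nt = edge_df(dag$edges),
    dag_hd = edge_df(hd_edges),
    deg_effects = effects,
    rescued_genes = rescued,
    cag_slopes = slopes,
    mito_genes = genes[idx$mito],
    dag_nodes = dag_nodes,
    gene_names = genes
  ), class = "ground_truth")
}

#' Simulate latent log-scale expression means for one arm
#'
#' Produces the cells-by-genes matrix of latent natural-log mean expression
#' for cells of one (genotype, treatment, cell type) arm:
#'
#' * module genes share a per-cell latent factor (loading 1, sd
#'   `module_factor_sd`), with a cell-type-dependent factor mean so modules
#'   correlate with cell identity;
#' * DAG genes follow the linear structural equation
#'   `child = sum(edge_effect * parent) + N(0, 1)` along the NT DAG for NT
#'   cells and the HD (edge-depleted) DAG for HD cells;
#' * HD cells receive the planted differential effects (log2 converted to
#'   natural log); under treatment the effects of rescued genes are zeroed;
#' * CAG genes receive `slope * (CAG - reference CAG)` per cell, where the
#'   reference is the mean donor CAG of the design;
#' * mitochondrial genes are set so that the expected mito count share equals
#'   a per-cell planted fraction (above 2 percent for flagged "bad" cells).
#'
#' @param design A [synthetic_design()].
#' @param truth Matching [plant_ground_truth()] output.
#' @param genotype `"NT"` or `"HD"`.
#' @param treatment `"vehicle"` or `"TB"`.
#' @param cell_type One of `names(design$cell_types)`.
#' @param n_cells Number of cells to simulate.
#' @param donor_cag Numeric vector (length `n_cells`) of donor CAG lengths.
#' @param bad_mito Logical vector (length `n_cells`): plant high mito fraction.
#' @param seed Integer seed for the per-cell draws.
#' @return Numeric matrix, cells x genes, of latent natural-log means.
#' @export
simulate_latent_expression <- function(design, truth, genotype, treatment,
                                       cell_type, n_cells, donor_cag,
                                       bad_mito = rep(FALSE, n_cells),
                                       seed = design$seed) {
  if (!genotype %in% c("NT", "HD") || !treatment %in% c("vehicle", "TB") ||
      !cell_type %in% names(design$cell_types)) {
    stop_sncnm(sprintf("unknown arm: %s/%s/%s", genotype, treatment, cell_type),
               "sncnm_invalid_arm")
  }
  stopifnot(length(donor_cag) == n_cells, length(bad_mito) == n_cells)
  idx <- gene_index_blocks(design)
  bl <- gene_baselines(design)
  lat <- matrix(rep(bl$base + bl$ct_offset[, cell_type], each = n_cells),
                nrow = n_cells)
  colnames(lat) <- truth$gene_names
  ct_i <- match(cell_type, names(design$cell_types))

  with_seed(seed, {
    # correlated modules
    if (design$n_modules > 0) {
      for (m in seq_len(design$n_modules)) {
        shift <- if ((m - 1L) %% length(design$cell_types) + 1L == ct_i)
          design$module_factor_sd else 0
        f <- rnorm(n_cells, shift, design$module_factor_sd)
        members <- idx$module[truth$module_labels[idx$module] == m]
        lat[, members] <- lat[, members] + f
      }
    }
    # causal DAG on latent log expression. Edge loss in the HD condition is
    # marginal-preserving: every node always follows the full-DAG structural
    # equation, but inputs along HD-removed edges come from an independent
    # replica of the parent. Dependence along removed edges vanishes while
    # each gene keeps the identical marginal distribution in both
    # conditions, so edge loss cannot masquerade as a library-size or
    # differential-expression signal.
    if (design$dag_genes > 0) {
      pe <- match(truth$dag_nt$parent, truth$dag_nodes)
      ce <- match(truth$dag_nt$child, truth$dag_nodes)
      kept_key <- paste(truth$dag_hd$parent, truth$dag_hd$child)
      kept <- paste(truth$dag_nt$parent, truth$dag_nt$child) %in% kept_key
      pdag <- structure(list(n_nodes = design$dag_genes,
                             edges = cbind(parent = pe, child = ce)),
                        class = "planted_dag")
      ord <- topological_order(pdag)
      sim_system <- function(inputs = NULL) {
        z <- matrix(0, n_cells, design$dag_genes)
        for (v in ord) {
          ei <- which(ce == v)
          z[, v] <- rnorm(n_cells, 0, design$dag_noise_sd)
          for (e in ei) {
            src <- if (!is.null(inputs) && !kept[e]) inputs else z
            z[, v] <- z[, v] + design$edge_effect * src[, pe[e]]
          }
        }
        z
      }
      z <- if (genotype == "NT") {
        sim_system()
      } else {
        sim_system(inputs = sim_system())   # replica feeds removed edges
      }
      lat[, idx$dag] <- lat[, idx$dag] + z
    }
    # genotype differential effects, natural-log scale; rescue under treatment
    if (genotype == "HD" && design$n_deg > 0) {
      eff <- truth$deg_effects * log(2)
      if (treatment == "TB") eff[names(eff) %in% truth$rescued_genes] <- 0
      lat[, idx$deg] <- lat[, idx$deg] +
        matrix(rep(eff, each = n_cells), nrow = n_cells)
    }
    # CAG-dependent slopes (all donors; NT donors sit near the reference)
    if (design$n_cag_genes > 0) {
      ref <- mean(design$donors$cag)
      lat[, idx$cag] <- lat[, idx$cag] +
        outer(donor_cag - ref, truth$cag_slopes)
    }
    # plant per-cell mitochondrial fractions
    if (length(idx$mito) > 0) {
      f <- ifelse(bad_mito, runif(n_cells, 0.025, 0.08),
                  runif(n_cells, 0.002, 0.015))
      other <- rowSums(exp(lat[, -idx$mito, drop = FALSE]))
      lat[, idx$mito] <- log(f / (1 - f) * other / length(idx$mito))
    }
    lat
  })
}

#' Sample negative binomial UMI counts from latent means
#'
#' Counts for gene g in cell c are drawn `NB(mu = s_c * exp(latent[c, g]),
#' size = nb_dispersion)` where `s_c` is a lognormal per-cell library-size
#' factor; the NB variance is `mu + mu^2 / nb_dispersion`.
#'
#' @param latent Cells x genes matrix of latent natural-log means.
#' @param libsize_lognormal_params Length-2 `(mu, sigma)` of the lognormal
#'   library-size factor.
#' @param nb_dispersion Positive dispersion theta.
#' @param seed Integer seed.
#' @return Sparse integer count matrix (`dgCMatrix`), genes x cells.
#' @export
sample_counts <- function(latent, libsize_lognormal_params = c(0, 0.3),
                          nb_dispersion = 2, seed = 1L) {
  check_scalar(nb_dispersion, "nb_dispersion", 1e-12)
  n_cells <- nrow(latent); n_genes <- ncol(latent)
  counts <- with_seed(seed, {
    s <- rlnorm(n_cells, libsize_lognormal_params[1],
                libsize_lognormal_params[2])
    mu <- exp(latent) * s
    matrix(rnbinom(length(mu), mu = mu, size = nb_dispersion),
           nrow = n_cells)
  })
  out <- methods::as(methods::as(Matrix::Matrix(t(counts)), "generalMatrix"),
                     "CsparseMatrix")
  rownames(out) <- colnames(latent)
  out
}

#' Generate a full synthetic dataset with ground truth
#'
#' Runs [plant_ground_truth()], [simulate_latent_expression()] and
#' [sample_counts()] for every (genotype, treatment, cell type) arm of the
#' design and assembles the count matrix, per-cell metadata and ground truth.
#' Cells are assigned round-robin to the donors of the matching genotype and
#' split across regions; per-cell metadata records sample, donor, cell type,
#' genotype, treatment, region, age, CAG, library size, detected genes and
#' the realized mitochondrial fraction.
#'
#' @param design A [synthetic_design()].
#' @return List with `counts` (sparse genes x cells), `metadata` (data frame,
#'   one row per cell) and `truth` ([plant_ground_truth()] output).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  truth <- plant_ground_truth(design)
  arms <- expand.grid(genotype = c("NT", "HD"),
                      treatment = c("vehicle", "TB"),
                      cell_type = names(design$cell_types),
                      stringsAsFactors = FALSE)
  blocks <- vector("list", nrow(arms))
  meta <- vector("list", nrow(arms))
  for (a in seq_len(nrow(arms))) {
    gt <- arms$genotype[a]; tr <- arms$treatment[a]; ct <- arms$cell_type[a]
    n_cells <- as.integer(design$cell_types[[ct]])
    dn <- design$donors[design$donors$genotype == gt, , drop = FALSE]
    d_i <- rep_len(seq_len(nrow(dn)), n_cells)
    # block the region cycle on the donor cycle so every donor contributes
    # cells to every region (avoids donor-region aliasing)
    region <- design$regions[((seq_len(n_cells) - 1L) %/% nrow(dn)) %%
                               length(design$regions) + 1L]
    arm_key <- paste("arm", gt, tr, ct, sep = ":")
    bad <- with_seed(derive_seed(design$seed, paste0(arm_key, ":mito")),
                     runif(n_cells) < design$frac_bad_mito)
    lat <- simulate_latent_expression(
      design, truth, gt, tr, ct, n_cells, donor_cag = dn$cag[d_i],
      bad_mito = bad, seed = derive_seed(design$seed, paste0(arm_key, ":latent"))
    )
    blocks[[a]] <- sample_counts(
      lat, design$libsize_lognormal_params, design$nb_dispersion,
      seed = derive_seed(design$seed, paste0(arm_key, ":counts"))
    )
    meta[[a]] <- data.frame(
      barcode = sprintf("%s_%s_%s_c%04d", gt, tr, ct, seq_len(n_cells)),
      donor = dn$donor[d_i],
      sample = paste(dn$donor[d_i], region, gt, tr, sep = "_"),
      cell_type = ct, genotype = gt, treatment = tr, region = region,
      age = dn$age[d_i], sex = dn$sex[d_i], cag = dn$cag[d_i],
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(cbind, blocks)
  metadata <- do.call(rbind, meta)
  colnames(counts) <- metadata$barcode
  metadata$library_size <- Matrix::colSums(counts)
  metadata$n_genes_detected <- Matrix::colSums(counts > 0)
  mito <- rownames(counts) %in% truth$mito_genes
  metadata$mito_frac <- as.numeric(
    Matrix::colSums(counts[mito, , drop = FALSE]) /
      pmax(metadata$library_size, 1))
  rownames(metadata) <- metadata$barcode
  list(counts = counts, metadata = metadata, truth = truth)
}
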