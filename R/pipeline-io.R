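#' Read a 10x-style Matrix Market count matrix
#'
#' Reads `matrix.mtx` (genes as rows), a gene file and a barcode file
#' (single-column TSVs), validating that the dimensions agree and the
#' entries are nonnegative integers. Duplicated gene names are suffixed
#' (`.1`, `.2`, ...) with a warning.
#'
#' @param path_mtx Path to the Matrix Market file.
#' @param path_genes Path to the genes TSV (first column used).
#' @param path_barcodes Path to the barcodes TSV (first column used).
#' @return Sparse integer count matrix (`dgCMatrix`), genes x cells.
#' @export
read_counts_mtx <- function(path_mtx, path_genes, path_barcodes) {
  for (p in c(path_mtx, path_genes, path_barcodes)) {
    if (!file.exists(p)) stop_sncnm(paste0("file not found: ", p),
                                    "sncnm_format_error")
  }
  m <- Matrix::readMM(path_mtx)
  genes <- read.delim(path_genes, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(path_barcodes, header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes)) {
    stop_sncnm(sprintf("matrix has %d rows but %d gene names",
                       nrow(m), length(genes)), "sncnm_format_error")
  }
  if (ncol(m) != length(barcodes)) {
    stop_sncnm(sprintf("matrix has %d columns but %d barcodes",
                       ncol(m), length(barcodes)), "sncnm_format_error")
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop_sncnm("counts must be nonnegative integers", "sncnm_format_error")
  }
  if (anyDuplicated(genes)) {
    warning("duplicated gene names; suffixing duplicates")
    genes <- make.unique(genes)
  }
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a synthetic dataset as a 10x-style fixture
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `cell_metadata.tsv` and
#' `ground_truth.json` (module labels, condition edge lists, differential
#' effects, rescued genes, CAG slopes) into a directory.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_tenx_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "cell_metadata.tsv", "ground_truth.json"))
  Matrix::writeMM(dataset$counts, paths[1])
  writeLines(rownames(dataset$counts), paths[2])
  writeLines(colnames(dataset$counts), paths[3])
  write.table(dataset$metadata, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(list(
    module_labels = as.list(tr$module_labels[tr$module_labels > 0]),
    dag_nt = tr$dag_nt, dag_hd = tr$dag_hd,
    deg_effects = as.list(tr$deg_effects),
    rescued_genes = tr$rescued_genes,
    cag_slopes = as.list(tr$cag_slopes),
    mito_genes = tr$mito_genes
  ), paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a merged network as GraphML
#'
#' Nodes carry `provenance`, `regulation` and (when computed) a
#' `key_driver_role` attribute; edges carry `provenance` and numeric
#' `weight`. The file round-trips losslessly through
#' [read_network_graphml()].
#'
#' @param net A `merged_network`.
#' @param path Output file path.
#' @param key_drivers Optional [find_key_drivers()] table.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path, key_drivers = NULL) {
  stopifnot(inherits(net, "merged_network"))
  role <- rep("none", nrow(net$nodes))
  if (!is.null(key_drivers) && nrow(key_drivers)) {
    hit <- match(net$nodes$node, key_drivers$gene)
    role[!is.na(hit)] <- key_drivers$role[hit[!is.na(hit)]]
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(net$nodes$node,
                     provenance = net$nodes$provenance,
                     regulation = net$nodes$regulation,
                     key_driver_role = role)
  if (nrow(net$edges)) {
    g <- g + igraph::edges(rbind(net$edges$from, net$edges$to),
                           provenance = net$edges$provenance,
                           weight = net$edges$weight)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a merged network from GraphML
#'
#' Inverse of [write_network_graphml()].
#'
#' @param path GraphML file path.
#' @return A `merged_network` (with attribute `key_driver_role` on nodes).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(node = va$name, provenance = va$provenance,
                      regulation = va$regulation,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(
    from = as.character(el[, 1]), to = as.character(el[, 2]),
    provenance = ea$provenance %||% character(nrow(el)),
    weight = as.numeric(ea$weight %||% numeric(nrow(el))),
    stringsAsFactors = FALSE
  )
  out <- structure(list(nodes = nodes, edges = edges),
                   class = "merged_network")
  attr(out, "key_driver_role") <- va$key_driver_role
  out
}

# default stage parameters; every entry is validated by validate_config
default_config <- function() {
  list(
    qc_min_genes = 200, qc_max_genes = 6000, qc_max_mito = 0.02,
    deg_min_frac = 0.25, deg_alpha = 0.05,
    gene_min_frac = 0.25, scale_factor = 1e4,
    wgcna_powers = c(2, 4, 6, 8, 10, 12), wgcna_min_module_size = 30,
    wgcna_cut_height = 0.99, wgcna_merge_cor = 0.75,
    wgcna_max_cells = 10000,
    bnet_n_boot = 200, bnet_sample_frac = 0.5, bnet_iss = 1,
    bnet_n_bins = 3, bnet_strength_thr = 0.85, bnet_direction_thr = 0.5,
    bnet_max_features = 60,
    hub_out_degree = 10,
    rescue_eps = 1,
    cag_covariates = c("age", "sex", "batch", "region"),
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Merges user settings over the documented defaults, rejecting unknown keys
#' and out-of-range values before any stage runs.
#'
#' @param config Named list of overrides (may be empty).
#' @return The merged, validated configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_sncnm(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
               "sncnm_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  check_scalar(cfg$qc_min_genes, "qc_min_genes", 1)
  check_scalar(cfg$qc_max_genes, "qc_max_genes", cfg$qc_min_genes)
  check_scalar(cfg$qc_max_mito, "qc_max_mito", 0, 1)
  check_scalar(cfg$deg_min_frac, "deg_min_frac", 0, 1)
  check_scalar(cfg$deg_alpha, "deg_alpha", 0, 1)
  check_scalar(cfg$gene_min_frac, "gene_min_frac", 1e-12, 1)
  check_scalar(cfg$bnet_n_boot, "bnet_n_boot", 1, Inf, integer = TRUE)
  check_scalar(cfg$bnet_sample_frac, "bnet_sample_frac", 1e-12, 1)
  check_scalar(cfg$bnet_iss, "bnet_iss", 1e-12)
  check_scalar(cfg$bnet_n_bins, "bnet_n_bins", 2, Inf, integer = TRUE)
  check_scalar(cfg$bnet_strength_thr, "bnet_strength_thr", 0, 1)
  check_scalar(cfg$bnet_direction_thr, "bnet_direction_thr", 0, 1)
  check_scalar(cfg$hub_out_degree, "hub_out_degree", 0)
  check_scalar(cfg$rescue_eps, "rescue_eps", 0)
  check_scalar(cfg$seed, "seed", 0, 2^31 - 1, integer = TRUE)
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' End-to-end orchestration on a synthetic design: simulate, QC, normalize,
#' genotype DEGs per cell type, co-expression modules on control cells,
#' feature selection, per-condition Bayesian networks with bootstrap
#' averaging, merging and key-driver extraction, rescue analysis, and CAG
#' pseudobulk regression. Outputs (fixture, DEG tables, networks, manifest)
#' are written under `out_dir`; the JSON manifest records stage parameters,
#' seeds and md5 hashes of every written file.
#'
#' @param design A [synthetic_design()]; its seed drives all stages.
#' @param out_dir Output directory.
#' @param config Named list of [validate_config()] overrides.
#' @param cell_types_for_bnet Cell types to learn networks for (default:
#'   the first cell type of the design).
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(design, out_dir, config = list(),
                         cell_types_for_bnet = names(design$cell_types)[1]) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  written <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_sncnm(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                 "sncnm_pipeline_error")
    })
    stages <<- c(stages, name)
    res
  }

  ds <- run_stage("simulate", generate_dataset(design))
  written <- c(written, run_stage("write_fixture",
                                  write_tenx_fixture(ds, file.path(out_dir, "fixture"))))

  qc <- run_stage("qc", filter_cells(ds$counts, ds$metadata,
                                     cfg$qc_min_genes, cfg$qc_max_genes,
                                     cfg$qc_max_mito))
  norm <- run_stage("normalize", log_normalize(qc$counts, cfg$scale_factor))
  kept_genes <- run_stage("gene_filter",
                          filter_genes_min_frac(qc$counts, cfg$gene_min_frac))

  # genotype DEGs per cell type (vehicle arms)
  degs <- run_stage("deg", {
    lapply(setNames(nm = names(design$cell_types)), function(ct) {
      g1 <- which(qc$meta$cell_type == ct & qc$meta$genotype == "HD" &
                    qc$meta$treatment == "vehicle")
      g2 <- which(qc$meta$cell_type == ct & qc$meta$genotype == "NT" &
                    qc$meta$treatment == "vehicle")
      wilcoxon_deg(norm, g1, g2, cfg$deg_min_frac, cfg$deg_alpha)
    })
  })
  for (ct in names(degs)) {
    f <- file.path(out_dir, paste0("deg_", ct, ".tsv"))
    write.table(degs[[ct]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  # modules on control cells over filtered genes
  modules <- run_stage("modules", {
    nt <- which(qc$meta$genotype == "NT")
    if (length(nt) > cfg$wgcna_max_cells) {
      nt <- with_seed(derive_seed(cfg$seed, "wgcna_subsample"),
                      sample(nt, cfg$wgcna_max_cells))
    }
    expr <- as.matrix(norm[kept_genes, nt, drop = FALSE])
    pw <- pick_soft_threshold(expr, cfg$wgcna_powers)
    tom <- tom_similarity(signed_adjacency(expr, pw$power))
    ms <- detect_modules(tom, expr, cfg$wgcna_min_module_size,
                         cfg$wgcna_cut_height, cfg$wgcna_merge_cor)
    attr(ms, "power") <- pw$power
    ms
  })
  mod_tab <- data.frame(gene = names(modules$labels),
                        module = unname(modules$labels))
  f <- file.path(out_dir, "modules.tsv")
  write.table(mod_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  # per-condition networks and merge, for each requested cell type
  networks <- run_stage("bnet", {
    lapply(setNames(nm = cell_types_for_bnet), function(ct) {
      deg_sig <- degs[[ct]]$gene[degs[[ct]]$significant]
      mod_genes <- names(modules$labels)[modules$labels > 0]
      feats <- select_features(intersect(deg_sig, kept_genes), mod_genes)
      if (length(feats) > cfg$bnet_max_features) {
        # keep the strongest features: DEGs by adjusted p, then module genes
        ranked <- degs[[ct]][order(degs[[ct]]$p_adj), "gene"]
        feats <- head(unique(c(intersect(ranked, feats), feats)),
                      cfg$bnet_max_features)
        feats <- sort(feats)
      }
      cells_ct <- which(qc$meta$cell_type == ct &
                          qc$meta$treatment == "vehicle")
      disc_all <- discretize_interval(norm[feats, cells_ct, drop = FALSE],
                                      cfg$bnet_n_bins)
      per_cond <- lapply(c(NT = "NT", HD = "HD"), function(gt) {
        rows <- qc$meta$genotype[cells_ct] == gt
        sub <- disc_all
        sub$values <- disc_all$values[rows, , drop = FALSE]
        bs <- bootstrap_strength(sub, cfg$bnet_n_boot, cfg$bnet_sample_frac,
                                 cfg$bnet_iss,
                                 seed = derive_seed(cfg$seed,
                                                    paste0("bnet:", ct, ":", gt)))
        averaged_network(bs, cfg$bnet_strength_thr, cfg$bnet_direction_thr)
      })
      merged <- merge_condition_networks(per_cond$NT, per_cond$HD,
                                         deg = degs[[ct]],
                                         labels = c("NT", "HD"))
      drivers <- find_key_drivers(merged, cfg$hub_out_degree)
      list(nt = per_cond$NT, hd = per_cond$HD, merged = merged,
           key_drivers = drivers)
    })
  })
  for (ct in names(networks)) {
    f <- file.path(out_dir, paste0("network_", ct, ".graphml"))
    write_network_graphml(networks[[ct]]$merged, f,
                          networks[[ct]]$key_drivers)
    written <- c(written, f)
  }

  rescue <- run_stage("rescue", {
    lapply(setNames(nm = names(design$cell_types)), function(ct) {
      con <- run_contrasts(norm, qc$meta, ct, min_frac = cfg$deg_min_frac,
                           alpha = cfg$deg_alpha)
      cls <- classify_rescue(con$genotype, con$treatment)
      red <- deg_reduction(sum(con$residual$significant),
                           sum(con$genotype$significant), cfg$rescue_eps)
      list(classification = cls, reduction = red,
           overlap = overlap_significance(con$genotype, con$treatment))
    })
  })

  cag <- run_stage("cag", {
    pb <- pseudobulk_sum(qc$counts, qc$meta,
                         cell_type = names(design$cell_types)[1])
    cag_fit(pb, covariates = cfg$cag_covariates)
  })
  f <- file.path(out_dir, "cag_fit.tsv")
  write.table(cag, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sncnm")),
    seed = design$seed,
    config = cfg[order(names(cfg))],
    stages = stages,
    n_cells_post_qc = ncol(qc$counts),
    n_genes_filtered = length(kept_genes),
    files = lapply(setNames(nm = basename(written)), function(b) {
      p <- written[basename(written) == b][1]
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(
    dataset = ds, qc = qc, norm = norm, degs = degs, modules = modules,
    networks = networks, rescue = rescue, cag = cag
  )))
}
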