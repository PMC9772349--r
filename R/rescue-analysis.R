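#' Run the three treatment-rescue contrasts for one cell type
#'
#' For one cell type with all four (genotype x treatment) arms present, runs
#' three Wilcoxon contrasts via [wilcoxon_deg()]:
#'
#' * genotype effect: case + vehicle vs control + vehicle,
#' * treatment effect: case + treated vs case + vehicle,
#' * residual effect: case + treated vs control + vehicle (what remains of
#'   the disease signature after treatment).
#'
#' @param norm Log-normalized matrix, genes x cells.
#' @param meta Per-cell metadata with columns `cell_type`, `genotype`,
#'   `treatment` aligned with the columns of `norm`.
#' @param cell_type Cell type label to analyze.
#' @param case,ctrl Genotype labels (defaults `"HD"`, `"NT"`).
#' @param treated,vehicle Treatment labels (defaults `"TB"`, `"vehicle"`).
#' @param min_frac,alpha Passed to [wilcoxon_deg()].
#' @return List of three DEG tables: `genotype`, `treatment`, `residual`.
#' @export
run_contrasts <- function(norm, meta, cell_type, case = "HD", ctrl = "NT",
                          treated = "TB", vehicle = "vehicle",
                          min_frac = 0.25, alpha = 0.05) {
  stopifnot(ncol(norm) == nrow(meta))
  arm <- function(gt, tr) {
    cells <- which(meta$cell_type == cell_type & meta$genotype == gt &
                     meta$treatment == tr)
    if (length(cells) < 3) {
      stop_sncnm(sprintf("missing or underpowered arm: %s/%s/%s",
                         cell_type, gt, tr), "sncnm_missing_arm")
    }
    cells
  }
  cv <- arm(case, vehicle); nv <- arm(ctrl, vehicle); ct <- arm(case, treated)
  list(
    genotype = wilcoxon_deg(norm, cv, nv, min_frac = min_frac, alpha = alpha),
    treatment = wilcoxon_deg(norm, ct, cv, min_frac = min_frac, alpha = alpha),
    residual = wilcoxon_deg(norm, ct, nv, min_frac = min_frac, alpha = alpha)
  )
}

#' Significance of the genotype/treatment DEG overlap
#'
#' Upper-tail hypergeometric test for the overlap between the significant
#' genes of the genotype and treatment contrasts, over the universe of genes
#' tested in both.
#'
#' @param deg_genotype,deg_treatment [wilcoxon_deg()] tables.
#' @return List with `overlap`, `p` and the `universe` size.
#' @export
overlap_significance <- function(deg_genotype, deg_treatment) {
  universe <- intersect(deg_genotype$gene, deg_treatment$gene)
  a <- intersect(deg_genotype$gene[deg_genotype$significant], universe)
  b <- intersect(deg_treatment$gene[deg_treatment$significant], universe)
  h <- hypergeometric_overlap(a, b, universe)
  c(h, list(universe = length(universe)))
}

#' Classify rescue by Z-scored fold-change discordance
#'
#' For the genes significant in both the genotype and the treatment
#' contrasts, compares the Z-scored log2 fold changes of the two effects:
#' opposite signs mean the treatment pushed expression back toward control
#' (rescued), same signs mean it pushed further (exacerbated), an exact zero
#' in either is unchanged. Two summary fractions are reported: the
#' discordance fraction `rescued / (rescued + exacerbated)` over the overlap
#' genes, and the disease-level fraction `rescued / (number of significant
#' genotype DEGs)`, which is 0 when the treatment touches nothing and
#' approaches 1 under a full rescue.
#'
#' @param deg_genotype,deg_treatment [wilcoxon_deg()] tables for the
#'   genotype and treatment contrasts of one cell type.
#' @return List with `table` (data frame `gene`, `z_genotype`, `z_treatment`,
#'   `class`), `rescue_fraction` (discordance fraction over the overlap; NA
#'   when the overlap is empty) and `rescue_fraction_of_disease`.
#' @export
classify_rescue <- function(deg_genotype, deg_treatment) {
  z_g <- zscore_log2fc(deg_genotype)
  z_t <- zscore_log2fc(deg_treatment)
  n_disease <- sum(deg_genotype$significant)
  genes <- intersect(deg_genotype$gene[deg_genotype$significant],
                     deg_treatment$gene[deg_treatment$significant])
  if (length(genes) == 0) {
    warning("no genes significant in both contrasts")
    return(list(table = data.frame(gene = character(0),
                                   z_genotype = numeric(0),
                                   z_treatment = numeric(0),
                                   class = character(0)),
                rescue_fraction = NA_real_,
                rescue_fraction_of_disease =
                  if (n_disease > 0) 0 else NA_real_))
  }
  zg <- z_g[genes]; zt <- z_t[genes]
  cls <- ifelse(zg == 0 | zt == 0, "unchanged",
                ifelse(sign(zg) != sign(zt), "rescued", "exacerbated"))
  tab <- data.frame(gene = genes, z_genotype = unname(zg),
                    z_treatment = unname(zt), class = cls,
                    stringsAsFactors = FALSE)
  n_r <- sum(cls == "rescued"); n_e <- sum(cls == "exacerbated")
  list(table = tab,
       rescue_fraction = if (n_r + n_e > 0) n_r / (n_r + n_e) else NA_real_,
       rescue_fraction_of_disease =
         if (n_disease > 0) n_r / n_disease else NA_real_)
}

#' DEG-count reduction under treatment
#'
#' Log2 ratio of the number of residual DEGs (case + treated vs control +
#' vehicle) to the number of vehicle DEGs (case + vehicle vs control +
#' vehicle), with a pseudocount of 1 on both sides so zero counts stay
#' finite. Negative values mean treatment reduced the disease signature.
#'
#' @param n_treated Count of significant residual DEGs.
#' @param n_vehicle Count of significant vehicle DEGs.
#' @param eps Pseudocount (default 1).
#' @return List with `n_vehicle`, `n_treated` and `log2_ratio`.
#' @export
deg_reduction <- function(n_treated, n_vehicle, eps = 1) {
  check_scalar(n_treated, "n_treated", 0)
  check_scalar(n_vehicle, "n_vehicle", 0)
  list(n_vehicle = n_vehicle, n_treated = n_treated,
       log2_ratio = log2((n_treated + eps) / (n_vehicle + eps)))
}
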