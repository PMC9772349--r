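#' Donor-by-region pseudobulk aggregation
#'
#' Sums raw UMI counts over the cells of each (donor, region) group —
#' optionally restricted to one cell type — then log-normalizes each
#' pseudo-sample (`ln(1 + 1e4 * c / total)`) and scales each gene to zero
#' mean and unit variance across samples. Groups left with no cells are
#' dropped with a warning.
#'
#' @param counts Sparse count matrix, genes x cells.
#' @param meta Per-cell metadata with columns `donor`, `region`, `cell_type`,
#'   and per-donor covariates `cag`, `age`, `sex` (plus optional `batch`).
#' @param cell_type Optional cell type filter.
#' @param scale_factor Normalization scale factor (default 1e4).
#' @return Object of class `pseudobulk`: list with `values` (genes x samples
#'   scaled matrix), `raw` (genes x samples integer sums) and `samples`
#'   (data frame of per-sample covariates: `donor`, `region`, `cag`, `age`,
#'   `sex`, `batch`, `n_cells`).
#' @export
pseudobulk_sum <- function(counts, meta, cell_type = NULL,
                           scale_factor = 1e4) {
  stopifnot(ncol(counts) == nrow(meta),
            all(c("donor", "region") %in% names(meta)))
  keep <- if (is.null(cell_type)) rep(TRUE, nrow(meta)) else
    meta$cell_type == cell_type
  if (!any(keep)) {
    stop_sncnm("no cells left after cell-type filter", "sncnm_pipeline_error")
  }
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  grp <- interaction(meta$donor, meta$region, sep = "_", drop = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), nlevels(grp)))
  raw <- as.matrix(counts %*% ind)
  colnames(raw) <- levels(grp)
  totals <- colSums(raw)
  if (any(totals == 0)) {
    warning("dropping pseudo-samples with zero counts")
    raw <- raw[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- log1p(sweep(raw, 2, scale_factor / totals, `*`))
  gene_sd <- apply(norm, 1, sd)
  scaled <- t(scale(t(norm)))
  scaled[!is.finite(scaled)] <- 0
  if (ncol(raw) == 1) {
    warning("single pseudo-sample: scaled values degenerate to zero")
  }
  first <- meta[!duplicated(grp), , drop = FALSE]
  ord <- match(colnames(raw), as.character(grp[!duplicated(grp)]))
  first <- first[ord, , drop = FALSE]
  samples <- data.frame(
    sample = colnames(raw),
    donor = first$donor, region = first$region,
    cag = first$cag, age = first$age, sex = first$sex,
    batch = if ("batch" %in% names(meta)) first$batch else "b1",
    n_cells = as.integer(table(grp)[colnames(raw)]),
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  structure(list(values = scaled, raw = raw, gene_sd = gene_sd,
                 samples = samples),
            class = "pseudobulk")
}

#' Per-gene regression of pseudobulk expression on CAG length
#'
#' Ordinary least squares of each gene's scaled pseudobulk expression on
#' `[intercept, CAG, age, sex, batch dummies, region dummies]`, with a
#' two-sided t-test on the CAG coefficient and Benjamini-Hochberg adjustment
#' across genes. Covariates can be dropped via `covariates`. Because the
#' response is scaled to unit variance per gene, `beta_cag` is in standard
#' deviations per CAG repeat; `beta_log` de-standardizes it back to
#' log-expression units per repeat (`beta_cag * sd(gene)`), the scale on
#' which effect sizes are comparable across genes.
#'
#' @param pb A [pseudobulk_sum()] result.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param covariates Character subset of `c("age", "sex", "batch", "region")`
#'   to adjust for (constant columns are dropped automatically).
#' @return Data frame with columns `gene`, `beta_cag`, `beta_log`, `se`,
#'   `t`, `p`, `p_adj`, `significant`.
#' @export
cag_fit <- function(pb, alpha = 0.05,
                    covariates = c("age", "sex", "batch", "region")) {
  stopifnot(inherits(pb, "pseudobulk"))
  s <- pb$samples
  design <- list(`(Intercept)` = rep(1, nrow(s)), cag = s$cag)
  if ("age" %in% covariates) design$age <- s$age
  if ("sex" %in% covariates) design$sex <- as.integer(factor(s$sex)) - 1L
  for (cv in intersect(c("batch", "region"), covariates)) {
    f <- factor(s[[cv]])
    if (nlevels(f) > 1) {
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      for (j in seq_len(ncol(mm))) design[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  # drop constant covariate columns (not CAG: a constant CAG is an error)
  keep <- vapply(names(design), function(nm)
    nm %in% c("(Intercept)", "cag") || var(design[[nm]]) > 0, logical(1))
  X <- do.call(cbind, design[keep])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_sncnm(paste0("design matrix is rank deficient; aliased columns: ",
                      paste(aliased, collapse = ", ")),
               "sncnm_collinear_design")
  }
  df_res <- nrow(X) - ncol(X)
  if (df_res < 1) {
    stop_sncnm("more design columns than pseudo-samples",
               "sncnm_collinear_design")
  }
  y <- t(pb$values)                      # samples x genes
  coefs <- qr.coef(qx, y)
  resid <- y - X %*% coefs
  sigma2 <- colSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qx))
  cag_col <- match("cag", colnames(X))
  se <- sqrt(sigma2 * xtx_inv[cag_col, cag_col])
  beta <- coefs[cag_col, ]
  t_stat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * pt(abs(t_stat), df = df_res, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  data.frame(
    gene = rownames(pb$values),
    beta_cag = unname(beta),
    beta_log = unname(beta * pb$gene_sd),
    se = unname(se), t = unname(t_stat),
    p = unname(p), p_adj = unname(p_adj),
    significant = unname(p_adj < alpha),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify genes by CAG-coefficient significance and sign across two
#' cell types
#'
#' Given the CAG fits of two cell populations (e.g. OPCs and OLs), assigns
#' each shared gene to a significance category (`first_only`, `second_only`,
#' `both`, `neither`) and, for genes significant somewhere, a quadrant from
#' the two coefficient signs (`upper_right` = positive in both,
#' `lower_left` = negative in both, the two mixed-sign quadrants otherwise).
#'
#' @param fit_a,fit_b [cag_fit()] tables over a shared gene universe.
#' @param labels Length-2 character names for the two populations.
#' @return Data frame with columns `gene`, `beta_a`, `beta_b`, `category`,
#'   `quadrant`.
#' @export
classify_cag_quadrants <- function(fit_a, fit_b, labels = c("OPC", "OL")) {
  genes <- intersect(fit_a$gene, fit_b$gene)
  ia <- match(genes, fit_a$gene); ib <- match(genes, fit_b$gene)
  sig_a <- fit_a$significant[ia]; sig_b <- fit_b$significant[ib]
  ba <- fit_a$beta_cag[ia]; bb <- fit_b$beta_cag[ib]
  category <- ifelse(sig_a & sig_b, "both",
                     ifelse(sig_a, paste0(labels[1], "_only"),
                            ifelse(sig_b, paste0(labels[2], "_only"),
                                   "neither")))
  quadrant <- ifelse(ba >= 0 & bb >= 0, "upper_right",
                     ifelse(ba < 0 & bb < 0, "lower_left",
                            ifelse(ba >= 0, "lower_right", "upper_left")))
  quadrant[category == "neither"] <- NA_character_
  data.frame(gene = genes, beta_a = ba, beta_b = bb,
             category = category, quadrant = quadrant,
             stringsAsFactors = FALSE)
}
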