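#' Filter cells on detected genes and mitochondrial fraction
#'
#' Keeps nuclei with `min_genes <= detected genes <= max_genes` (both bounds
#' inclusive) and mitochondrial read fraction `<= max_mito`. Defaults match
#' the standard single-nucleus thresholds (200-6000 genes, 2 percent mito).
#' Cell order is preserved; the operation is idempotent.
#'
#' @param counts Sparse integer count matrix, genes x cells.
#' @param meta Per-cell metadata with a `mito_frac` column; rows aligned with
#'   the columns of `counts`.
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito Inclusive upper bound on the mitochondrial fraction.
#' @return List with the filtered `counts` and `meta`.
#' @export
filter_cells <- function(counts, meta, min_genes = 200, max_genes = 6000,
                         max_mito = 0.02) {
  check_scalar(min_genes, "min_genes", 1)
  check_scalar(max_genes, "max_genes", min_genes)
  check_scalar(max_mito, "max_mito", 0, 1)
  stopifnot(ncol(counts) == nrow(meta))
  if (!"mito_frac" %in% names(meta)) {
    stop_sncnm("`meta` must contain a `mito_frac` column",
               "sncnm_config_error")
  }
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= min_genes & detected <= max_genes &
    meta$mito_frac <= max_mito
  if (!any(keep)) warning("no cells pass QC filters")
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Keep genes detected in at least a fraction of cells
#'
#' Returns the genes with at least one count in at least `min_frac` of all
#' cells (fraction compared with `>=`, so the boundary is kept). This is the
#' feature filter applied before co-expression and network modeling.
#'
#' @param counts Sparse count matrix, genes x cells.
#' @param min_frac Minimum detection fraction in (0, 1].
#' @return Character vector of retained gene names.
#' @export
filter_genes_min_frac <- function(counts, min_frac = 0.25) {
  check_scalar(min_frac, "min_frac", 1e-12, 1)
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  rownames(counts)[frac >= min_frac]
}

#' Log-normalize UMI counts
#'
#' Scales each cell to `scale_factor` total counts and applies
#' `log1p`: `value = ln(1 + scale_factor * count / cell_total)` — the
#' standard single-cell log-normalization.
#'
#' @param counts Sparse count matrix, genes x cells.
#' @param scale_factor Positive scale factor (default 1e4).
#' @return Sparse numeric matrix of the same shape.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  check_scalar(scale_factor, "scale_factor", 1e-12)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop_sncnm("cells with zero total counts cannot be normalized",
               "sncnm_degenerate_cell")
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

# two-sided Wilcoxon rank-sum p-value for one gene.
# exact (no ties, both groups <= exact_max) via the null rank-sum
# distribution, otherwise normal approximation with tie and continuity
# correction — mirroring the standard wilcox.test conventions.
wilcox_p <- function(x, y, exact_max = 25) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- if (w > n1 * n2 / 2) {
      pwilcox(w - 1, n1, n2, lower.tail = FALSE)
    } else {
      pwilcox(w, n1, n2)
    }
    return(min(2 * p, 1))
  }
  nties <- table(r)
  z <- w - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - sum(nties^3 - nties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  if (sigma == 0) return(1)
  correction <- sign(z) * 0.5
  z <- (z - correction) / sigma
  min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Tests each gene expressed (count > 0) in at least `min_frac` of either
#' group, using a two-sided Wilcoxon rank-sum test on log-normalized values:
#' exact when both groups have at most 25 cells and there are no ties,
#' otherwise a normal approximation with tie and continuity correction.
#' The log2 fold change is the fold change of mean de-logged expression,
#' `log2((mean(expm1(x1)) + 1e-9) / (mean(expm1(x2)) + 1e-9))`.
#' P-values are Benjamini-Hochberg adjusted across the tested genes only.
#'
#' @param norm Log-normalized matrix (genes x cells), e.g. [log_normalize()].
#' @param group1,group2 Disjoint cell identifiers (column names or indices).
#' @param min_frac Expression-fraction filter applied per group (OR rule).
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame with columns `gene`, `log2fc`, `pct1`, `pct2`, `p`,
#'   `p_adj`, `significant`, `direction` (up = higher in `group1`).
#' @export
wilcoxon_deg <- function(norm, group1, group2, min_frac = 0.25, alpha = 0.05) {
  check_scalar(min_frac, "min_frac", 0, 1)
  check_scalar(alpha, "alpha", 0, 1)
  if (length(intersect(group1, group2)) > 0) {
    stop_sncnm("groups must be disjoint", "sncnm_invalid_groups")
  }
  if (length(group1) < 3 || length(group2) < 3) {
    stop_sncnm("each group needs at least 3 cells", "sncnm_invalid_groups")
  }
  x1 <- as.matrix(norm[, group1, drop = FALSE])
  x2 <- as.matrix(norm[, group2, drop = FALSE])
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  tested <- pct1 >= min_frac | pct2 >= min_frac
  genes <- rownames(norm)[tested]
  m1 <- rowMeans(expm1(x1[tested, , drop = FALSE]))
  m2 <- rowMeans(expm1(x2[tested, , drop = FALSE]))
  log2fc <- log2((m1 + 1e-9) / (m2 + 1e-9))
  p <- vapply(genes, function(g) wilcox_p(x1[g, ], x2[g, ]), numeric(1))
  p_adj <- bh_adjust(p)
  data.frame(
    gene = genes,
    log2fc = log2fc,
    pct1 = pct1[tested],
    pct2 = pct2[tested],
    p = unname(p),
    p_adj = p_adj,
    significant = p_adj < alpha,
    direction = ifelse(log2fc >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement and
#' capping at 1, after validating the input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_sncnm("p-values must be finite numbers in [0, 1]",
               "sncnm_invalid_pvalues")
  }
  p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the given overlap between two gene sets
#' drawn from a common universe: `P(X >= overlap)` with
#' `X ~ Hypergeometric(|universe|, |A|, |B|)` (upper tail inclusive).
#'
#' @param setA,setB Character vectors of genes, subsets of `universe`.
#' @param universe Character vector, the analyzed-gene universe.
#' @return List with `overlap` (count) and `p`.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  if (length(universe) == 0) {
    stop_sncnm("universe must be nonempty", "sncnm_invalid_universe")
  }
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop_sncnm("both sets must be subsets of the universe",
               "sncnm_invalid_universe")
  }
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, length(setA), length(universe) - length(setA),
              length(setB), lower.tail = FALSE)
  list(overlap = k, p = min(p, 1))
}

#' Z-score log2 fold changes across a DEG table
#'
#' Standardizes the `log2fc` column to zero mean and unit population
#' (n-denominator) standard deviation over the table's tested genes; this is
#' the scale on which genotype and treatment effects are compared in the
#' rescue analysis.
#'
#' @param deg A [wilcoxon_deg()] table (>= 2 genes).
#' @return Named numeric vector of Z-scores (names = genes).
#' @export
zscore_log2fc <- function(deg) {
  stopifnot(is.data.frame(deg), nrow(deg) >= 2)
  s <- sd_pop(deg$log2fc)
  if (s == 0) {
    warning("log2 fold changes have zero variance; returning zeros")
    return(setNames(numeric(nrow(deg)), deg$gene))
  }
  setNames((deg$log2fc - mean(deg$log2fc)) / s, deg$gene)
}
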