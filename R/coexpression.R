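#' Signed soft-thresholded adjacency
#'
#' Computes the signed weighted adjacency
#' `a_ij = ((1 + cor(i, j)) / 2)^beta` over genes, with unit diagonal.
#' Anti-correlated genes map near 0, perfectly correlated genes to 1.
#' Constant genes (undefined correlation) are dropped with a warning.
#'
#' @param expr Log-normalized expression, genes x cells.
#' @param power Soft-thresholding power beta (>= 1).
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(expr, power = 6) {
  check_scalar(power, "power", 1)
  x <- as.matrix(expr)
  if (nrow(x) < 2) stop_sncnm("need at least 2 genes", "sncnm_invalid_design")
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant gene(s) before correlation",
                    sum(v == 0)))
    x <- x[v > 0, , drop = FALSE]
  }
  r <- cor(t(x))
  a <- ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Pick a soft-thresholding power by the scale-free fit criterion
#'
#' For each candidate power the signed adjacency is formed and the network's
#' connectivity distribution is checked for approximate scale-free topology:
#' connectivities are split into 10 bins, and the fit is the squared
#' correlation between `log10(frequency)` and `log10(mean connectivity)` per
#' bin, sign-penalized (negated) when the slope is positive. The smallest
#' power with fit >= `rsq_cut` is chosen; if none qualifies, the power with
#' the maximal fit.
#'
#' @param expr Log-normalized expression, genes x cells.
#' @param candidate_powers Integer vector of candidate betas (>= 2 values).
#' @param rsq_cut Scale-free fit threshold (default 0.8).
#' @return List with `power` (the chosen beta) and `fit_table` (data frame of
#'   power and signed R squared).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(2, 4, 6, 8, 10, 12),
                                rsq_cut = 0.8) {
  if (length(candidate_powers) < 2) {
    stop_sncnm("need at least 2 candidate powers", "sncnm_invalid_design")
  }
  fits <- vapply(candidate_powers, function(b) {
    a <- signed_adjacency(expr, b)
    k <- rowSums(a) - 1
    if (max(k) - min(k) < 1e-12) return(NA_real_)
    scale_free_fit(k)
  }, numeric(1))
  if (all(is.na(fits))) {
    warning("degenerate connectivity for all powers; using smallest candidate")
    return(list(power = min(candidate_powers),
                fit_table = data.frame(power = candidate_powers,
                                       signed_rsq = fits)))
  }
  ok <- which(!is.na(fits) & fits >= rsq_cut)
  power <- if (length(ok)) candidate_powers[min(ok)] else
    candidate_powers[which.max(fits)]
  list(power = power,
       fit_table = data.frame(power = candidate_powers, signed_rsq = fits))
}

# signed scale-free topology fit R^2 for a connectivity vector
scale_free_fit <- function(k, n_bins = 10) {
  cut_pts <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- findInterval(k, cut_pts, rightmost.closed = TRUE)
  freq <- tabulate(bin, n_bins)
  mean_k <- vapply(seq_len(n_bins),
                   function(b) mean(k[bin == b]), numeric(1))
  keep <- freq > 0 & mean_k > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(mean_k[keep]); ly <- log10(freq[keep] / sum(freq))
  r <- cor(lx, ly)
  sign_pen <- if (r > 0) -1 else 1   # scale-free slope must be negative
  sign_pen * r^2
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` (with the diagonal of `a` zeroed internally and
#' `k_i = sum_u a_iu`), `TOM_ii = 1`. Two genes are topologically similar
#' when they are connected and share neighbors.
#'
#' @param adj Symmetric adjacency in \[0, 1\] from [signed_adjacency()].
#' @return Symmetric similarity matrix with entries in \[0, 1\].
#' @export
tom_similarity <- function(adj) {
  a <- as.matrix(adj)
  stopifnot(nrow(a) == ncol(a))
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  mins <- outer(k, k, pmin)
  tom <- (shared + a) / (mins + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at `cut_height`. Clusters smaller than `min_module_size`
#' are assigned the unassigned label 0; modules whose eigengenes correlate
#' above `merge_cor` are merged iteratively; final labels are renumbered by
#' decreasing module size.
#'
#' @param tom Topological overlap matrix from [tom_similarity()].
#' @param expr The expression matrix (genes x cells) used to compute
#'   eigengenes for merging and kME.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static tree-cut height on `1 - TOM` (default 0.99).
#' @param merge_cor Eigengene correlation above which modules merge.
#' @return An object of class `module_set`: list with `labels` (named integer
#'   per gene, 0 = unassigned), `eigengenes` (cells x modules), `kme`
#'   (genes x modules), and `tree` (the hclust object).
#' @export
detect_modules <- function(tom, expr, min_module_size = 30, cut_height = 0.99,
                           merge_cor = 0.75) {
  check_scalar(min_module_size, "min_module_size", 2)
  stopifnot(nrow(tom) == ncol(tom), nrow(tom) == nrow(expr))
  genes <- rownames(expr)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(module_set(setNames(integer(nrow(tom)), genes), expr, tree = NULL))
  }
  tree <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(tree, h = cut_height)
  sizes <- table(raw)
  labels <- ifelse(sizes[as.character(raw)] >= min_module_size, raw, 0L)
  labels <- as.integer(labels)
  names(labels) <- genes

  # iterative eigengene merging
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2) break
    eg <- sapply(mods, function(m)
      module_eigengene(expr, genes[labels == m]))
    ec <- cor(eg)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[top[1], top[2]] <= merge_cor) break
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }
  # renumber by decreasing size
  mods <- setdiff(unique(labels), 0L)
  if (length(mods)) {
    sz <- vapply(mods, function(m) sum(labels == m), integer(1))
    remap <- setNames(seq_along(mods), mods[order(-sz, mods)])
    labels[labels != 0L] <- remap[as.character(labels[labels != 0L])]
  }
  module_set(labels, expr, tree = tree)
}

# assemble a module_set (labels + eigengenes + kME) from labels and expression
module_set <- function(labels, expr, tree = NULL) {
  mods <- setdiff(sort(unique(labels)), 0L)
  genes <- names(labels)
  if (length(mods)) {
    eigengenes <- sapply(mods, function(m)
      module_eigengene(expr, genes[labels == m]))
    colnames(eigengenes) <- paste0("ME", mods)
    kme <- kme(expr, eigengenes)
  } else {
    eigengenes <- matrix(numeric(0), nrow = ncol(expr), ncol = 0)
    kme <- matrix(numeric(0), nrow = nrow(expr), ncol = 0,
                  dimnames = list(genes, NULL))
  }
  structure(list(labels = labels, eigengenes = eigengenes, kme = kme,
                 tree = tree),
            class = "module_set")
}

#' Module eigengene
#'
#' First principal component of the standardized (per-gene z-scored)
#' expression submatrix of the module, scaled to unit variance across cells,
#' with the sign fixed so that the mean correlation with member genes is
#' nonnegative.
#'
#' @param expr Expression matrix, genes x cells.
#' @param genes Member gene names (>= 2).
#' @return Numeric vector of per-cell eigengene scores.
#' @export
module_eigengene <- function(expr, genes) {
  x <- as.matrix(expr[genes, , drop = FALSE])
  stopifnot(nrow(x) >= 2, ncol(x) >= 3)
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0
  if (all(xs == 0)) {
    warning("rank-0 module submatrix; zero eigengene")
    return(numeric(ncol(x)))
  }
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- e / max(sd(e), .Machine$double.eps)
  memb_cor <- cor(t(x), e)
  if (mean(memb_cor, na.rm = TRUE) < 0) e <- -e
  as.numeric(e)
}

#' Eigengene-based connectivity (kME)
#'
#' Pearson correlation of each gene's expression with each module eigengene.
#' Constant genes get kME 0.
#'
#' @param expr Expression matrix, genes x cells.
#' @param eigengenes Cells x modules eigengene matrix.
#' @return Genes x modules correlation matrix in \[-1, 1\].
#' @export
kme <- function(expr, eigengenes) {
  x <- as.matrix(expr)
  eg <- as.matrix(eigengenes)
  stopifnot(ncol(x) == nrow(eg))
  out <- suppressWarnings(cor(t(x), eg))
  out[!is.finite(out)] <- 0
  rownames(out) <- rownames(expr)
  out
}

#' Module-trait correlation with Student asymptotic p-values
#'
#' Pearson correlation of each module eigengene with each trait column
#' (e.g. one-hot cell-type indicators), with the two-sided Student asymptotic
#' p-value `p = 2 P(T_{n-2} >= |r| sqrt((n-2) / (1-r^2)))`. Constant traits
#' are reported as r = 0 with p = 1 and flagged.
#'
#' @param eigengenes Cells x modules matrix.
#' @param traits Cells x traits numeric matrix (e.g. one-hot cell types).
#' @return Data frame with columns `module`, `trait`, `r`, `p`, `degenerate`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  eg <- as.matrix(eigengenes); tr <- as.matrix(traits)
  n <- nrow(eg)
  stopifnot(n == nrow(tr), n >= 3)
  grid <- expand.grid(module = colnames(eg) %||% seq_len(ncol(eg)),
                      trait = colnames(tr) %||% seq_len(ncol(tr)),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    e <- eg[, grid$module[i]]; t_ <- tr[, grid$trait[i]]
    if (sd(t_) == 0 || sd(e) == 0) {
      return(data.frame(r = 0, p = 1, degenerate = TRUE))
    }
    r <- cor(e, t_)
    data.frame(r = r, p = cor_t_pvalue(r, n), degenerate = FALSE)
  })
  cbind(grid, do.call(rbind, res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Student asymptotic p for a Pearson correlation
cor_t_pvalue <- function(r, n) {
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

#' Hypergeometric DEG enrichment per module
#'
#' Tests each module (label > 0) for enrichment of the significant genes of
#' a DEG table against the analyzed-gene universe, via
#' [hypergeometric_overlap()].
#'
#' @param modules A `module_set` from [detect_modules()].
#' @param deg A [wilcoxon_deg()] table.
#' @param universe Character vector of analyzed genes.
#' @return Data frame with columns `module`, `size`, `overlap`, `p`.
#' @export
module_deg_enrichment <- function(modules, deg, universe) {
  sig <- intersect(deg$gene[deg$significant], universe)
  mods <- setdiff(sort(unique(modules$labels)), 0L)
  out <- lapply(mods, function(m) {
    members <- intersect(names(modules$labels)[modules$labels == m], universe)
    h <- hypergeometric_overlap(members, sig, universe)
    data.frame(module = m, size = length(members),
               overlap = h$overlap, p = h$p)
  })
  if (!length(out)) {
    return(data.frame(module = integer(0), size = integer(0),
                      overlap = integer(0), p = numeric(0)))
  }
  do.call(rbind, out)
}
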