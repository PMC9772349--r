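# Independent oracles and small fixture builders shared across tests.
# Each oracle deliberately avoids the implementation's code paths
# (no caching, no stride tricks, no pwilcox/phyper shortcuts).

# wrap an integer matrix (cells x genes, 0-based codes) as a
# discretized_matrix without going through discretize_interval
tiny_disc <- function(values, nlev = NULL) {
  storage.mode(values) <- "integer"
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  if (is.null(nlev)) {
    nlev <- apply(values, 2, function(v) max(v) + 1L)
  }
  names(nlev) <- colnames(values)
  structure(list(values = values,
                 nlev = setNames(as.integer(nlev), colnames(values)),
                 breaks = NULL, constant = setNames(nlev == 1L, colnames(values)),
                 n_bins = max(nlev)),
            class = "discretized_matrix")
}

# brute-force Dirichlet-multinomial marginal likelihood: loops over every
# parent configuration explicitly and counts matching rows by comparison
brute_bde <- function(values, nlev, edges, iss = 1) {
  nodes <- colnames(values)
  total <- 0
  for (child in nodes) {
    parents <- edges$from[edges$to == child]
    r <- nlev[[child]]
    configs <- if (length(parents)) {
      do.call(expand.grid, lapply(parents, function(p) 0:(nlev[[p]] - 1L)))
    } else {
      data.frame(row.names = 1)
    }
    q <- nrow(configs)
    a_ijk <- iss / (r * q)
    a_ij <- iss / q
    for (j in seq_len(q)) {
      rows <- rep(TRUE, nrow(values))
      for (pi in seq_along(parents)) {
        rows <- rows & values[, parents[pi]] == configs[j, pi]
      }
      n_ij <- sum(rows)
      total <- total + lgamma(a_ij) - lgamma(a_ij + n_ij)
      for (k in 0:(r - 1L)) {
        n_ijk <- sum(rows & values[, child] == k)
        total <- total + lgamma(a_ijk + n_ijk) - lgamma(a_ijk)
      }
    }
  }
  total
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1+n2, n1) group assignments
wilcox_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  all_w <- apply(combn(length(pooled), n1), 2, function(idx) sum(r[idx]))
  mu <- mean(all_w)
  # two-sided: assignments at least as extreme (distance from the mean)
  mean(abs(all_w - mu) >= abs(obs - mu) - 1e-9)
}

# upper-tail hypergeometric by enumeration of all draws of B from the
# universe
hyper_enum_p <- function(setA, setB, universe) {
  k_obs <- length(intersect(setA, setB))
  n_b <- length(setB)
  draws <- combn(length(universe), n_b)
  mean(apply(draws, 2, function(idx)
    length(intersect(universe[idx], setA)) >= k_obs))
}

# skeleton-level F1 between two edge data frames (columns 1-2 = from, to)
skeleton_f1 <- function(est, truth) {
  sk <- function(e) {
    if (NROW(e) == 0) return(character(0))
    unique(paste(pmin(e[[1]], e[[2]]), pmax(e[[1]], e[[2]])))
  }
  s_est <- sk(est); s_tr <- sk(truth)
  tp <- length(intersect(s_est, s_tr))
  if (length(s_est) == 0 || length(s_tr) == 0 || tp == 0) return(0)
  prec <- tp / length(s_est); rec <- tp / length(s_tr)
  2 * prec * rec / (prec + rec)
}

# all DAGs on `nodes` (by enumerating edge subsets and dropping cyclic ones)
all_dags <- function(nodes) {
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- pairs[bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0, ,
                 drop = FALSE]
    dag <- tryCatch(make_dag(nodes, sel), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <- dag
  }
  out
}

# Markov equivalence class signature: skeleton + v-structures
mec_signature <- function(dag) {
  e <- dag_edges(dag)
  skel <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  vs <- character(0)
  for (child in dag$nodes) {
    pars <- sort(e$from[e$to == child])
    if (length(pars) >= 2) {
      cmb <- combn(pars, 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        # v-structure only if the two parents are not adjacent
        adjacent <- any((e$from == a & e$to == b) | (e$from == b & e$to == a))
        if (!adjacent) vs <- c(vs, paste(a, child, b))
      }
    }
  }
  paste(c(paste(skel, collapse = ";"), paste(sort(vs), collapse = ";")),
        collapse = "|")
}

# edge data frame from a logical adjacency matrix
which_edges <- function(amat) {
  idx <- which(amat, arr.ind = TRUE)
  data.frame(from = rownames(amat)[idx[, 1]], to = colnames(amat)[idx[, 2]])
}
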