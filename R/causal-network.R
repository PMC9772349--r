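#' Select network features for one cell type
#'
#' The feature set for structure learning is the union of the cell type's
#' differentially expressed genes and the members of its correlated
#' co-expression module, sorted and de-duplicated.
#'
#' @param cell_type_degs Character vector of DEG names.
#' @param module_genes Character vector of module member names.
#' @return Sorted character vector of features.
#' @export
select_features <- function(cell_type_degs, module_genes) {
  out <- sort(unique(c(cell_type_degs, module_genes)))
  if (length(out) == 0) {
    stop_sncnm("empty feature set: nothing to learn", "sncnm_pipeline_error")
  }
  out
}

#' Interval discretization of expression
#'
#' Per gene, splits the observed range `[min, max]` into `n_bins` equal-width
#' intervals; all intervals are half-open `[lo, hi)` except the last, which
#' is closed so the maximum falls in the top bin. Constant genes collapse to
#' a single level and are flagged.
#'
#' @param expr Log-normalized expression, genes x cells.
#' @param n_bins Number of intervals (default 3).
#' @return Object of class `discretized_matrix`: list with `values`
#'   (cells x genes integer matrix, entries `0 .. n_bins-1`), `breaks`
#'   (per-gene boundary vectors), `nlev` (per-gene level count) and
#'   `constant` (logical flags).
#' @export
discretize_interval <- function(expr, n_bins = 3) {
  check_scalar(n_bins, "n_bins", 2, Inf, integer = TRUE)
  x <- t(as.matrix(expr))       # cells x genes
  genes <- colnames(x)
  breaks <- vector("list", ncol(x))
  nlev <- integer(ncol(x))
  constant <- logical(ncol(x))
  vals <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi <= lo) {
      breaks[[j]] <- c(lo, lo)
      nlev[j] <- 1L
      constant[j] <- TRUE
      next
    }
    b <- seq(lo, hi, length.out = n_bins + 1)
    vals[, j] <- findInterval(x[, j], b, rightmost.closed = TRUE,
                              all.inside = TRUE) - 1L
    breaks[[j]] <- b
    nlev[j] <- as.integer(n_bins)
  }
  names(breaks) <- genes; names(nlev) <- genes; names(constant) <- genes
  structure(list(values = vals, breaks = breaks, nlev = nlev,
                 constant = constant, n_bins = as.integer(n_bins)),
            class = "discretized_matrix")
}

# re-bin a raw matrix with previously fixed breaks (used when scoring new
# cells on the coding learned from the full data)
apply_breaks <- function(disc, expr) {
  x <- t(as.matrix(expr))
  vals <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in colnames(x)) {
    if (disc$constant[j]) next
    vals[, j] <- findInterval(x[, j], disc$breaks[[j]],
                              rightmost.closed = TRUE, all.inside = TRUE) - 1L
  }
  out <- disc
  out$values <- vals
  out
}

#' Create a DAG over a node set
#'
#' @param nodes Character vector of node labels.
#' @param edges Optional 2-column data frame or matrix (`from`, `to`).
#' @return Object of class `sncnm_dag`: list with `nodes` and logical
#'   adjacency `amat` (`amat[p, c]` is `TRUE` for the arc p -> c).
#' @export
make_dag <- function(nodes, edges = NULL) {
  n <- length(nodes)
  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    if (any(edges[, 1] == edges[, 2])) {
      stop_sncnm("self-loops are not allowed", "sncnm_cyclic_graph")
    }
    amat[cbind(edges[, 1], edges[, 2])] <- TRUE
  }
  dag <- structure(list(nodes = nodes, amat = amat), class = "sncnm_dag")
  if (dag_is_cyclic(amat)) {
    stop_sncnm("edge set contains a cycle", "sncnm_cyclic_graph")
  }
  dag
}

#' Edge list of a DAG
#' @param dag An `sncnm_dag`.
#' @return Data frame with columns `from`, `to`.
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$amat, arr.ind = TRUE)
  data.frame(from = dag$nodes[idx[, 1]], to = dag$nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# transitive reachability: reach[i, j] TRUE if a directed path i -> ... -> j
dag_reachability <- function(amat) {
  r <- amat
  repeat {
    r2 <- r | ((r %*% amat) > 0)
    if (identical(r2, r)) return(r)
    r <- r2
  }
}

dag_is_cyclic <- function(amat) {
  any(diag(dag_reachability(amat)))
}

# BDeu local score of `child` given `parents` (integer column indices into
# vals, a cells x genes 0-based integer matrix). alpha_ijk = iss / (r * q).
local_bde <- function(vals, nlev, child, parents, iss) {
  n_obs <- nrow(vals)
  r <- nlev[child]
  if (length(parents)) {
    q <- prod(nlev[parents])
    cfg <- integer(n_obs)
    stride <- 1L
    for (p in parents) {
      cfg <- cfg + vals[, p] * stride
      stride <- stride * nlev[p]
    }
  } else {
    q <- 1
    cfg <- integer(n_obs)
  }
  if (n_obs == 0) return(0)
  counts <- tabulate(vals[, child] + r * cfg + 1L, r * q)
  a_ijk <- iss / (r * q)
  a_ij <- iss / q
  nij <- colSums(matrix(counts, nrow = r))
  sum(lgamma(a_ijk + counts) - lgamma(a_ijk)) +
    sum(lgamma(a_ij) - lgamma(a_ij + nij))
}

#' BDeu network score
#'
#' Log marginal likelihood of the discretized data under the DAG with a
#' Bayesian Dirichlet equivalent uniform prior: summed over nodes i and
#' parent configurations j,
#' `lnGamma(a_ij) - lnGamma(a_ij + N_ij) +
#'  sum_k [lnGamma(a_ijk + N_ijk) - lnGamma(a_ijk)]`
#' with `a_ijk = iss / (r_i q_i)` and `a_ij = iss / q_i`, where `r_i` is the
#' child cardinality and `q_i` the number of parent configurations. The
#' score is decomposable per node and likelihood-equivalent: DAGs in the
#' same Markov equivalence class score identically.
#'
#' @param data A [discretize_interval()] result.
#' @param dag An `sncnm_dag` over (a subset of) the data's genes.
#' @param iss Imaginary sample size (> 0), default 1.
#' @return The log score (a single number).
#' @export
bde_score <- function(data, dag, iss = 1) {
  check_scalar(iss, "iss", 1e-12)
  stopifnot(inherits(data, "discretized_matrix"), inherits(dag, "sncnm_dag"))
  if (dag_is_cyclic(dag$amat)) {
    stop_sncnm("cannot score a cyclic graph", "sncnm_cyclic_graph")
  }
  cols <- match(dag$nodes, colnames(data$values))
  if (anyNA(cols)) {
    stop_sncnm("dag nodes missing from data", "sncnm_pipeline_error")
  }
  vals <- data$values[, cols, drop = FALSE]
  nlev <- data$nlev[cols]
  total <- 0
  for (ci in seq_along(dag$nodes)) {
    total <- total + local_bde(vals, nlev, ci, which(dag$amat[, ci]), iss)
  }
  total
}

#' Hill-climbing structure search under the BDeu score
#'
#' Greedy local search starting from the empty graph: at each step the single
#' arc operation (addition, deletion or reversal) that most improves the
#' total BDeu score is applied, subject to acyclicity and the optional
#' in-degree bound, until no operation improves the score. Ties are broken
#' deterministically (operation type add < delete < reverse, then parent
#' label, then child label), so the search is fully reproducible. Local
#' scores are cached per (node, parent set).
#'
#' @param data A [discretize_interval()] result (all genes are used as
#'   nodes).
#' @param iss Imaginary sample size, default 1.
#' @param max_in_degree Optional maximum number of parents per node.
#' @return An `sncnm_dag`, with attribute `score_trace` recording the score
#'   after each accepted move.
#' @export
hill_climb <- function(data, iss = 1, max_in_degree = NULL) {
  stopifnot(inherits(data, "discretized_matrix"))
  vals <- data$values
  nlev <- data$nlev
  nodes <- colnames(vals)
  n <- length(nodes)
  if (n < 2) stop_sncnm("need at least 2 variables", "sncnm_pipeline_error")
  max_in <- if (is.null(max_in_degree)) n else as.integer(max_in_degree)
  eps <- 1e-10

  cache <- new.env(parent = emptyenv())
  local_score <- function(child, parents) {
    key <- paste0(child, "|", paste(parents, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- local_bde(vals, nlev, child, sort(parents), iss)
    cache[[key]] <- s
    s
  }

  amat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  pa <- rep(list(integer(0)), n)
  lsc <- vapply(seq_len(n), function(c) local_score(c, integer(0)), numeric(1))
  addD <- matrix(NA_real_, n, n)  # addD[p, c]: gain of adding p -> c
  delD <- matrix(NA_real_, n, n)  # delD[p, c]: gain of deleting p -> c
  refresh_child <- function(c) {
    for (p in seq_len(n)) {
      if (p == c) next
      if (amat[p, c]) {
        delD[p, c] <<- local_score(c, setdiff(pa[[c]], p)) - lsc[c]
        addD[p, c] <<- NA_real_
      } else {
        addD[p, c] <<- local_score(c, c(pa[[c]], p)) - lsc[c]
        delD[p, c] <<- NA_real_
      }
    }
  }
  for (c in seq_len(n)) refresh_child(c)

  # lexicographic candidate order for deterministic tie-breaking
  node_rank <- rank(nodes, ties.method = "first")
  trace <- numeric(0)
  score <- sum(lsc)

  repeat {
    reach <- dag_reachability(amat)
    indeg <- colSums(amat)
    best <- list(delta = eps)
    consider <- function(delta, type, p, c) {
      if (is.na(delta)) return()
      if (delta > best$delta + 1e-12) {
        best <<- list(delta = delta, type = type, p = p, c = c)
      }
    }
    # additions (type 1): p -> c legal if no edge either way, no path c ~> p
    ordp <- order(node_rank)
    for (p in ordp) for (c in ordp) {
      if (p == c || amat[p, c] || amat[c, p]) next
      if (reach[c, p] || indeg[c] >= max_in) next
      consider(addD[p, c], 1L, p, c)
    }
    # deletions (type 2)
    for (p in ordp) for (c in ordp) {
      if (amat[p, c]) consider(delD[p, c], 2L, p, c)
    }
    # reversals (type 3): p -> c becomes c -> p
    for (p in ordp) for (c in ordp) {
      if (!amat[p, c]) next
      if (indeg[p] >= max_in) next
      amat[p, c] <- FALSE
      cyclic <- dag_reachability(amat)[p, c]
      amat[p, c] <- TRUE
      if (cyclic) next
      rev_gain <- local_score(p, c(pa[[p]], c)) - lsc[p]
      consider(delD[p, c] + rev_gain, 3L, p, c)
    }
    if (best$delta <= eps) break

    p <- best$p; c <- best$c
    if (best$type == 1L) {
      amat[p, c] <- TRUE
      pa[[c]] <- c(pa[[c]], p)
      lsc[c] <- local_score(c, pa[[c]])
      refresh_child(c)
    } else if (best$type == 2L) {
      amat[p, c] <- FALSE
      pa[[c]] <- setdiff(pa[[c]], p)
      lsc[c] <- local_score(c, pa[[c]])
      refresh_child(c)
    } else {
      amat[p, c] <- FALSE
      amat[c, p] <- TRUE
      pa[[c]] <- setdiff(pa[[c]], p)
      pa[[p]] <- c(pa[[p]], c)
      lsc[c] <- local_score(c, pa[[c]])
      lsc[p] <- local_score(p, pa[[p]])
      refresh_child(c)
      refresh_child(p)
    }
    score <- sum(lsc)
    trace <- c(trace, score)
  }
  dag <- structure(list(nodes = nodes, amat = amat), class = "sncnm_dag")
  attr(dag, "score_trace") <- trace
  attr(dag, "score") <- score
  dag
}

#' Bootstrap arc strength and direction
#'
#' Repeatedly subsamples `ceiling(sample_frac * n_cells)` cells without
#' replacement (discretization bins fixed from the full data so replicates
#' share a coding), learns a DAG by [hill_climb()] on each replicate, and
#' accumulates, for every gene pair, the fraction of replicates containing
#' the arc (strength, orientation-agnostic) and the fraction of those
#' oriented each way (direction). Replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param data A [discretize_interval()] result.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param sample_frac Fraction of cells per replicate (default 0.5).
#' @param iss Imaginary sample size for scoring.
#' @param seed Integer seed.
#' @param max_in_degree Optional in-degree bound passed to [hill_climb()].
#' @return Object of class `bootstrap_strength`: list with `nodes`, `counts`
#'   (nodes x nodes matrix of arc occurrence counts by orientation) and
#'   `n_replicates`.
#' @export
bootstrap_strength <- function(data, n_boot = 200, sample_frac = 0.5,
                               iss = 1, seed = 1L, max_in_degree = NULL) {
  check_scalar(n_boot, "n_boot", 1, Inf, integer = TRUE)
  check_scalar(sample_frac, "sample_frac", 1e-12, 1)
  n_cells <- nrow(data$values)
  n_take <- ceiling(sample_frac * n_cells)
  nodes <- colnames(data$values)
  counts <- matrix(0L, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
  for (b in seq_len(n_boot)) {
    rows <- with_seed(derive_seed(seed, paste0("bootstrap:", b)),
                      sample.int(n_cells, n_take))
    sub <- data
    sub$values <- data$values[rows, , drop = FALSE]
    dag <- hill_climb(sub, iss = iss, max_in_degree = max_in_degree)
    counts <- counts + dag$amat
  }
  structure(list(nodes = nodes, counts = counts,
                 n_replicates = as.integer(n_boot)),
            class = "bootstrap_strength")
}

#' Arc strength/direction table from bootstrap counts
#'
#' @param bs A [bootstrap_strength()] result.
#' @return Data frame, one row per ordered pair with nonzero occurrence:
#'   `from`, `to`, `strength` (fraction of replicates containing the arc in
#'   either direction) and `direction` (among those, fraction oriented
#'   from -> to). `direction(a,b) + direction(b,a) = 1` for any pair with
#'   positive strength.
#' @export
strength_table <- function(bs) {
  stopifnot(inherits(bs, "bootstrap_strength"))
  cnt <- bs$counts
  tot <- cnt + t(cnt)
  idx <- which(tot > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction = numeric(0)))
  }
  data.frame(
    from = bs$nodes[idx[, 1]], to = bs$nodes[idx[, 2]],
    strength = tot[idx] / bs$n_replicates,
    direction = cnt[idx] / tot[idx],
    stringsAsFactors = FALSE
  )
}

#' Model-averaged network from bootstrap strengths
#'
#' Keeps every gene pair whose arc strength is at least `strength_thr` and
#' orients it in the direction with bootstrap frequency at least
#' `direction_thr`. An exact 0.5/0.5 split is oriented from the
#' lexicographically smaller label and flagged. Because thresholding each
#' pair independently can create directed cycles, any cycle is repaired by
#' dropping its weakest-strength arc (with a warning) until the result is
#' acyclic.
#'
#' @param bs A [bootstrap_strength()] result.
#' @param strength_thr Minimum arc strength (default 0.85).
#' @param direction_thr Minimum direction frequency (default 0.5).
#' @return Object of class `avg_network`: list with `nodes` and `edges`
#'   (data frame `from`, `to`, `strength`, `direction`, `tie`).
#' @export
averaged_network <- function(bs, strength_thr = 0.85, direction_thr = 0.5) {
  check_scalar(strength_thr, "strength_thr", 0, 1)
  check_scalar(direction_thr, "direction_thr", 0, 1)
  st <- strength_table(bs)
  st <- st[st$strength >= strength_thr, , drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0),
                      strength = numeric(0), direction = numeric(0),
                      tie = logical(0), stringsAsFactors = FALSE)
  seen <- character(0)
  for (i in seq_len(nrow(st))) {
    a <- st$from[i]; b <- st$to[i]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    d_ab <- st$direction[i]
    tie <- abs(d_ab - 0.5) < 1e-12
    if (tie) {
      pair <- sort(c(a, b))
      edges[nrow(edges) + 1L, ] <- list(pair[1], pair[2], st$strength[i],
                                        0.5, TRUE)
    } else if (d_ab >= direction_thr && d_ab > 0.5) {
      edges[nrow(edges) + 1L, ] <- list(a, b, st$strength[i], d_ab, FALSE)
    } else if ((1 - d_ab) >= direction_thr) {
      edges[nrow(edges) + 1L, ] <- list(b, a, st$strength[i], 1 - d_ab, FALSE)
    }
  }
  if (any(edges$tie)) {
    warning(sprintf("%d arc(s) had an exact 0.5/0.5 direction split; %s",
                    sum(edges$tie), "oriented lexicographically"))
  }
  # cycle repair: drop the weakest arc on each remaining cycle
  repeat {
    if (nrow(edges) == 0) break
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
    if (igraph::is_dag(g)) break
    cyc <- find_cycle(edges)
    weakest <- cyc[which.min(edges$strength[cyc])]
    warning(sprintf("cycle repair: dropping arc %s -> %s (strength %.3f)",
                    edges$from[weakest], edges$to[weakest],
                    edges$strength[weakest]))
    edges <- edges[-weakest, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = bs$nodes, edges = edges), class = "avg_network")
}

# indices (into the edges data frame) of one directed cycle
find_cycle <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  parent_edge <- setNames(rep(NA_integer_, length(nodes)), nodes)
  out <- NULL
  visit <- function(v) {
    state[v] <<- 1L
    for (ei in which(edges$from == v)) {
      w <- edges$to[ei]
      if (state[w] == 1L) {
        # unwind the open path from v back to w
        cyc <- ei
        cur <- v
        while (cur != w) {
          cyc <- c(parent_edge[cur], cyc)
          cur <- edges$from[parent_edge[cur]]
        }
        out <<- cyc
        return(TRUE)
      }
      if (state[w] == 0L) {
        parent_edge[w] <<- ei
        if (visit(w)) return(TRUE)
      }
    }
    state[v] <<- 2L
    FALSE
  }
  for (v in nodes) {
    if (state[v] == 0L && visit(v)) break
  }
  out
}

#' Merge control and case averaged networks
#'
#' Combines the two condition networks into one graph annotated with
#' provenance: nodes and edges present in both conditions, only in the
#' control network, or only in the case network. When an edge exists in
#' both, the control condition's strength is used as the merged weight.
#' Node regulation (up / down / ns) is taken from the case-vs-control DEG
#' table.
#'
#' @param net_ctrl,net_case `avg_network` objects (e.g. NT and HD).
#' @param deg Optional [wilcoxon_deg()] table for node regulation flags.
#' @param labels Length-2 character vector naming the conditions (used for
#'   provenance values), default `c("ctrl", "case")`.
#' @return Object of class `merged_network`: list with `nodes` (data frame
#'   `node`, `provenance`, `regulation`) and `edges` (data frame `from`,
#'   `to`, `provenance`, `weight`).
#' @export
merge_condition_networks <- function(net_ctrl, net_case, deg = NULL,
                                     labels = c("ctrl", "case")) {
  stopifnot(inherits(net_ctrl, "avg_network"), inherits(net_case, "avg_network"))
  active <- function(net) unique(c(net$edges$from, net$edges$to))
  n_ctrl <- active(net_ctrl); n_case <- active(net_case)
  nodes <- sort(unique(c(n_ctrl, n_case)))
  prov <- ifelse(nodes %in% n_ctrl & nodes %in% n_case, "both",
                 ifelse(nodes %in% n_ctrl, labels[1], labels[2]))
  reg <- rep("ns", length(nodes))
  if (!is.null(deg)) {
    hit <- match(nodes, deg$gene)
    ok <- !is.na(hit) & deg$significant[hit]
    reg[which(ok)] <- deg$direction[hit[which(ok)]]
  }
  ekey <- function(e) paste(e$from, e$to, sep = "->")
  kc <- ekey(net_ctrl$edges); kk <- ekey(net_case$edges)
  all_k <- unique(c(kc, kk))
  e_prov <- ifelse(all_k %in% kc & all_k %in% kk, "both",
                   ifelse(all_k %in% kc, labels[1], labels[2]))
  weight <- ifelse(all_k %in% kc,
                   net_ctrl$edges$strength[match(all_k, kc)],
                   net_case$edges$strength[match(all_k, kk)])
  parts <- strsplit(all_k, "->", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    provenance = e_prov, weight = weight, stringsAsFactors = FALSE
  )
  structure(list(
    nodes = data.frame(node = nodes, provenance = prov, regulation = reg,
                       stringsAsFactors = FALSE),
    edges = edges
  ), class = "merged_network")
}

#' Identify key driver genes in a merged network
#'
#' Hubs are nodes with out-degree strictly greater than `hub_out_degree`;
#' connectors are non-hub nodes lying on a directed path between two
#' distinct hubs (an incoming edge from one hub and an outgoing edge to
#' another). With `undirected_connector = TRUE` a connector only needs to be
#' adjacent (either orientation) to two distinct hubs.
#'
#' @param net A `merged_network`.
#' @param hub_out_degree Out-degree threshold (strict, default 10).
#' @param undirected_connector Relax the connector rule to mere adjacency.
#' @return Data frame with columns `gene`, `role` (`hub` / `connector`) and
#'   `out_degree`.
#' @export
find_key_drivers <- function(net, hub_out_degree = 10,
                             undirected_connector = FALSE) {
  stopifnot(inherits(net, "merged_network"))
  nodes <- net$nodes$node
  outdeg <- vapply(nodes, function(v) sum(net$edges$from == v), integer(1))
  hubs <- nodes[outdeg > hub_out_degree]
  conn <- character(0)
  for (x in setdiff(nodes, hubs)) {
    if (undirected_connector) {
      adj <- unique(c(net$edges$to[net$edges$from == x],
                      net$edges$from[net$edges$to == x]))
      if (length(intersect(adj, hubs)) >= 2) conn <- c(conn, x)
    } else {
      up <- intersect(net$edges$from[net$edges$to == x], hubs)
      down <- intersect(net$edges$to[net$edges$from == x], hubs)
      if (length(up) >= 1 && length(down) >= 1 &&
          length(union(up, down)) >= 2) {
        conn <- c(conn, x)
      }
    }
  }
  out <- rbind(
    data.frame(gene = hubs, role = rep("hub", length(hubs)),
               stringsAsFactors = FALSE),
    data.frame(gene = conn, role = rep("connector", length(conn)),
               stringsAsFactors = FALSE)
  )
  out$out_degree <- outdeg[out$gene]
  rownames(out) <- NULL
  out
}
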