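#' Build a brain graph from a connectivity matrix
#'
#' Turns a symmetric, non-negative, zero-diagonal connectivity matrix into
#' a weighted undirected graph: an edge (i, j) is present iff the matrix
#' cell is positive, weighted by the connection strength.
#'
#' @param mat square numeric matrix; symmetric, non-negative, zero diagonal
#' @return an `igraph` undirected weighted graph with vertex names taken
#'   from the matrix dimnames (or `V1..Vn`)
#' @export
build_graph <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("connectivity matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(mat, t(mat), tolerance = 1e-10)))
    stop("connectivity matrix must be symmetric", call. = FALSE)
  if (any(mat < 0)) stop("connectivity weights must be >= 0", call. = FALSE)
  if (any(diag(mat) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(rownames(mat)))
    dimnames(mat) <- list(paste0("V", seq_len(nrow(mat))),
                          paste0("V", seq_len(nrow(mat))))
  igraph::graph_from_adjacency_matrix(mat, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Transform edge weights into distances
#'
#' Shortest-path-based metrics interpret strong connections as short: each
#' distance is the reciprocal of the edge weight. Weights are first
#' rescaled by the maximum weight so distances are >= 1 and the derived
#' closeness/efficiency values stay in \[0, 1\]; shortest-path trees are
#' unchanged by the rescaling.
#'
#' @param graph weighted undirected `igraph`
#' @param rescale divide weights by the maximum before inverting
#' @return the graph with a `distance` edge attribute
#' @export
to_distance_weights <- function(graph, rescale = TRUE) {
  w <- igraph::E(graph)$weight
  if (length(w) == 0) return(graph)
  if (any(w <= 0))
    stop("zero-weight edge encountered: edges with weight 0 must be absent",
         call. = FALSE)
  wmax <- if (rescale) max(w) else 1
  igraph::E(graph)$distance <- wmax / w
  graph
}

.edge_distances <- function(graph) {
  if (igraph::ecount(graph) == 0) return(numeric(0))
  g <- to_distance_weights(graph)
  igraph::E(g)$distance
}

# geometric-mean weighted clustering coefficient (networkx-style):
# weights rescaled by the max, cube-rooted, triangle intensity summed and
# normalized by k(k-1)
.weighted_clustering <- function(mat) {
  n <- nrow(mat)
  k <- colSums(mat > 0)
  if (max(mat) == 0) return(stats::setNames(rep(0, n), rownames(mat)))
  m <- (mat / max(mat))^(1 / 3)
  tri <- diag(m %*% m %*% m)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(mat))
}

#' Nodal graph metrics
#'
#' Computes the seven node-wise metrics on a weighted undirected graph:
#' clustering coefficient (CC, geometric-mean weighted variant), degree
#' centrality (DC = degree / (n - 1)), eigenvector centrality (EC, leading
#' eigenvector of the weighted adjacency, unit 2-norm), closeness
#' centrality (CClo) and betweenness centrality (BC) on inverse-weight
#' distances with standard pair normalizations, node strength (NS, sum of
#' incident weights), and PageRank (PR, damping 0.85 on weighted
#' transitions). Disconnected nodes take closeness within their own
#' component, scaled by reachable-set size.
#'
#' @param graph weighted undirected `igraph`
#' @return tibble with columns `region`, `CC`, `DC`, `EC`, `CClo`, `BC`,
#'   `NS`, `PR`
#' @export
nodal_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  labels <- igraph::V(graph)$name
  mat <- .graph_matrix(graph)
  deg <- igraph::degree(graph)
  ns <- igraph::strength(graph)

  cc <- .weighted_clustering(mat)
  dc <- if (n > 1) deg / (n - 1) else rep(0, n)

  if (igraph::ecount(graph) > 0) {
    ev <- eigen(mat, symmetric = TRUE)
    lead <- ev$vectors[, which.max(abs(ev$values))]
    if (sum(lead) < 0) lead <- -lead
    ec <- abs(lead) / sqrt(sum(lead^2))

    d <- igraph::distances(graph, weights = .edge_distances(graph))
    reach <- is.finite(d)
    nr <- rowSums(reach)
    dsum <- rowSums(ifelse(reach, d, 0))
    cclo <- ifelse(nr > 1, (nr - 1) / dsum * (nr - 1) / max(1, n - 1), 0)

    bc_raw <- igraph::betweenness(graph, weights = .edge_distances(graph),
                                  normalized = FALSE)
    bc <- if (n > 2) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
    pr <- igraph::page_rank(graph, damping = 0.85,
                            weights = igraph::E(graph)$weight)$vector
  } else {
    ec <- cclo <- bc <- rep(0, n)
    pr <- rep(1 / n, n)
  }

  tibble::tibble(region = labels, CC = unname(cc), DC = unname(dc),
                 EC = unname(ec), CClo = unname(cclo), BC = unname(bc),
                 NS = unname(ns), PR = unname(pr))
}

.graph_matrix <- function(graph) {
  as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                        sparse = TRUE))
}

# degree-preserving rewired reference: topology rewired by double-edge
# swaps (10x|E| attempts), original weights permuted onto the new edges
.rewired_reference <- function(graph) {
  m <- igraph::ecount(graph)
  g2 <- igraph::rewire(graph, igraph::keeping_degseq(niter = 10 * m))
  igraph::E(g2)$weight <- sample(igraph::E(graph)$weight)
  g2
}

.lcc <- function(graph) {
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(graph, keep)
}

.cpl_diameter <- function(graph) {
  g <- .lcc(graph)
  if (igraph::vcount(g) < 2) return(c(CPL = 0, diameter = 0))
  d <- igraph::distances(g, weights = .edge_distances(g))
  ut <- d[upper.tri(d)]
  c(CPL = mean(ut), diameter = max(ut))
}

.global_efficiency <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2 || igraph::ecount(graph) == 0) return(0)
  d <- igraph::distances(graph, weights = .edge_distances(graph))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global graph metrics
#'
#' The 17 whole-network measures: density, modularity (greedy agglomerative
#' maximization on weights, deterministic), weighted degree assortativity
#' (correlation of endpoint strengths over the edge list), transitivity
#' (3 x triangles / triads, unweighted), global efficiency (mean inverse
#' shortest-path distance; 0 for unreachable pairs), characteristic path
#' length and diameter on the largest connected component, small-worldness
#' (C/C_rand)/(L/L_rand) against seeded degree-preserving rewired
#' references, degree-distribution entropy (natural log over observed
#' degrees), spectral radius, and the means of degree and of the six
#' weighted nodal metrics.
#'
#' @param graph weighted undirected `igraph`
#' @param seed integer seed for the rewired small-world references
#' @param n_rewire number of rewired reference graphs
#' @param nodal optional precomputed [nodal_metrics()] tibble
#' @return named numeric vector of length 17
#' @export
global_metrics <- function(graph, seed = 1L, n_rewire = 10L, nodal = NULL) {
  n <- igraph::vcount(graph)
  if (n < 3)
    stop("triangle-based global metrics are undefined for n < 3",
         call. = FALSE)
  if (is.null(nodal)) nodal <- nodal_metrics(graph)
  m <- igraph::ecount(graph)
  deg <- igraph::degree(graph)

  density <- 2 * m / (n * (n - 1))
  modularity <- if (m > 0) {
    comm <- igraph::cluster_fast_greedy(graph,
                                        weights = igraph::E(graph)$weight)
    igraph::modularity(comm)
  } else 0
  assortativity <- if (m > 1) {
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    s <- igraph::strength(graph)
    x <- c(s[ends[, 1]], s[ends[, 2]])
    y <- c(s[ends[, 2]], s[ends[, 1]])
    if (stats::sd(x) == 0) 0 else stats::cor(x, y)
  } else 0
  transitivity <- igraph::transitivity(graph, type = "global")
  if (is.nan(transitivity)) transitivity <- 0

  cpl_diam <- .cpl_diameter(graph)
  geff <- .global_efficiency(graph)

  sw <- if (m > 1 && cpl_diam[["CPL"]] > 0 && mean(nodal$CC) > 0) {
    refs <- .with_substream(seed, 999999L, {
      purrr::map(seq_len(n_rewire), function(r) {
        g2 <- .rewired_reference(graph)
        c(C = mean(.weighted_clustering(.graph_matrix(g2))),
          L = .cpl_diameter(g2)[["CPL"]])
      })
    })
    c_rand <- mean(purrr::map_dbl(refs, "C"))
    l_rand <- mean(purrr::map_dbl(refs, "L"))
    if (c_rand > 0 && l_rand > 0)
      (mean(nodal$CC) / c_rand) / (cpl_diam[["CPL"]] / l_rand)
    else NA_real_
  } else 0

  pdeg <- as.numeric(table(deg)) / n
  degent <- -sum(pdeg * log(pdeg))
  specrad <- if (m > 0) max(abs(eigen(.graph_matrix(graph),
                                      symmetric = TRUE,
                                      only.values = TRUE)$values)) else 0

  c(density = density, modularity = modularity,
    assortativity = assortativity, transitivity = transitivity,
    global_efficiency = geff, CPL = cpl_diam[["CPL"]],
    diameter = cpl_diam[["diameter"]], SW = sw, DegEnt = degent,
    SpecRad = specrad, avgDeg = mean(deg), avgCC = mean(nodal$CC),
    avgBC = mean(nodal$BC), avgEC = mean(nodal$EC),
    avgCClo = mean(nodal$CClo), avgNS = mean(nodal$NS),
    avgPR = mean(nodal$PR))
}

#' Extract the full graph-theoretical feature vector
#'
#' Concatenates the 7 nodal metrics per region with the 17 global metrics
#' into a single named vector in a frozen order (`"<metric>_<region>"`
#' blocks, then the globals): 591 features for an 82-node connectome,
#' 7n + 17 in general.
#'
#' @param mat symmetric non-negative connectivity matrix with label
#'   dimnames
#' @param seed seed for the small-world rewired references
#' @return named numeric vector of length `7 * n + 17`
#' @export
extract_gt_features <- function(mat, seed = 1L) {
  g <- build_graph(mat)
  nod <- nodal_metrics(g)
  glob <- global_metrics(g, seed = seed, nodal = nod)
  vals <- c(
    stats::setNames(nod$CC, paste0("CC_", nod$region)),
    stats::setNames(nod$DC, paste0("DC_", nod$region)),
    stats::setNames(nod$EC, paste0("EC_", nod$region)),
    stats::setNames(nod$CClo, paste0("CClo_", nod$region)),
    stats::setNames(nod$BC, paste0("BC_", nod$region)),
    stats::setNames(nod$NS, paste0("NS_", nod$region)),
    stats::setNames(nod$PR, paste0("PR_", nod$region)),
    glob
  )
  vals[gt_feature_names(nod$region)]
}

#' Extract graph features for a list of connectomes
#'
#' @param connectomes named list of connectivity matrices (one per subject)
#' @param seed seed for the small-world references
#' @return tibble: `subject_id` plus one column per graph feature
#' @export
extract_gt_table <- function(connectomes, seed = 1L) {
  rows <- purrr::imap(connectomes, function(mat, id) {
    v <- extract_gt_features(mat, seed = seed)
    dplyr::bind_cols(tibble::tibble(subject_id = id),
                     tibble::as_tibble(as.list(v)))
  })
  dplyr::bind_rows(rows)
}
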