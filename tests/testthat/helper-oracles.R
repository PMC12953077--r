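# independent oracles, deliberately naive: exhaustive path enumeration for
# shortest-path metrics, full 2^n sign enumeration for the signed-rank
# test, and a literal double loop for importance propagation

# all simple paths i -> j in an adjacency (weight > 0 = edge)
.all_simple_paths <- function(adj, i, j) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(i)
  out
}

# exhaustive shortest-path structure on inverse-weight distances (weights
# rescaled by the maximum, matching the package's distance convention)
oracle_shortest_paths <- function(mat) {
  n <- nrow(mat)
  wmax <- max(mat)
  dmat <- ifelse(mat > 0, wmax / mat, Inf)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  spaths <- vector("list", n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    paths <- .all_simple_paths(mat, i, j)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(p) {
      sum(dmat[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    dist[i, j] <- min(lens)
    spaths[[(i - 1) * n + j]] <- paths[abs(lens - min(lens)) < 1e-9]
  }
  list(dist = dist, spaths = spaths, n = n)
}

oracle_betweenness <- function(mat) {
  sp <- oracle_shortest_paths(mat)
  n <- sp$n
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- sp$spaths[[(s - 1) * n + t]]
    if (is.null(paths) || length(paths) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_path <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + on_path / length(paths)
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(mat) {
  sp <- oracle_shortest_paths(mat)
  n <- sp$n
  vapply(seq_len(n), function(u) {
    d <- sp$dist[u, ]
    reach <- which(is.finite(d) & seq_len(n) != u)
    if (length(reach) == 0) return(0)
    nr <- length(reach) + 1
    (nr - 1) / sum(d[reach]) * (nr - 1) / (n - 1)
  }, numeric(1))
}

oracle_global_sp_metrics <- function(mat) {
  sp <- oracle_shortest_paths(mat)
  n <- sp$n
  ut <- sp$dist[upper.tri(sp$dist)]
  finite <- ut[is.finite(ut)]
  inv <- 1 / sp$dist
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(CPL = mean(finite), diameter = max(finite),
       global_efficiency = sum(inv) / (n * (n - 1)))
}

# exact one-sided signed-rank p by literal enumeration of sign vectors
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  list(W = w_obs, p = mean(w_all >= w_obs - 1e-12))
}

oracle_propagate <- function(w, betas) {
  features <- names(betas[[1]])
  raw <- sapply(features, function(j) {
    s <- 0
    for (m in names(w)) s <- s + abs(w[[m]]) * abs(betas[[m]][[j]])
    s
  })
  raw / sum(raw)
}
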