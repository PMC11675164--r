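# Independent brute-force reference implementations. Deliberately written in
# plain loop style, sharing no code with the package internals, so the tests
# compare two genuinely different routes to the same quantities.

# Fixed-point iteration of the linear-threshold rule, node by node.
oracle_spread <- function(adj, states, theta, max_iters = 50) {
  n <- nrow(adj)
  deg <- integer(n)
  for (i in seq_len(n)) deg[i] <- sum(adj[i, ])
  it <- 0
  converged <- FALSE
  while (it < max_iters) {
    it <- it + 1
    nxt <- states
    for (i in seq_len(n)) {
      if (states[i] == 0) {
        active_nbrs <- 0
        for (j in seq_len(n)) {
          if (adj[i, j] && states[j] == 1) active_nbrs <- active_nbrs + 1
        }
        if (theta * deg[i] < active_nbrs) nxt[i] <- 1L
      }
    }
    if (all(nxt == states)) { converged <- TRUE; break }
    states <- nxt
  }
  list(states = states, converged = converged)
}

# Direct edge enumeration over an edge-list view of the network.
oracle_edges <- function(net) {
  idx <- which(net$adj & upper.tri(net$adj), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

oracle_Z <- function(net) {
  el <- oracle_edges(net)
  cross <- 0
  for (r in seq_len(nrow(el))) {
    if (net$community[el$i[r]] != net$community[el$j[r]]) cross <- cross + 1
  }
  cross / nrow(el)
}

# Entropy from the explicit random-walk transition distribution of each node.
oracle_entropy <- function(net) {
  n <- nrow(net$adj)
  total <- 0
  for (i in seq_len(n)) {
    nbrs <- which(net$adj[i, ])
    k <- length(nbrs)
    if (k > 0) {
      p <- rep(1 / k, k)
      total <- total + (-sum(p * log(p)))
    }
  }
  total / (n * log(n - 1))
}

oracle_tightness <- function(net, community) {
  el <- oracle_edges(net)
  internal <- 0; external <- 0
  for (r in seq_len(nrow(el))) {
    in_i <- net$community[el$i[r]] == community
    in_j <- net$community[el$j[r]] == community
    if (in_i && in_j) internal <- internal + 1
    else if (in_i || in_j) external <- external + 1
  }
  external / (internal + external)
}

# Closed-form OLS slope.
oracle_ols_slope <- function(y, x) {
  (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
}

# Small random test network: G(n, p) with a random balanced-ish partition.
random_net <- function(n, p = 0.3, n_comm = 2) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  nodes <- as.character(seq_len(n) - 1)
  dimnames(adj) <- list(nodes, nodes)
  comm <- stats::setNames(sample(0:(n_comm - 1), n, replace = TRUE), nodes)
  # keep every community id present
  comm[seq_len(min(n_comm, n))] <- 0:(min(n_comm, n) - 1)
  sitnet:::new_memory_network(adj, comm)
}

# Adjacency matrix from a bitmask over the upper triangle, for exhaustive
# graph enumeration on tiny n.
mask_to_adj <- function(mask, n) {
  adj <- matrix(FALSE, n, n)
  pos <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bitwAnd(mask, bitwShiftL(1L, pos)) != 0) adj[i, j] <- adj[j, i] <- TRUE
      pos <- pos + 1
    }
  }
  adj
}

net_from_adj <- function(adj, community = NULL) {
  n <- nrow(adj)
  nodes <- as.character(seq_len(n) - 1)
  dimnames(adj) <- list(nodes, nodes)
  if (is.null(community)) community <- stats::setNames(rep(0L, n), nodes)
  else names(community) <- nodes
  sitnet:::new_memory_network(adj, community)
}
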