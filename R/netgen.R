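#' Construct a memory network
#'
#' A memory network is a simple, undirected, unweighted graph together with a
#' fixed community partition and a binary activation state per node. It is the
#' basic object every other function in the package operates on.
#'
#' @param edges two-column matrix or data frame of edge endpoints (node
#'   labels). May have zero rows.
#' @param communities named vector mapping every node label to an integer
#'   community id. The node set of the network is exactly `names(communities)`;
#'   isolated nodes are allowed.
#'
#' @details Self-loops and duplicated edges are rejected, as are edges whose
#'   endpoints do not appear in `communities`. All activation states start
#'   inactive (0).
#'
#' @return An object of class `memory_network` with elements `adj` (logical
#'   adjacency matrix), `community` (named integer vector) and `states`
#'   (named integer vector of 0/1).
#' @examples
#' net <- memory_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
#'                       c(a = 0, b = 0, c = 1))
#' compute_Z(net) # 2/3
#' @export
memory_network <- function(edges, communities) {
  if (is.null(names(communities)) || any(!nzchar(names(communities)))) {
    abort_malformed_input("`communities` must be a named vector (node -> community id)")
  }
  nodes <- names(communities)
  if (anyDuplicated(nodes)) {
    abort_malformed_input("duplicated node labels in the community assignment")
  }
  comm <- as.integer(communities)
  if (anyNA(comm)) abort_malformed_input("community ids must be integers")
  names(comm) <- nodes

  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(character(), ncol = 2)
  if (ncol(edges) != 2) abort_malformed_input("`edges` must have two columns")
  mode(edges) <- "character"

  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges)), nodes)
    if (length(unknown) > 0) {
      abort_malformed_input(paste0(
        "edge endpoint(s) absent from the community assignment: ",
        paste(head(unknown, 5), collapse = ", ")))
    }
    if (any(edges[, 1] == edges[, 2])) {
      abort_malformed_input("self-loops are not allowed")
    }
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    key <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key)) {
      abort_malformed_input("duplicated edges are not allowed")
    }
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }

  new_memory_network(adj, comm)
}

## internal constructor: trusts its inputs
new_memory_network <- function(adj, community, states = NULL) {
  nodes <- rownames(adj)
  if (is.null(states)) states <- setNames(integer(length(nodes)), nodes)
  structure(
    list(adj = adj, community = community, states = states),
    class = "memory_network"
  )
}

#' Build an initially segregated memory network
#'
#' Constructs `C` equally sized communities, each an independent random
#' `k_int`-regular graph, then adds `L_ext` inter-community edges placed
#' uniformly at random over distinct-community node pairs so that the degree
#' of integration of the result approximates the target `Z0`:
#' `L_ext = round(Z0 * L_int / (1 - Z0))` (at least 1 whenever `Z0 > 0`).
#'
#' @param N total number of nodes; must be divisible by `C`.
#' @param C number of communities (default 4).
#' @param Z0 target degree of integration in `[0, 1)`.
#' @param seed optional integer; when given, the construction is
#'   bit-reproducible (same edge set for the same seed).
#' @param k_int intra-community degree; defaults to half the community size,
#'   `(N/C)/2`. Must make a regular graph feasible (`k_int * (N/C)` even,
#'   `0 < k_int < N/C`).
#'
#' @return A [memory_network] with nodes labelled `"0" ... "N-1"` ordered
#'   community by community (communities `0 ... C-1`), all states inactive.
#' @examples
#' net <- build_segregated_network(128, 4, 0.01, seed = 1)
#' compute_Z(net) # 10/1034, approximately 0.01
#' @export
build_segregated_network <- function(N, C = 4, Z0, seed = NULL, k_int = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N); C <- as.integer(C)
  if (N <= 0 || C <= 0 || N %% C != 0) {
    abort_invalid_config("N must be a positive multiple of C")
  }
  size <- N %/% C
  if (is.null(k_int)) k_int <- size %/% 2
  k_int <- as.integer(k_int)
  if (k_int < 1 || k_int >= size || (k_int * size) %% 2 != 0) {
    abort_invalid_config(sprintf(
      "cannot build a %d-regular graph on %d nodes per community", k_int, size))
  }
  if (!is.numeric(Z0) || Z0 < 0 || Z0 >= 1) {
    abort_invalid_config("Z0 must lie in [0, 1)")
  }

  nodes <- as.character(seq_len(N) - 1L)
  community <- setNames(rep(0:(C - 1L), each = size), nodes)
  adj <- matrix(FALSE, N, N, dimnames = list(nodes, nodes))
  for (ci in seq_len(C)) {
    g <- igraph::sample_k_regular(size, k_int)
    el <- igraph::as_edgelist(g, names = FALSE) + (ci - 1L) * size
    adj[el] <- TRUE
    adj[el[, 2:1, drop = FALSE]] <- TRUE
  }
  L_int <- sum(adj) / 2

  L_ext <- if (Z0 > 0) max(1L, as.integer(round(Z0 * L_int / (1 - Z0)))) else 0L
  if (L_ext > 0) {
    cross <- outer(community, community, "!=") & upper.tri(adj)
    avail <- which(cross)
    if (L_ext > length(avail)) {
      abort_invalid_config(sprintf(
        "requested %d inter-community edges but only %d distinct pairs exist",
        L_ext, length(avail)))
    }
    pick <- sample(avail, L_ext)
    i <- ((pick - 1L) %% N) + 1L
    j <- ((pick - 1L) %/% N) + 1L
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }

  new_memory_network(adj, community)
}

#' Degree of integration
#'
#' Fraction of edges whose endpoints lie in different communities, each edge
#' counted once: `Z = L_ext / L`. `Z ~ 0` characterises a highly segregated
#' (modular) network and `Z ~ 1` a fully integrated one.
#'
#' @param net a [memory_network] with at least one edge.
#' @return Numeric scalar in `[0, 1]`.
#' @export
compute_Z <- function(net) {
  stopifnot(inherits(net, "memory_network"))
  L <- sum(net$adj) / 2
  if (L < 1) abort_undefined_metric("degree of integration is undefined on an edgeless network")
  cross <- outer(net$community, net$community, "!=")
  (sum(net$adj & cross) / 2) / L
}

#' Number of nodes, edges and communities of a memory network
#' @param net a [memory_network].
#' @return `network_size`: integer node count. `edge_count`: integer edge
#'   count. `community_ids`: sorted vector of community ids.
#' @export
network_size <- function(net) nrow(net$adj)

#' @rdname network_size
#' @export
edge_count <- function(net) as.integer(sum(net$adj) / 2)

#' @rdname network_size
#' @export
community_ids <- function(net) sort(unique(net$community))

#' Convert a memory network to an igraph object
#'
#' Node community and activation state are attached as the vertex attributes
#' `community` and `state`.
#'
#' @param net a [memory_network].
#' @return An [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "memory_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
  igraph::V(g)$community <- unname(net$community)
  igraph::V(g)$state <- unname(net$states)
  g
}

#' @export
print.memory_network <- function(x, ...) {
  L <- sum(x$adj) / 2
  cat(sprintf(
    "<memory_network> %d nodes, %d edges, %d communities, %d active\n",
    nrow(x$adj), L, length(unique(x$community)), sum(x$states)))
  if (L >= 1) cat(sprintf("  degree of integration Z = %.4g\n", compute_Z(x)))
  invisible(x)
}

## shared validation used by tests and loaders
validate_memory_network <- function(net) {
  stopifnot(
    inherits(net, "memory_network"),
    is.logical(net$adj),
    isSymmetric(unname(net$adj)),
    !any(diag(net$adj)),
    identical(names(net$community), rownames(net$adj)),
    identical(names(net$states), rownames(net$adj)),
    all(net$states %in% c(0L, 1L))
  )
  invisible(net)
}
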