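#' Load a memory network from disk
#'
#' Reads a graph from a whitespace-separated edge list (`"u v"` per line, no
#' header, undirected) or a GraphML file, together with a community
#' assignment. For edge lists the partition sidecar is required; for GraphML
#' the community is taken from the `community` node attribute unless a
#' sidecar is given.
#'
#' @param path path to the graph file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param partition_path optional CSV with columns `node,community`.
#' @return A [memory_network] with all states inactive.
#' @export
load_network <- function(path, format = c("edgelist", "graphml"),
                         partition_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_malformed_input(paste0("no such file: ", path))

  if (format == "edgelist") {
    if (is.null(partition_path)) {
      abort_malformed_input("an edge list needs a partition sidecar (node,community CSV)")
    }
    communities <- read_partition(partition_path)
    info <- file.info(path)
    edges <- if (!is.na(info$size) && info$size > 0) {
      tab <- read.table(path, colClasses = "character")
      if (ncol(tab) < 2) abort_malformed_input("edge list must have two columns per line")
      as.matrix(tab[, 1:2])
    } else {
      matrix(character(), ncol = 2)
    }
    return(memory_network(edges, communities))
  }

  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) abort_malformed_input(paste0("cannot parse GraphML: ", conditionMessage(e)))
  )
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "id")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)) - 1L)
  communities <- if (!is.null(partition_path)) {
    read_partition(partition_path)
  } else {
    comm <- igraph::vertex_attr(g, "community")
    if (is.null(comm)) {
      abort_malformed_input("GraphML has no 'community' node attribute and no partition sidecar was given")
    }
    setNames(as.integer(comm), labels)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(labels[el[, 1]], labels[el[, 2]])
  net <- memory_network(edges, communities)
  if (!setequal(labels, rownames(net$adj))) {
    abort_malformed_input("partition does not cover the GraphML node set")
  }
  net
}

read_partition <- function(path) {
  if (!file.exists(path)) abort_malformed_input(paste0("no such file: ", path))
  tab <- read.csv(path, colClasses = c("character", "integer"))
  if (!all(c("node", "community") %in% names(tab))) {
    abort_malformed_input("partition CSV needs columns `node` and `community`")
  }
  setNames(as.integer(tab$community), tab$node)
}

#' Write a memory network to disk
#'
#' Writes the edge set as a two-column whitespace-separated edge list and the
#' community assignment as a `node,community` CSV. Output is deterministic
#' (edges sorted by node order), so identical networks produce byte-identical
#' files.
#'
#' @param net a [memory_network].
#' @param edge_path destination for the edge list.
#' @param partition_path destination for the partition CSV.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_network <- function(net, edge_path, partition_path) {
  stopifnot(inherits(net, "memory_network"))
  nodes <- rownames(net$adj)
  idx <- which(net$adj & upper.tri(net$adj), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- paste(nodes[idx[, 1]], nodes[idx[, 2]])
  writeLines(lines, edge_path)
  write.csv(
    data.frame(node = nodes, community = unname(net$community)),
    partition_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, partition_path))
}

#' Deterministic small networks used throughout the test suite
#'
#' * `"toy-triangle"`: three nodes `a, b, c` forming a triangle with
#'   partition `{a: 0, b: 0, c: 1}`, so `Z = 2/3`.
#' * `"two-clique-bridge"`: two 4-cliques joined by a single edge, one
#'   community each, so `Z = 1/13`.
#' * `"paper-default"`: the default simulation substrate,
#'   `build_segregated_network(128, 4, 0.01, seed)`.
#'
#' @param kind fixture name.
#' @param seed RNG seed (only used by `"paper-default"`).
#' @return A [memory_network].
#' @export
make_fixture <- function(kind = c("toy-triangle", "two-clique-bridge", "paper-default"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "toy-triangle" = memory_network(
      rbind(c("a", "b"), c("b", "c"), c("a", "c")),
      c(a = 0L, b = 0L, c = 1L)),
    "two-clique-bridge" = {
      left <- paste0("l", 1:4); right <- paste0("r", 1:4)
      cl <- function(v) t(utils::combn(v, 2))
      edges <- rbind(cl(left), cl(right), c("l1", "r1"))
      memory_network(edges, setNames(rep(c(0L, 1L), each = 4), c(left, right)))
    },
    "paper-default" = build_segregated_network(128, 4, 0.01, seed = seed)
  )
}
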