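#' Random-walker network entropy
#'
#' Degree-based normalised Shannon entropy of the one-step random-walk
#' transition distributions. A node of degree `k` jumps to each neighbour
#' with probability `1/k`, giving per-node entropy `h_n = ln k_n`; isolated
#' nodes contribute 0. The network entropy is the average normalised by the
#' maximum attainable value `ln(N - 1)`:
#' `H = sum(h_n) / (N * ln(N - 1))`, so `H = 1` exactly on the complete
#' graph and low `H` marks sparse configurations with little uncertainty in
#' where activation flows.
#'
#' @param net a [memory_network] with at least 3 nodes.
#' @return Numeric scalar in `[0, 1]`.
#' @export
network_entropy <- function(net) {
  stopifnot(inherits(net, "memory_network"))
  N <- nrow(net$adj)
  if (N < 3) abort_undefined_metric("network entropy needs at least 3 nodes")
  k <- colSums(net$adj)
  sum(log(pmax(k, 1))) / (N * log(N - 1))
}

#' Malleability index of a reactivation
#'
#' Relative connectivity change induced by one reactivation:
#' `deltaL = (L_created + L_removed) / L_before`. Zero means the rewiring
#' left the edge count composition untouched; only the counts matter, not
#' which edges changed.
#'
#' @param outcome a `reactivation_outcome` (from [reactivate()] or
#'   [apply_plasticity()]), or any list with elements `edges_created`,
#'   `edges_removed` and `edges_before`.
#' @return Non-negative numeric scalar.
#' @export
malleability <- function(outcome) {
  need <- c("edges_created", "edges_removed", "edges_before")
  if (!all(need %in% names(outcome))) {
    abort_invalid_config("outcome must carry edges_created, edges_removed and edges_before")
  }
  if (outcome$edges_before < 1) {
    abort_undefined_metric("malleability is undefined when there were no edges before the reactivation")
  }
  (outcome$edges_created + outcome$edges_removed) / outcome$edges_before
}

#' Amplitude of the malleability nonlinearity
#'
#' Height of the inverted-U in a malleability trajectory: the maximum of the
#' per-reactivation (run-averaged) malleability minus the mean of its last
#' five entries. A clearly positive amplitude indicates an early malleability
#' window; values near or below zero indicate a flat or still-rising
#' trajectory.
#'
#' @param trajectory numeric vector of per-reactivation mean malleability,
#'   length at least 6.
#' @return Numeric scalar (may be negative; reported as computed).
#' @export
amp_deltaL <- function(trajectory) {
  if (length(trajectory) < 6) {
    abort_invalid_config("the trajectory must cover at least 6 reactivations")
  }
  max(trajectory) - mean(tail(trajectory, 5))
}

#' Community tightness
#'
#' Fraction of a community's incident edges that leave the community:
#' external incident edges over all edges with at least one endpoint in the
#' community. `T ~ 0` marks a cohesive, clearly identifiable community;
#' `T = 1/2` means as many links leave the community as stay inside it;
#' `T ~ 1` marks a community dissolved into the rest of the network.
#'
#' @param net a [memory_network].
#' @param community a community id present in the partition.
#' @return Numeric scalar in `[0, 1]`.
#' @export
tightness <- function(net, community) {
  stopifnot(inherits(net, "memory_network"))
  if (!community %in% net$community) {
    abort_invalid_config(paste0("no community with id ", community))
  }
  members <- net$community == community
  internal <- sum(net$adj[members, members, drop = FALSE]) / 2
  external <- sum(net$adj[members, !members, drop = FALSE])
  total <- internal + external
  if (total < 1) {
    abort_undefined_metric("tightness is undefined for a community with no incident edges")
  }
  external / total
}

#' Tightness decay slope
#'
#' Ordinary-least-squares slope of a per-reactivation mean tightness series
#' against the (1-based) reactivation index, fitted over a window of
#' reactivations (default 3 to 9 inclusive). Quantifies how fast a
#' repeatedly reactivated community re-segregates.
#'
#' @param T_series numeric vector of mean tightness values, entry `r` being
#'   the value after reactivation `r`.
#' @param from,to window of reactivation indices for the fit.
#' @return Numeric slope (tightness change per reactivation).
#' @export
tightness_slope <- function(T_series, from = 3L, to = 9L) {
  if (from >= to) abort_invalid_config("`from` must be below `to`")
  if (length(T_series) < to) {
    abort_invalid_config(sprintf(
      "the series must cover reactivations %d..%d (got length %d)",
      from, to, length(T_series)))
  }
  idx <- seq(from, to)
  unname(coef(lm(T_series[idx] ~ idx))[2])
}
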