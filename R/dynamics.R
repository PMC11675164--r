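#' Reactivation parameters
#'
#' Bundles the knobs of a single reactivation event: the cue-driven turn-on,
#' the linear-threshold spreading and its iteration cap.
#'
#' @param Int turn-on intensity: mean fraction of a community's nodes
#'   activated by the cue, in `[0, 1]`. Models the overlap between the cue
#'   and the stored memory.
#' @param theta excitability threshold in `(0, 1)`: a node activates when
#'   strictly more than `theta * degree` of its neighbours are active.
#' @param turn_on_sd standard deviation of the per-community turn-on
#'   fraction (default 0.05). The drawn fraction is clipped to `[0, 1]`.
#' @param max_iters cap on synchronous spreading updates (default 50).
#' @param target_communities community ids receiving the cue; `NULL` (the
#'   default) targets every community.
#' @param turn_on_select how cue nodes are picked once the count
#'   `round(fraction * community size)` is fixed. `"draws"` (default) makes
#'   that many uniform draws over the community and keeps the distinct ones,
#'   so collisions can reduce the activated count slightly; `"distinct"`
#'   samples exactly that many distinct nodes.
#' @return An object of class `reactivation_params`.
#' @export
reactivation_params <- function(Int, theta, turn_on_sd = 0.05, max_iters = 50L,
                                target_communities = NULL,
                                turn_on_select = c("draws", "distinct")) {
  turn_on_select <- match.arg(turn_on_select)
  if (!is.numeric(Int) || Int < 0 || Int > 1) abort_invalid_config("Int must lie in [0, 1]")
  if (!is.numeric(theta) || theta <= 0) abort_invalid_config("theta must be positive")
  if (turn_on_sd < 0) abort_invalid_config("turn_on_sd must be non-negative")
  if (max_iters < 1) abort_invalid_config("max_iters must be at least 1")
  structure(
    list(Int = Int, theta = theta, turn_on_sd = turn_on_sd,
         max_iters = as.integer(max_iters),
         target_communities = if (is.null(target_communities)) NULL else as.integer(target_communities),
         turn_on_select = turn_on_select),
    class = "reactivation_params")
}

resolve_targets <- function(net, params) {
  ids <- sort(unique(net$community))
  targets <- params$target_communities
  if (is.null(targets)) return(ids)
  missing <- setdiff(targets, ids)
  if (length(missing) > 0) {
    abort_invalid_config(paste0("unknown target community id(s): ",
                                paste(missing, collapse = ", ")))
  }
  targets
}

#' Cue-driven turn-on
#'
#' For each targeted community independently, draws an activation fraction
#' from `Normal(Int, turn_on_sd)` clipped to `[0, 1]`, converts it to a node
#' count by nearest-integer rounding of `fraction * community size`, and
#' activates that many nodes chosen uniformly from the community (see
#' `turn_on_select` in [reactivation_params()] for the two selection rules).
#'
#' @param net a [memory_network] with every state inactive.
#' @param params a [reactivation_params].
#' @param seed optional RNG seed.
#' @return The network with the cue states set to 1.
#' @export
turn_on <- function(net, params, seed = NULL) {
  stopifnot(inherits(net, "memory_network"), inherits(params, "reactivation_params"))
  if (!is.null(seed)) set.seed(seed)
  if (any(net$states != 0L)) {
    abort_invalid_config("turn_on expects a fresh reactivation: all states must be 0")
  }
  for (ci in resolve_targets(net, params)) {
    members <- which(net$community == ci)
    f <- rnorm(1, params$Int, params$turn_on_sd)
    f <- min(max(f, 0), 1)
    n_on <- round(f * length(members))
    if (n_on > 0) {
      chosen <- if (params$turn_on_select == "draws") {
        unique(sample(members, n_on, replace = TRUE))
      } else {
        sample(members, n_on)
      }
      net$states[chosen] <- 1L
    }
  }
  net
}

#' Linear-threshold activation spreading
#'
#' Synchronous deterministic diffusion: at each step every inactive node
#' with strictly more than `theta * degree` active neighbours becomes
#' active; active nodes never deactivate. Stops at the first step whose
#' update changes no state (`converged = TRUE`) or after `max_iters` updates
#' (`converged = FALSE`).
#'
#' @param net a [memory_network] whose states were set by [turn_on()].
#' @param params a [reactivation_params].
#' @return A list with `states` (named 0/1 vector at the fixed point or cap),
#'   `spreading_iters` (number of synchronous updates evaluated) and
#'   `converged`.
#' @export
spread <- function(net, params) {
  stopifnot(inherits(net, "memory_network"), inherits(params, "reactivation_params"))
  A <- net$adj * 1
  k <- colSums(A)
  thr <- params$theta * k
  s <- as.numeric(net$states)
  iters <- 0L
  converged <- FALSE
  while (iters < params$max_iters) {
    iters <- iters + 1L
    s_next <- as.numeric(s == 1 | (A %*% s) > thr)
    if (identical(s_next, s)) {
      converged <- TRUE
      break
    }
    s <- s_next
  }
  list(states = setNames(as.integer(s), rownames(net$adj)),
       spreading_iters = iters, converged = converged)
}

#' Hebbian plasticity rewiring
#'
#' Applies the pairwise rewiring rule simultaneously to every unordered node
#' pair of the network: two active nodes end up connected (the edge is
#' created if absent), an active-inactive pair ends up disconnected (the
#' edge is removed if present), and pairs of inactive nodes keep their edge
#' status. Afterwards every node state is reset to 0 so the next
#' reactivation starts from an all-inactive network.
#'
#' @param net a [memory_network].
#' @param steady_states named 0/1 vector covering all nodes (usually the
#'   `states` element returned by [spread()]).
#' @return A list with `net` (the rewired network, states reset) and
#'   `outcome`, a `reactivation_outcome` holding `steady_states`,
#'   `edges_created` (`L^c`), `edges_removed` (`L^R`) and `edges_before`
#'   (`L_-1`).
#' @export
apply_plasticity <- function(net, steady_states) {
  stopifnot(inherits(net, "memory_network"))
  nodes <- rownames(net$adj)
  if (!setequal(names(steady_states), nodes)) {
    abort_invalid_config("steady_states must cover exactly the node set")
  }
  s <- as.integer(steady_states[nodes])
  active <- which(s == 1L)
  inactive <- which(s == 0L)
  edges_before <- as.integer(sum(net$adj) / 2)

  created <- 0L
  if (length(active) > 1) {
    sub <- net$adj[active, active, drop = FALSE]
    n_act <- length(active)
    created <- as.integer(n_act * (n_act - 1) / 2 - sum(sub) / 2)
    net$adj[active, active] <- TRUE
    diag(net$adj) <- FALSE
  }
  removed <- 0L
  if (length(active) > 0 && length(inactive) > 0) {
    removed <- as.integer(sum(net$adj[active, inactive, drop = FALSE]))
    net$adj[active, inactive] <- FALSE
    net$adj[inactive, active] <- FALSE
  }
  net$states[] <- 0L

  outcome <- structure(
    list(steady_states = setNames(s, nodes),
         spreading_iters = NA_integer_, converged = NA,
         edges_created = created, edges_removed = removed,
         edges_before = edges_before),
    class = "reactivation_outcome")
  list(net = net, outcome = outcome)
}

#' Run one full reactivation
#'
#' Composes the three stages of a reactivation event: stochastic cue-driven
#' [turn_on()], deterministic linear-threshold [spread()] to a steady state,
#' and the Hebbian rewiring of [apply_plasticity()]. The returned network has
#' all states reset to 0, ready for the next reactivation.
#'
#' @inheritParams turn_on
#' @return A list with `net` (the rewired network) and `outcome` (a
#'   `reactivation_outcome`: steady states, spreading iteration count,
#'   convergence flag and edge-change counts).
#' @examples
#' net <- build_segregated_network(16, 4, 0.3, seed = 1)
#' res <- reactivate(net, reactivation_params(Int = 0.3, theta = 0.4), seed = 2)
#' res$outcome$edges_created
#' @export
reactivate <- function(net, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- turn_on(net, params)
  sp <- spread(net, params)
  res <- apply_plasticity(net, sp$states)
  res$outcome$spreading_iters <- sp$spreading_iters
  res$outcome$converged <- sp$converged
  res
}

#' @export
print.reactivation_outcome <- function(x, ...) {
  cat(sprintf(
    "<reactivation_outcome> %d active at steady state (%d iters, %s), %d edges before, +%d / -%d\n",
    sum(x$steady_states), x$spreading_iters,
    if (isTRUE(x$converged)) "converged" else "capped",
    x$edges_before, x$edges_created, x$edges_removed))
  invisible(x)
}
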