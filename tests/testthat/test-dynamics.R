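params_fixed <- function(Int, theta = 0.4, ...) {
  reactivation_params(Int = Int, theta = theta, turn_on_sd = 0, ...)
}

test_that("turn-on activates the expected counts at zero noise", {
  net <- build_segregated_network(128, 4, 0.01, seed = 1)

  none <- turn_on(net, params_fixed(0), seed = 1)
  expect_equal(sum(none$states), 0)

  all_on <- turn_on(net, params_fixed(1, turn_on_select = "distinct"), seed = 1)
  expect_equal(sum(all_on$states), 128)

  # distinct sampling gives exactly round(0.3 * 32) = 10 per community
  ten <- turn_on(net, params_fixed(0.3, turn_on_select = "distinct"), seed = 1)
  for (ci in 0:3) {
    expect_equal(sum(ten$states[ten$community == ci]), 10)
  }

  # collision-allowing draws activate at most that many, at least one
  draws <- turn_on(net, params_fixed(0.3), seed = 1)
  for (ci in 0:3) {
    n_on <- sum(draws$states[draws$community == ci])
    expect_lte(n_on, 10)
    expect_gte(n_on, 1)
  }
})

test_that("turn-on validates its preconditions", {
  net <- build_segregated_network(16, 4, 0.3, seed = 1)
  expect_error(turn_on(net, params_fixed(0.3, target_communities = 9)),
               class = "sitnet_invalid_config")
  dirty <- net
  dirty$states[1] <- 1L
  expect_error(turn_on(dirty, params_fixed(0.3)), class = "sitnet_invalid_config")
})

test_that("spreading follows the threshold rule on hand-worked cases", {
  p <- reactivation_params(Int = 0, theta = 0.4)

  # path a-b-c seeded at a: b (k=2, needs > 0.8) then c (k=1, needs > 0.4)
  path <- memory_network(rbind(c("a", "b"), c("b", "c")), c(a = 0, b = 0, c = 0))
  path$states["a"] <- 1L
  out <- spread(path, p)
  expect_true(out$converged)
  expect_equal(unname(out$states), c(1L, 1L, 1L))
  expect_equal(out$spreading_iters, 3) # two growth steps + confirming step

  # star hub with k = 5 and 2 active leaves: 2 < 0.4 * 5 with strict inequality
  leaves <- paste0("l", 1:5)
  star <- memory_network(cbind("hub", leaves),
                         stats::setNames(rep(0, 6), c("hub", leaves)))
  star$states[c("l1", "l2")] <- 1L
  out <- spread(star, p)
  expect_true(out$converged)
  expect_equal(sum(out$states), 2)

  # all-active is a fixed point recognised in one check
  full <- path
  full$states[] <- 1L
  out <- spread(full, p)
  expect_true(out$converged)
  expect_equal(out$spreading_iters, 1)

  # degree-0 node never self-activates
  iso <- memory_network(rbind(c("a", "b")), c(a = 0, b = 0, c = 0))
  iso$states["a"] <- 1L
  out <- spread(iso, p)
  expect_equal(unname(out$states[c("b", "c")]), c(1L, 0L))
})

test_that("activation grows monotonically and spreading is deterministic", {
  set.seed(7)
  p <- reactivation_params(Int = 0, theta = 0.3)
  for (rep in 1:10) {
    net <- random_net(12, p = 0.3)
    net$states[sample(12, 3)] <- 1L
    before <- net$states
    out1 <- spread(net, p)
    out2 <- spread(net, p)
    expect_identical(out1, out2)
    expect_true(all(out1$states >= before)) # no deactivation
    expect_lte(out1$spreading_iters, 50)
  }
})

test_that("plasticity applies the pairwise rule and resets states", {
  comm <- c(a = 0, b = 0, c = 1, d = 1)

  # both active, no prior edge -> created
  net <- memory_network(matrix(character(), ncol = 2), comm)
  res <- apply_plasticity(net, c(a = 1, b = 1, c = 0, d = 0))
  expect_equal(res$outcome$edges_created, 1L)
  expect_true(res$net$adj["a", "b"])

  # active-inactive with prior edge -> removed; inactive pair keeps its edge
  net <- memory_network(rbind(c("a", "c"), c("c", "d")), comm)
  res <- apply_plasticity(net, c(a = 1, b = 0, c = 0, d = 0))
  expect_equal(res$outcome$edges_removed, 1L)
  expect_false(res$net$adj["a", "c"])
  expect_true(res$net$adj["c", "d"])
  expect_equal(res$outcome$edges_before, 2L)
  expect_true(all(res$net$states == 0))
})

test_that("after plasticity the active set is a clique with no active-inactive edge", {
  set.seed(21)
  for (rep in 1:15) {
    net <- random_net(15, p = 0.25, n_comm = 3)
    p <- reactivation_params(Int = runif(1, 0.1, 0.6), theta = runif(1, 0.2, 0.6))
    res <- reactivate(net, p)
    act <- names(which(res$outcome$steady_states == 1))
    inact <- setdiff(rownames(net$adj), act)
    if (length(act) > 1) {
      sub <- res$net$adj[act, act]
      expect_true(all(sub[upper.tri(sub)]))
    }
    if (length(act) > 0 && length(inact) > 0) {
      expect_equal(sum(res$net$adj[act, inact]), 0)
    }
  }
})

test_that("reactivation endpoints behave as designed", {
  net <- build_segregated_network(16, 4, 0.3, seed = 3)

  # Int = 0: nothing happens
  res <- reactivate(net, params_fixed(0), seed = 1)
  expect_identical(res$net$adj, net$adj)
  expect_equal(res$outcome$edges_created + res$outcome$edges_removed, 0L)

  # Int = 1: complete graph, nothing removed
  res <- reactivate(net, params_fixed(1, turn_on_select = "distinct"), seed = 1)
  expect_equal(edge_count(res$net), 16L * 15L / 2L)
  expect_equal(res$outcome$edges_removed, 0L)
  expect_equal(malleability(res$outcome), (120 - 23) / 23)

  # reproducibility from the seed
  a <- reactivate(net, params_fixed(0.4), seed = 99)
  b <- reactivate(net, params_fixed(0.4), seed = 99)
  expect_identical(a$net$adj, b$net$adj)
})

test_that("one reactivation of the default substrate raises integration", {
  p <- reactivation_params(Int = 0.3, theta = 0.4)
  for (s in 1:25) {
    net <- build_segregated_network(128, 4, 0.01, seed = s)
    z0 <- compute_Z(net)
    res <- reactivate(net, p, seed = 1000 + s)
    expect_gt(compute_Z(res$net), z0)
  }
})
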