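test_that("transition probabilities obey the two-state closed form", {
  expect_equal(transition_prob(1, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_prob(0.3, 1e9),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  P <- transition_prob(1, 1)
  expect_equal(P[1, 2], (1 - exp(-2)) / 2)
  # independent check: numerical matrix exponential of the generator
  Q <- matrix(c(-0.7, 0.7, 0.7, -0.7), 2, 2)
  expect_equal(unname(transition_prob(0.7, 1.3)),
               ape::matexpo(Q * 1.3), tolerance = 1e-10)
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  set.seed(1)
  for (rep in 1:20) {
    mu <- runif(1, 0.05, 5)
    t1 <- runif(1, 0, 3)
    t2 <- runif(1, 0, 3)
    P1 <- transition_prob(mu, t1)
    expect_equal(rowSums(P1), c("0" = 1, "1" = 1))
    expect_lt(max(abs(P1 %*% transition_prob(mu, t2) -
                        transition_prob(mu, t1 + t2))), 1e-12)
  }
})

test_that("pruning likelihood matches exhaustive enumeration", {
  # degenerate zero-length cherries have closed-form likelihoods
  cherry <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(prune_likelihood(cherry, c(A = 1, B = 1), 1), 0.5)
  expect_equal(prune_likelihood(cherry, c(A = 0, B = 1), 1), 0)
  set.seed(7)
  for (n in c(4, 6, 8)) {
    tr <- simulate_yule_tree(n, 1)
    traits <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
    mu <- runif(1, 0.1, 2)
    expect_equal(prune_likelihood(tr, traits, mu),
                 brute_likelihood(tr, traits, mu), tolerance = 1e-10)
  }
  expect_error(prune_likelihood(cherry, c(A = 1), 1), "missing trait")
})

test_that("tip-state likelihoods sum to one over all assignments", {
  set.seed(8)
  tr <- simulate_yule_tree(6, 1)
  total <- sum(vapply(0:63, function(code) {
    traits <- setNames(as.integer(intToBits(code))[1:6], tr$tip.label)
    prune_likelihood(tr, traits, 0.7)
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("ML rate matches a grid search and scales with branch lengths", {
  # unequal states on a two-tip tree: the likelihood (1 - e^(-4 mu))/4 is
  # monotone, so compare the achieved maximum against a dense grid rather
  # than arg-maxima on the flat plateau
  tr <- ape::read.tree(text = "(A:1,B:1);")
  traits <- c(A = 0, B = 1)
  fit <- ml_rate(tr, traits)
  grid <- exp(seq(log(1e-6), log(fit$bounds[2]), length.out = 20001))
  ll <- vapply(grid, function(m) prune_likelihood(tr, traits, m, log = TRUE),
               numeric(1))
  expect_gte(fit$loglik, max(ll) - 1e-8)
  # an informative case with an interior maximum: a 4-tip tree
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  traits4 <- c(A = 0, B = 0, C = 1, D = 1)
  fit4 <- ml_rate(tr4, traits4)
  grid4 <- exp(seq(log(1e-6), log(fit4$bounds[2]), length.out = 20001))
  ll4 <- vapply(grid4, function(m) prune_likelihood(tr4, traits4, m,
                                                    log = TRUE), numeric(1))
  expect_equal(fit4$mu_hat, grid4[which.max(ll4)], tolerance = 1e-3)
  # rate-time non-identifiability: doubling lengths halves the rate
  set.seed(11)
  tr2 <- simulate_yule_tree(30, 1)
  traits2 <- simulate_trait_history(tr2, 0.8)$traits
  if (length(unique(traits2)) == 2) {
    m1 <- ml_rate(tr2, traits2)$mu_hat
    tr2$edge.length <- tr2$edge.length * 2
    expect_equal(ml_rate(tr2, traits2)$mu_hat, m1 / 2, tolerance = 1e-3)
  }
  expect_warning(f <- ml_rate(tr, c(A = 1, B = 1)), "monomorphic")
  expect_equal(f$mu_hat, 1e-6)
})

test_that("branch paths respect the endpoint parity constraint", {
  set.seed(13)
  expect_length(sample_branch_path(0, 0, 0, 1), 0)
  expect_error(sample_branch_path(0, 1, 0, 1), "impossible")
  for (rep in 1:200) {
    a <- rbinom(1, 1, 0.5); b <- rbinom(1, 1, 0.5)
    t <- runif(1, 0.01, 4); mu <- runif(1, 0.05, 8)
    path <- sample_branch_path(a, b, t, mu)
    expect_equal(length(path) %% 2, as.integer(a != b))
    expect_true(all(path >= 0 & path <= t))
    expect_false(is.unsorted(path))
  }
})

test_that("conditional jump counts match their closed-form means", {
  set.seed(17)
  n <- 2e4
  lam <- 1
  odd <- halorange:::r_parity_pois(rep(lam, n), rep(TRUE, n))
  even <- halorange:::r_parity_pois(rep(lam, n), rep(FALSE, n))
  expect_lt(abs(mean(odd) - cond_mean_jumps(lam, TRUE)),
            3 * sd(odd) / sqrt(n))
  expect_lt(abs(mean(even) - cond_mean_jumps(lam, FALSE)),
            3 * sd(even) / sqrt(n))
  expect_true(all(odd %% 2 == 1))
  expect_true(all(even %% 2 == 0))
  # large-rate branch uses the rejection path
  big <- halorange:::r_parity_pois(rep(25, 2000), rep(TRUE, 2000))
  expect_true(all(big %% 2 == 1))
  expect_lt(abs(mean(big) - cond_mean_jumps(25, TRUE)), 3 * sd(big) / sqrt(2000))
})

test_that("sampled node states follow their exact joint conditional", {
  set.seed(19)
  tr <- ape::read.tree(text = "((A:0.5,B:1.0):0.7,C:2.0);")
  traits <- c(A = 1, B = 0, C = 1)
  mu <- 0.8
  n <- 5e4
  S <- sample_node_states(tr, traits, mu, n)
  # exact joint over root (node 4) and the cherry ancestor (node 5)
  Pt <- function(t, a, b) transition_prob(mu, t)[a + 1, b + 1]
  joint <- matrix(0, 2, 2)
  for (r in 0:1) for (s in 0:1) {
    joint[r + 1, s + 1] <- 0.5 * Pt(0.7, r, s) * Pt(0.5, s, 1) *
      Pt(1.0, s, 0) * Pt(2.0, r, 1)
  }
  joint <- joint / sum(joint)
  for (r in 0:1) for (s in 0:1) {
    p <- joint[r + 1, s + 1]
    emp <- mean(S[4, ] == r & S[5, ] == s)
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
  # zero-length tree pins internal states to the shared tip state
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  S0 <- sample_node_states(tr0, c(A = 0, B = 0, C = 0), 1, 100)
  expect_true(all(S0 == 0))
})

test_that("stochastic maps reproduce the two-tip closed-form mean", {
  set.seed(23)
  tr <- ape::read.tree(text = "(A:0.8,B:1.3);")
  traits <- c(A = 0, B = 1)
  mu <- 0.9
  # marginalize the root over its exact conditional, then apply the
  # per-branch conditional means
  pp <- halorange:::prune_partials(tr, traits, mu)
  pr <- pp$partials[3, ] / sum(pp$partials[3, ])
  expected <- sum(vapply(0:1, function(r) {
    pr[r + 1] * (cond_mean_jumps(mu * 0.8, r != 0) +
                   cond_mean_jumps(mu * 1.3, r != 1))
  }, numeric(1)))
  sm <- stochastic_map(tr, traits, mu, 1e5)
  se <- sd(sm$jump_counts) / sqrt(length(sm$jump_counts))
  expect_lt(abs(mean(sm$jump_counts) - expected), 3 * se)
})

test_that("monomorphic tips under a tiny rate yield changeless histories", {
  set.seed(29)
  tr <- simulate_yule_tree(8, 1)
  traits <- setNames(rep(0L, 8), tr$tip.label)
  sm <- stochastic_map(tr, traits, 1e-8, 200, full_history = TRUE)
  expect_true(all(sm$jump_counts == 0))
  expect_true(all(vapply(sm$histories, function(h) h$n_jumps, numeric(1)) == 0))
})

test_that("full histories keep endpoint-consistent change times", {
  set.seed(31)
  tr <- simulate_yule_tree(6, 1)
  traits <- setNames(c(0, 0, 1, 1, 0, 1), tr$tip.label)
  sm <- stochastic_map(tr, traits, 1.2, 50, full_history = TRUE)
  for (h in sm$histories[1:10]) {
    expect_equal(sum(h$edge_jumps), h$n_jumps)
    for (e in seq_along(h$edge_jumps)) {
      expect_length(h$change_times[[e]], h$edge_jumps[e])
      expect_equal(h$edge_jumps[e] %% 2,
                   as.numeric(h$start_states[e] != h$end_states[e]))
      expect_true(all(h$change_times[[e]] <= h$edge_lengths[e]))
    }
  }
})

test_that("stochastic map jump means agree with an independent mapper", {
  set.seed(37)
  tr <- simulate_yule_tree(6, 1)
  traits <- setNames(c(0, 1, 1, 0, 1, 0), tr$tip.label)
  mu <- 0.6
  sm <- stochastic_map(tr, traits, mu, 4000)
  Q <- matrix(c(-mu, mu, mu, -mu), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  x <- setNames(c("a", "b")[traits[tr$tip.label] + 1], tr$tip.label)
  simmap <- suppressMessages(
    phytools::make.simmap(tr, x, Q = Q, pi = setNames(c(0.5, 0.5),
                                                      c("a", "b")),
                          nsim = 4000, message = FALSE)
  )
  ref <- mean(vapply(simmap, function(m) phytools::countSimmap(m)$N,
                     numeric(1)))
  se <- sd(sm$jump_counts) / sqrt(4000)
  expect_lt(abs(mean(sm$jump_counts) - ref), 5 * se + 0.05 * ref)
})

test_that("HPD intervals are the shortest covering window", {
  expect_equal(unclass(hpd(rep(3.5, 10)))[c("lower", "upper")],
               list(lower = 3.5, upper = 3.5))
  h <- hpd(1:100, 0.95)
  expect_equal(h$upper - h$lower, 94)
  expect_equal(h$lower, 1)        # ties break toward the smaller bound
  expect_equal(unclass(hpd(c(9, 2, 5), 1))[c("lower", "upper")],
               list(lower = 2, upper = 9))
  # a concentrated mode wins over a diffuse tail
  x <- c(rep(5, 90), 1:10 * 100)
  h2 <- hpd(x, 0.9)
  expect_equal(c(h2$lower, h2$upper), c(5, 5))
  expect_error(hpd(numeric(0)), "empty")
})

test_that("trait randomization permutes states uniformly", {
  set.seed(41)
  traits <- c(t1 = 0, t2 = 0, t3 = 1, t4 = 1, t5 = 1)
  perms <- replicate(1e4, paste(randomize_traits(traits), collapse = ""))
  counts <- table(perms)
  expect_equal(length(counts), choose(5, 2))   # all arrangements appear
  # chi-square uniformity over the 10 distinguishable assignments
  expect_gt(chisq.test(counts)$p.value, 0.01)
  expect_equal(sum(randomize_traits(traits)), 3)
  expect_equal(names(randomize_traits(traits)), names(traits))
})

test_that("the signal test is invariant under state relabeling", {
  # the model is label-symmetric: likelihoods and rate posteriors are
  # exactly invariant under 0 <-> 1 ...
  set.seed(43)
  for (rep in 1:10) {
    tr <- simulate_yule_tree(10, 1)
    traits <- setNames(rbinom(10, 1, 0.5), tr$tip.label)
    mu <- runif(1, 0.1, 3)
    expect_equal(prune_likelihood(tr, traits, mu),
                 prune_likelihood(tr, 1L - traits, mu), tolerance = 1e-14)
  }
  # ... so both labelings of a strongly structured dataset give the same
  # decision (up to Monte-Carlo realization, negligible at this strength)
  cs <- simulate_clade_structured(32)
  r1 <- signal_test(cs$tree, cs$traits, n_map_samples = 250, seed = 99)
  r2 <- signal_test(cs$tree, 1L - cs$traits, n_map_samples = 250, seed = 99)
  expect_equal(r1$decision, "signal")
  expect_equal(r2$decision, "signal")
})

test_that("seeded signal tests are reproducible and flag degeneracy", {
  set.seed(47)
  tr <- simulate_yule_tree(12, 1)
  traits <- randomize_traits(setNames(rep(0:1, 6), tr$tip.label))
  a <- signal_test(tr, traits, n_map_samples = 150, n_null = 4, seed = 7)
  b <- signal_test(tr, traits, n_map_samples = 150, n_null = 4, seed = 7)
  expect_identical(a$real$jumps, b$real$jumps)
  expect_identical(a$decision, b$decision)
  mono <- signal_test(tr, setNames(rep(1L, 12), tr$tip.label))
  expect_true(mono$degenerate)
  expect_true(is.na(mono$decision))
})

test_that("multiple input trees pool their map samples", {
  set.seed(53)
  trees <- replicate(3, simulate_yule_tree(10, 1), simplify = FALSE)
  traits <- setNames(rep(0:1, 5), trees[[1]]$tip.label)
  r <- signal_test(trees, traits, n_map_samples = 90, n_null = 3, seed = 2)
  expect_length(r$real$jumps, 90)
  expect_length(r$real$mu_hat, 3)
})
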