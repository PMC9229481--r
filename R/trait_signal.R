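#' Transition probabilities of the symmetric two-state trait model
#'
#' Binary trait evolving on a tree under a continuous-time Markov chain
#' with equal forward and backward rate \code{mu} and stationary
#' distribution (1/2, 1/2).  The closed form is
#' P_same(t) = (1 + exp(-2 mu t))/2 and P_diff(t) = (1 - exp(-2 mu t))/2.
#'
#' @param mu positive rate per branch-length unit.
#' @param t branch length, t >= 0.
#' @return 2x2 stochastic matrix with rows/cols named "0", "1".
#' @export
transition_prob <- function(mu, t) {
  if (mu <= 0) stop("mu must be positive")
  if (t < 0) stop("t must be non-negative")
  same <- (1 + exp(-2 * mu * t)) / 2
  diff <- (1 - exp(-2 * mu * t)) / 2
  matrix(c(same, diff, diff, same), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

check_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) {
    stop("missing trait state for tip(s): ", paste(missing, collapse = ", "))
  }
  st <- traits[tree$tip.label]
  if (!all(st %in% c(0, 1))) stop("trait states must be 0 or 1")
  as.integer(st)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths on all edges")
  }
  if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length))) {
    stop("branch lengths must be finite and non-negative")
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(tree)
}

# Felsenstein pruning: per-node conditional likelihoods of the data below
# each node, with underflow rescaling.  Returns list(partials, log_scale,
# postorder edge matrix).  Rows of `partials` are proportional to the true
# conditional likelihoods (per-row scale absorbed into log_scale).
prune_partials <- function(tree, traits, mu) {
  check_tree(tree)
  st <- check_traits(tree, traits)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- matrix(1, nn, 2)
  L[seq_len(ntip), ] <- 0
  L[cbind(seq_len(ntip), st + 1L)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  log_scale <- 0
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    P <- transition_prob(mu, po$edge.length[i])
    L[par, ] <- L[par, ] * as.vector(P %*% L[ch, ])
    m <- max(L[par, ])
    if (m < 1e-150 && m > 0) {
      L[par, ] <- L[par, ] / m
      log_scale <- log_scale + log(m)
    }
  }
  list(partials = L, log_scale = log_scale, postorder = po, ntip = ntip)
}

#' Pruning likelihood of binary tip states
#'
#' Likelihood of the observed tip states under the symmetric two-state
#' model with a stationary (1/2, 1/2) root prior, computed by the pruning
#' algorithm.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param traits named 0/1 vector covering every tip.
#' @param mu positive trait change rate.
#' @param log return the log-likelihood instead.
#' @return numeric likelihood (or log-likelihood).
#' @export
prune_likelihood <- function(tree, traits, mu, log = FALSE) {
  pp <- prune_partials(tree, traits, mu)
  root <- pp$ntip + 1L
  ll <- log(sum(0.5 * pp$partials[root, ])) + pp$log_scale
  if (log) ll else exp(ll)
}

#' Maximum-likelihood trait change rate
#'
#' One-dimensional maximization of \code{\link{prune_likelihood}} over
#' \code{mu} in \code{[1e-6, 100 * n_tips / total tree length]} (log scale,
#' relative tolerance 1e-6).  Because only tip states inform the rate, a
#' monomorphic trait carries no signal: the lower bound is returned with a
#' warning.
#'
#' @inheritParams prune_likelihood
#' @return list with \code{mu_hat}, \code{loglik}, and the search
#'   \code{bounds}.
#' @export
ml_rate <- function(tree, traits) {
  check_tree(tree)
  st <- check_traits(tree, traits)
  lo <- 1e-6
  hi <- 100 * length(tree$tip.label) / sum(tree$edge.length)
  if (length(unique(st)) < 2) {
    warning("monomorphic trait: rate not identifiable, returning lower bound")
    return(list(mu_hat = lo,
                loglik = prune_likelihood(tree, traits, lo, log = TRUE),
                bounds = c(lo, hi)))
  }
  f <- function(lm) prune_likelihood(tree, traits, exp(lm), log = TRUE)
  opt <- stats::optimize(f, c(log(lo), log(hi)), maximum = TRUE, tol = 1e-7)
  list(mu_hat = exp(opt$maximum), loglik = opt$objective, bounds = c(lo, hi))
}

# Parity-constrained Poisson sampler: P(N = n) proportional to lambda^n/n!
# restricted to n odd (odd = TRUE) or even.  This is the jump-count law of
# an endpoint-conditioned symmetric two-state path under uniformization
# with dominating rate mu: the uniformized chain is the deterministic flip,
# so virtual jumps equal real jumps and the endpoint constraint is exactly
# a parity constraint.  Vectorized over lambda/odd.
r_parity_pois <- function(lambda, odd) {
  n <- max(length(lambda), length(odd))
  lambda <- rep_len(lambda, n); odd <- rep_len(as.logical(odd), n)
  out <- integer(n)
  zero <- lambda <= 0
  if (any(zero & odd)) {
    stop("impossible endpoint pair: unequal states with zero branch length")
  }
  big <- !zero & lambda >= 20      # series is slow/overflowy; rejection is ~50%
  for (i in which(big)) {
    repeat {
      k <- stats::rpois(1, lambda[i])
      if ((k %% 2 == 1) == odd[i]) break
    }
    out[i] <- k
  }
  idx <- which(!big & !zero)
  if (length(idx)) {
    lam <- lambda[idx]; od <- odd[idx]
    z <- ifelse(od, sinh(lam), cosh(lam))
    u <- stats::runif(length(idx)) * z
    k <- ifelse(od, 1L, 0L)
    term <- ifelse(od, lam, 1)     # lambda^k / k!
    cum <- term
    res <- rep(NA_integer_, length(idx))
    done <- u <= cum
    res[done] <- k[done]
    it <- 0L
    while (any(!done)) {
      k <- k + 2L
      term <- term * lam * lam / ((k - 1) * k)
      cum <- cum + term
      newly <- !done & u <= cum
      res[newly] <- k[newly]
      done <- done | newly
      it <- it + 1L
      if (it > 500L) {             # exhausted series mass numerically
        res[!done] <- k[!done]
        break
      }
    }
    out[idx] <- res
  }
  out
}

#' Endpoint-conditioned trait path on one branch
#'
#' Samples a complete two-state trajectory on a branch of length \code{t}
#' conditional on its endpoint states, by uniformization with dominating
#' rate \code{mu}: the number of changes is a parity-constrained Poisson
#' (odd if the endpoints differ, even otherwise) and, given the count, the
#' change times are order statistics of uniforms on (0, t).
#'
#' @param state_a,state_b endpoint states (0/1).
#' @param t branch length, t >= 0.
#' @param mu positive rate.
#' @return sorted numeric vector of change times in (0, t); length 0 when
#'   no change occurs.  Unequal endpoints on a zero-length branch are an
#'   error (impossible pair).
#' @export
sample_branch_path <- function(state_a, state_b, t, mu) {
  if (t < 0) stop("t must be non-negative")
  if (mu <= 0) stop("mu must be positive")
  n <- r_parity_pois(mu * t, state_a != state_b)
  sort(stats::runif(n, 0, t))
}

#' Sample internal node states given tip states
#'
#' Backward pruning, forward sampling: conditional likelihoods from
#' \code{\link{prune_likelihood}}'s pruning pass, then the root state is
#' drawn from its exact posterior and each descendant internal state from
#' its conditional given the sampled parent state.  The draws come from
#' the exact joint conditional distribution of internal states given tips.
#'
#' @inheritParams prune_likelihood
#' @param n_samples number of independent joint draws.
#' @return integer matrix (n_nodes x n_samples) of 0/1 states for all
#'   nodes, tips included (tip rows are constant at the observed states);
#'   rows follow ape's node numbering.
#' @export
sample_node_states <- function(tree, traits, mu, n_samples = 1) {
  pp <- prune_partials(tree, traits, mu)
  L <- pp$partials
  ntip <- pp$ntip
  nn <- nrow(L)
  root <- ntip + 1L
  if (sum(L[root, ]) <= 0) stop("tip states have zero likelihood")
  S <- matrix(0L, nn, n_samples)
  st <- check_traits(tree, traits)
  S[seq_len(ntip), ] <- st
  p1 <- (0.5 * L[root, 2]) / sum(0.5 * L[root, ])
  S[root, ] <- as.integer(stats::runif(n_samples) < p1)
  pre <- pp$postorder$edge[rev(seq_len(nrow(pp$postorder$edge))), ,
                           drop = FALSE]
  prelen <- rev(pp$postorder$edge.length)
  for (i in seq_len(nrow(pre))) {
    ch <- pre[i, 2]
    if (ch <= ntip) next
    P <- transition_prob(mu, prelen[i])
    # P(child = 1 | parent = s) proportional to P[s,1] * L[child, 1]
    w1 <- P[, 2] * L[ch, 2]
    w0 <- P[, 1] * L[ch, 1]
    p1c <- w1 / (w0 + w1)                     # indexed by parent state + 1
    ps <- S[pre[i, 1], ]
    S[ch, ] <- as.integer(stats::runif(n_samples) < p1c[ps + 1L])
  }
  S
}

#' Stochastic character mapping
#'
#' Draws complete trait-change histories conditional on the tip states:
#' internal node states via \code{\link{sample_node_states}}, then an
#' endpoint-conditioned path on every branch via
#' \code{\link{sample_branch_path}}.  The per-history total number of
#' changes is the Markov-jump count used by \code{\link{signal_test}}.
#'
#' @inheritParams sample_node_states
#' @param full_history keep per-branch change times (\code{TRUE}) or only
#'   jump counts (\code{FALSE}; considerably faster for large samples).
#' @return object of class \code{character_map}: list with
#'   \code{jump_counts} (integer vector, one per sample),
#'   \code{node_states} (nodes x samples matrix) and, when
#'   \code{full_history}, \code{histories}: per sample a list with
#'   \code{edge} (ape edge matrix), \code{edge_jumps} and
#'   \code{change_times} per edge.
#' @export
stochastic_map <- function(tree, traits, mu, n_samples = 100,
                           full_history = FALSE) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  S <- sample_node_states(tree, traits, mu, n_samples)
  po <- ape::reorder.phylo(check_tree(tree), "postorder")
  ne <- nrow(po$edge)
  # parity per edge x sample, jump counts vectorized across the whole grid
  a <- S[po$edge[, 1], , drop = FALSE]
  b <- S[po$edge[, 2], , drop = FALSE]
  lam <- matrix(mu * po$edge.length, ne, n_samples)
  jumps <- matrix(r_parity_pois(as.vector(lam), as.vector(a != b)),
                  ne, n_samples)
  out <- list(jump_counts = colSums(jumps), node_states = S,
              mu = mu, tree = tree)
  if (full_history) {
    out$histories <- lapply(seq_len(n_samples), function(s) {
      ct <- lapply(seq_len(ne), function(e) {
        sort(stats::runif(jumps[e, s], 0, po$edge.length[e]))
      })
      list(edge = po$edge, edge_lengths = po$edge.length,
           start_states = a[, s], end_states = b[, s],
           edge_jumps = jumps[, s], change_times = ct,
           n_jumps = sum(jumps[, s]))
    })
  }
  class(out) <- "character_map"
  out
}

#' @export
print.character_map <- function(x, ...) {
  cat("Stochastic character maps:", length(x$jump_counts),
      "samples, mu =", signif(x$mu, 4), "\n")
  cat("  jump counts: mean", round(mean(x$jump_counts), 2),
      " range", paste(range(x$jump_counts), collapse = "-"), "\n")
  invisible(x)
}

#' Highest posterior density interval of a sample
#'
#' Shortest contiguous interval of the sorted sample containing
#' \code{ceiling(mass * n)} points; among equally short candidates the one
#' with the smaller lower bound is taken.
#'
#' @param samples numeric vector, length >= 1.
#' @param mass target probability mass (default 0.95).
#' @return list of class \code{hpd} with \code{lower}, \code{upper},
#'   \code{mass}.
#' @export
hpd <- function(samples, mass = 0.95) {
  if (!length(samples)) stop("empty sample")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  i <- seq_len(n - k + 1L)
  w <- x[i + k - 1L] - x[i]
  best <- which.min(w)             # first minimum = smallest lower bound
  structure(list(lower = x[best], upper = x[best + k - 1L], mass = mass),
            class = "hpd")
}

#' @export
print.hpd <- function(x, ...) {
  cat(sprintf("%.0f%% HPD [%g, %g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

hpd_overlap <- function(a, b) a$lower <= b$upper && b$lower <= a$upper

#' Randomize tip states
#'
#' Uniform random permutation of the observed states across tips; the
#' state counts are preserved, which makes this the exchangeability null
#' for the phylogenetic-signal test.
#'
#' @param traits named 0/1 vector.
#' @return named vector with the same names and permuted states.
#' @export
randomize_traits <- function(traits) {
  setNames(sample(unname(traits)), names(traits))
}

#' Posterior distribution of the trait change rate on a log grid
#'
#' Discretized posterior of \code{mu} under a uniform-in-log-rate prior on
#' \code{[1e-6, 100 * n_tips / total tree length]}: weights proportional
#' to the pruning likelihood at each grid point.  Marginalizing stochastic
#' maps over this distribution propagates rate uncertainty into the
#' Markov-jump counts, which is what keeps the jump HPDs honestly wide
#' when the tip states carry little rate information (a point rate
#' estimate is unstable for scattered traits and produces spuriously
#' narrow jump distributions).
#'
#' @inheritParams prune_likelihood
#' @param grid_n number of log-spaced grid points (default 61).
#' @return list with \code{mu} (grid values), \code{weights} (posterior
#'   probabilities summing to 1) and \code{mu_mean} (posterior mean).
#' @export
rate_posterior <- function(tree, traits, grid_n = 61) {
  check_tree(tree)
  lo <- 1e-6
  hi <- 100 * length(tree$tip.label) / sum(tree$edge.length)
  lmu <- seq(log(lo), log(hi), length.out = grid_n)
  ll <- vapply(lmu, function(m) prune_likelihood(tree, traits, exp(m),
                                                 log = TRUE), numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  list(mu = exp(lmu), weights = w, mu_mean = sum(exp(lmu) * w))
}

#' Phylogenetic-signal test for a binary trait by Markov-jump comparison
#'
#' Samples stochastic character maps to obtain the posterior distribution
#' of Markov-jump counts - by default marginalizing over the trait-rate
#' posterior (\code{\link{rate_posterior}}), so rate uncertainty widens
#' the jump distribution just as it does in a fully Bayesian analysis -
#' and compares its HPD interval against \code{n_null} independent runs
#' in which the tip states are randomly permuted (each null run
#' re-estimates the rate on the permuted data).  Overlap between the real
#' HPD and at least one null HPD indicates the absence of phylogenetic
#' signal in the trait; disjointness from every null run indicates signal
#' (the trait clusters on the tree more than random tip assignment would
#' produce).
#'
#' @param trees a rooted \code{phylo}, a \code{multiPhylo}, or a list of
#'   trees (e.g. a posterior tree sample); map samples are split equally
#'   across trees and pooled, with the rate re-estimated per tree.
#' @param traits named 0/1 vector covering every tip (1 = infects the
#'   focal host).
#' @param n_map_samples total stochastic maps per run (default 1000).
#' @param n_null number of randomized-tip null runs (default 10).
#' @param mass HPD mass (default 0.95).
#' @param rate \code{"marginal"} (default) marginalizes each run's maps
#'   over \code{\link{rate_posterior}}; \code{"ml"} conditions every map
#'   on the \code{\link{ml_rate}} point estimate (narrower HPDs, unstable
#'   for weakly informative traits).
#' @param grid_n rate-posterior grid size (marginal mode).
#' @param seed optional integer; when given, the real run uses
#'   \code{seed} and null run i uses \code{seed + i}, so individual runs
#'   are reproducible in isolation.
#' @return object of class \code{signal_test_result}: list with
#'   \code{real} (jump sample, \code{hpd}, \code{mu_hat} per tree),
#'   \code{null_runs} (same per null run), \code{overlap} (logical per
#'   null run), \code{decision} (\code{"signal"} / \code{"no_signal"}),
#'   and \code{degenerate} (TRUE with no decision when the trait is
#'   monomorphic).
#' @export
signal_test <- function(trees, traits, n_map_samples = 1000, n_null = 10,
                        mass = 0.95, rate = c("marginal", "ml"),
                        grid_n = 61, seed = NULL) {
  rate <- match.arg(rate)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  lapply(trees, check_tree)
  st <- check_traits(trees[[1]], traits)
  if (length(unique(st)) < 2) {
    return(structure(list(degenerate = TRUE, decision = NA_character_,
                          reason = "monomorphic trait"),
                     class = "signal_test_result"))
  }
  per_tree <- max(1L, round(n_map_samples / length(trees)))
  run_once <- function(trts) {
    jumps <- integer(0)
    mus <- numeric(length(trees))
    for (ti in seq_along(trees)) {
      if (rate == "marginal") {
        rp <- rate_posterior(trees[[ti]], trts, grid_n)
        mus[ti] <- rp$mu_mean
        cnt <- as.vector(stats::rmultinom(1, per_tree, rp$weights))
        for (g in which(cnt > 0)) {
          sm <- stochastic_map(trees[[ti]], trts, rp$mu[g], cnt[g],
                               full_history = FALSE)
          jumps <- c(jumps, sm$jump_counts)
        }
      } else {
        mus[ti] <- ml_rate(trees[[ti]], trts)$mu_hat
        sm <- stochastic_map(trees[[ti]], trts, mus[ti], per_tree,
                             full_history = FALSE)
        jumps <- c(jumps, sm$jump_counts)
      }
    }
    list(jumps = jumps, hpd = hpd(jumps, mass), mu_hat = mus)
  }
  if (!is.null(seed)) set.seed(seed)
  real <- run_once(traits)
  null_runs <- vector("list", n_null)
  for (i in seq_len(n_null)) {
    if (!is.null(seed)) set.seed(seed + i)
    null_runs[[i]] <- run_once(randomize_traits(traits))
  }
  overlap <- vapply(null_runs, function(r) hpd_overlap(real$hpd, r$hpd),
                    logical(1))
  structure(list(degenerate = FALSE, real = real, null_runs = null_runs,
                 overlap = overlap,
                 decision = if (any(overlap)) "no_signal" else "signal",
                 mass = mass, n_map_samples = n_map_samples,
                 n_null = n_null, rate = rate, seed = seed),
            class = "signal_test_result")
}

#' @export
print.signal_test_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Signal test: degenerate (", x$reason, "), no decision\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Markov-jump signal test (%d maps, %d null runs)\n",
              x$n_map_samples, x$n_null))
  cat(sprintf("  real jumps: mean %.2f, %.0f%% HPD [%g, %g]\n",
              mean(x$real$jumps), 100 * x$mass,
              x$real$hpd$lower, x$real$hpd$upper))
  nl <- vapply(x$null_runs, function(r) r$hpd$lower, numeric(1))
  nu <- vapply(x$null_runs, function(r) r$hpd$upper, numeric(1))
  cat(sprintf("  null HPDs: lower %g-%g, upper %g-%g; overlap in %d/%d runs\n",
              min(nl), max(nl), min(nu), max(nu),
              sum(x$overlap), length(x$overlap)))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}
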