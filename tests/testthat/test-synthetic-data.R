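test_that("Yule trees have the right shape and are seed-reproducible", {
  set.seed(1)
  cherry <- simulate_yule_tree(2, 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_equal(cherry$edge.length[1], cherry$edge.length[2])
  set.seed(5)
  a <- ape::write.tree(simulate_yule_tree(20, 1))
  set.seed(5)
  b <- ape::write.tree(simulate_yule_tree(20, 1))
  expect_identical(a, b)
  tr <- simulate_yule_tree(25, 2)
  expect_equal(length(tr$tip.label), 25)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_error(simulate_yule_tree(1), "n_tips")
})

test_that("fixed-time Yule growth matches the exponential expectation", {
  set.seed(2)
  b <- 1; t_max <- 1.5
  tips <- replicate(400, length(simulate_yule_tree(birth_rate = b,
                                                   t_max = t_max)$tip.label))
  # starting from 2 lineages: E[N(t)] = 2 * exp(b t)
  expected <- 2 * exp(b * t_max)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 4 * se)
})

test_that("trait histories respect parity and the Poisson jump budget", {
  set.seed(3)
  tr <- simulate_yule_tree(20, 1)
  mu <- 0.7
  hs <- replicate(300, simulate_trait_history(tr, mu), simplify = FALSE)
  for (h in hs[1:20]) {
    # per-branch parity: endpoint equality determines evenness
    for (e in seq_len(nrow(tr$edge))) {
      same <- h$node_states[tr$edge[e, 1]] == h$node_states[tr$edge[e, 2]]
      expect_equal(h$edge_jumps[e] %% 2 == 0, same)
    }
    expect_equal(sum(h$edge_jumps), h$n_jumps)
  }
  jumps <- vapply(hs, function(h) h$n_jumps, numeric(1))
  expected <- mu * sum(tr$edge.length)
  se <- sd(jumps) / sqrt(length(jumps))
  expect_lt(abs(mean(jumps) - expected), 4 * se)
  # vanishing rate: monomorphic tips, no jumps
  h0 <- simulate_trait_history(tr, 1e-9)
  expect_equal(h0$n_jumps, 0)
  expect_equal(length(unique(h0$traits)), 1)
})

test_that("avoided-motif genomes are clean on both strands", {
  set.seed(4)
  g <- simulate_avoided_genome(20000, avoided_motifs = c("CTAG", "GATC"))
  expect_equal(count_motif(g, "CTAG", both_strands = TRUE)$count, 0)
  expect_equal(count_motif(g, "GATC", both_strands = TRUE)$count, 0)
  tt <- tetramer_tau(g, "CTAG")
  expect_equal(tt$tau, 0)
  expect_true(tt$underrepresented)
  expect_equal(nchar(unname(g)), 20000)
  set.seed(9)
  g1 <- simulate_avoided_genome(5000, avoided_motifs = "CTAG")
  set.seed(9)
  g2 <- simulate_avoided_genome(5000, avoided_motifs = "CTAG")
  expect_identical(g1, g2)
})

test_that("non-avoided motif densities track the model expectation", {
  set.seed(6)
  g <- simulate_avoided_genome(50000, avoided_motifs = "CTAG")
  # TTTT is untouched by CTAG avoidance; expectation (L-3)/4^4 occurrences
  cnt <- count_motif(g, "TTTT")$count
  expected <- (50000 - 3) / 256
  # overlapping counts are overdispersed; allow a generous Poisson-scale band
  expect_lt(abs(cnt - expected), 6 * sqrt(expected))
})

test_that("first-order genomes follow the dinucleotide transition bias", {
  set.seed(7)
  dinuc <- matrix(1, 4, 4)
  dinuc[1, 1] <- 20  # strong AA enrichment
  g <- simulate_avoided_genome(20000, order = 1, dinuc_freqs = dinuc / sum(dinuc))
  f_aa <- count_motif(g, "AA")$count / (20000 - 1)
  expect_gt(f_aa, 0.15)   # i.i.d. uniform would give 1/16
})

test_that("infeasible avoidance fails loudly", {
  set.seed(8)
  expect_error(
    simulate_avoided_genome(1000, avoided_motifs = c("AA", "AC", "AG", "AT",
                                                     "CA", "CC", "CG", "CT",
                                                     "GA", "GC", "GG", "GT",
                                                     "TA", "TC", "TG", "TT"),
                            max_passes = 3),
    "retry budget")
})

test_that("screen simulation separates halocin hits from true positives", {
  set.seed(10)
  sim <- simulate_infection_tables(n_viruses = 40, n_hosts = 6,
                                   p_susceptible = 0.15, halocin_rate = 0.3)
  m <- build_host_range_matrix(sim$titers)
  for (h in colnames(sim$truth)) {
    expect_equal(count_positive(m, h), sum(sim$truth[, h]))
  }
  # every spot-only inhibition is a halocin suspect, never a positive
  suspects <- m$cells[m$cells$call == "halocin_suspect", ]
  expect_true(all(!sim$truth[cbind(suspects$virus_id, suspects$host_id)]))
  # plaque-confirmed calls recover the truth matrix exactly
  pos <- m$cells[m$cells$call == "positive", ]
  expect_true(all(sim$truth[cbind(pos$virus_id, pos$host_id)]))
  expect_equal(nrow(pos), sum(sim$truth))
})

test_that("a halocin-free screen reproduces the truth matrix exactly", {
  set.seed(11)
  sim <- simulate_infection_tables(n_viruses = 30, n_hosts = 5,
                                   p_susceptible = 0.2, halocin_rate = 0)
  m <- build_host_range_matrix(sim$titers)
  expect_false(any(m$cells$call == "halocin_suspect"))
  pos <- m$cells[m$cells$call == "positive", ]
  expect_equal(sort(paste(pos$virus_id, pos$host_id)),
               sort(paste(rownames(sim$truth)[row(sim$truth)[sim$truth]],
                          colnames(sim$truth)[col(sim$truth)[sim$truth]])))
})

test_that("screen tables round-trip through the CSV layer", {
  set.seed(12)
  sim <- simulate_infection_tables(n_viruses = 10, n_hosts = 3,
                                   p_susceptible = 0.3, halocin_rate = 0.2)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(sim$titers, f, row.names = FALSE)
  back <- read_titer_csv(f)
  m1 <- build_host_range_matrix(sim$titers)
  m2 <- build_host_range_matrix(back)
  expect_equal(m1$cells, m2$cells)
})

test_that("clade-structured datasets split the tree at the root", {
  set.seed(13)
  cs <- simulate_clade_structured(24, min_clade = 8, stretch = 6)
  expect_equal(sort(unique(unname(cs$traits))), c(0L, 1L))
  k <- sum(cs$traits)
  expect_gte(min(k, 24 - k), 8)
  # the derived state is exactly one root clade
  root <- 25L
  re <- which(cs$tree$edge[, 1] == root)
  ch <- cs$tree$edge[re[1], 2]
  clade <- if (ch <= 24) cs$tree$tip.label[ch] else
    ape::extract.clade(cs$tree, ch)$tip.label
  expect_true(all(cs$traits[clade] == cs$traits[clade][1]))
  expect_true(all(cs$traits[setdiff(cs$tree$tip.label, clade)] !=
                    cs$traits[clade][1]))
})
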