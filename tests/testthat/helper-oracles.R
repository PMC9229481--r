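# Independent oracles and shared fixtures for the suite.  Everything here
# is deliberately brute-force and must stay independent of the package's
# own code paths.

extdata <- function(f) system.file("extdata", f, package = "halorange")

screen_matrix <- function() {
  build_host_range_matrix(
    read_titer_csv(extdata("screen_titers.csv")),
    utils::read.csv(extdata("screen_viruses.csv"), stringsAsFactors = FALSE),
    read_identity_csv(extdata("screen_identity.csv"))
  )
}

# likelihood by exhaustive enumeration of internal-node states
brute_likelihood <- function(tree, traits, mu) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  st <- traits[tree$tip.label]
  internal <- (ntip + 1):nn
  total <- 0
  for (code in 0:(2^length(internal) - 1)) {
    s <- integer(nn)
    s[seq_len(ntip)] <- st
    s[internal] <- as.integer(intToBits(code))[seq_along(internal)]
    p <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      P <- transition_prob(mu, tree$edge.length[e])
      p <- p * P[s[tree$edge[e, 1]] + 1, s[tree$edge[e, 2]] + 1]
    }
    total <- total + p
  }
  total
}

# overlapping occurrences by explicit sliding window
brute_count <- function(s, motif) {
  k <- nchar(motif)
  n <- nchar(s)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1) == motif,
             logical(1)))
}

# strand-symmetrized word frequency by brute force (sequence + its
# reverse complement, valid ACGT-only windows as denominator)
brute_sym_freq <- function(s, w) {
  rc_base <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(rc_base[strsplit(x, "")[[1]]]), collapse = "")
  cnt <- brute_count(s, w) + brute_count(rc(s), w)
  nw <- function(x, k) {
    ok <- strsplit(x, "")[[1]] %in% names(rc_base)
    r <- rle(ok)
    sum(pmax(0L, r$lengths[r$values] - k + 1L))
  }
  cnt / (nw(s, nchar(w)) + nw(rc(s), nchar(w)))
}

brute_tau <- function(s, motif) {
  f4 <- brute_sym_freq(s, motif)
  f2 <- brute_sym_freq(s, substr(motif, 2, 3))
  f3a <- brute_sym_freq(s, substr(motif, 1, 3))
  f3b <- brute_sym_freq(s, substr(motif, 2, 4))
  (f4 * f2) / (f3a * f3b)
}

random_iid_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# conditional mean jump count on one branch (parity-restricted Poisson)
cond_mean_jumps <- function(lambda, unequal) {
  if (unequal) lambda / tanh(lambda) else lambda * tanh(lambda)
}
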