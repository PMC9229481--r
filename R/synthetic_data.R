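#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: starting from two lineages at the root, each of the
#' k extant lineages splits independently at rate \code{birth_rate}, so
#' waiting times between splits are Exponential(k * birth_rate).  With
#' \code{n_tips} the process stops when that many lineages exist and all
#' pendant branches are extended by the waiting time to the next (unused)
#' split, giving an ultrametric tree.  With \code{t_max} the process runs
#' for a fixed time and the tip count is random (mean grows as
#' exp(birth_rate * t)).
#'
#' @param n_tips number of tips (>= 2); ignored when \code{t_max} given.
#' @param birth_rate per-lineage split rate.
#' @param t_max optional fixed simulation time.
#' @return rooted ultrametric \code{phylo} with tips "t1", "t2", ...
#' @export
simulate_yule_tree <- function(n_tips = NULL, birth_rate = 1, t_max = NULL) {
  if (is.null(t_max) && (is.null(n_tips) || n_tips < 2)) {
    stop("n_tips must be >= 2 (or supply t_max)")
  }
  if (birth_rate <= 0) stop("birth_rate must be positive")
  # lineage records: parent lineage, birth time, end time (split or present)
  parent <- c(0L, 0L)
  start <- c(0, 0)
  end <- c(NA_real_, NA_real_)
  alive <- c(1L, 2L)
  now <- 0
  repeat {
    k <- length(alive)
    wait <- stats::rexp(1, birth_rate * k)
    if (!is.null(t_max) && now + wait > t_max) { now <- t_max; break }
    now <- now + wait
    if (is.null(t_max) && k == n_tips) break   # stop at the unused split
    who <- alive[sample.int(k, 1)]
    end[who] <- now
    id1 <- length(parent) + 1L; id2 <- id1 + 1L
    parent <- c(parent, who, who)
    start <- c(start, now, now)
    end <- c(end, NA_real_, NA_real_)
    alive <- c(setdiff(alive, who), id1, id2)
  }
  end[alive] <- now
  tips <- sort(alive)
  tip_label <- setNames(paste0("t", seq_along(tips)), tips)
  build <- function(id) {
    len <- end[id] - start[id]
    ch <- which(parent == id)
    if (!length(ch)) {
      paste0(tip_label[[as.character(id)]], ":", format(len, digits = 17))
    } else {
      paste0("(", build(ch[1]), ",", build(ch[2]), "):",
             format(len, digits = 17))
    }
  }
  nwk <- paste0("(", build(1L), ",", build(2L), "):0;")
  ape::read.tree(text = nwk)
}

#' Simulate a binary trait history on a tree
#'
#' Forward simulation of the symmetric two-state process: root state drawn
#' from the stationary (1/2, 1/2) prior, then along each branch the number
#' of state flips is Poisson(mu_true * branch length) and each flip
#' inverts the state.  Returns both the tip states and the complete true
#' history with its jump count, which is the ground truth that
#' \code{\link{stochastic_map}} and \code{\link{signal_test}} are tested
#' against.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param mu_true positive trait change rate.
#' @return list with \code{traits} (named 0/1 tip vector),
#'   \code{node_states} (0/1 per ape node number), \code{edge_jumps}
#'   (per edge of \code{tree$edge}), \code{change_times} (list per edge)
#'   and \code{n_jumps} (total).
#' @export
simulate_trait_history <- function(tree, mu_true) {
  check_tree(tree)
  if (mu_true <= 0) stop("mu_true must be positive")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- integer(nn)
  root <- ntip + 1L
  states[root] <- stats::rbinom(1, 1, 0.5)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  edge_jumps <- integer(nrow(po$edge))
  change_times <- vector("list", nrow(po$edge))
  for (i in pre) {
    t <- po$edge.length[i]
    nflip <- stats::rpois(1, mu_true * t)
    edge_jumps[i] <- nflip
    change_times[[i]] <- sort(stats::runif(nflip, 0, t))
    states[po$edge[i, 2]] <- (states[po$edge[i, 1]] + nflip) %% 2L
  }
  # map per-postorder-edge results back to tree$edge order
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  ej <- integer(nrow(tree$edge)); ej[ord] <- edge_jumps
  ct <- vector("list", nrow(tree$edge)); ct[ord] <- change_times
  list(
    traits = setNames(states[seq_len(ntip)], tree$tip.label),
    node_states = states, edge_jumps = ej, change_times = ct,
    n_jumps = sum(ej)
  )
}

#' Simulate a strongly clade-structured trait dataset
#'
#' Positive control for \code{\link{signal_test}}: a Yule tree whose root
#' bipartition is reasonably balanced (each side holds at least
#' \code{min_clade} tips; trees are redrawn until this holds), with both
#' root-adjacent branches lengthened by \code{stretch} and the trait
#' assigned by the root bipartition.  The single state change then
#' concentrates on the long root branches, the real Markov-jump
#' distribution sits near 1, and any tip permutation scatters the states
#' across the tree - the textbook picture of strong phylogenetic signal.
#' An unbalanced split (one or two tips against the rest) is deliberately
#' excluded: a lone derived tip is matched by random permutations and
#' carries almost no signal.
#'
#' @param n_tips number of tips (>= 4).
#' @param birth_rate Yule split rate.
#' @param stretch length added to each root-adjacent branch (same units
#'   as branch lengths; default 10, several times the height of a
#'   \code{birth_rate = 1} Yule tree).
#' @param min_clade minimum tips on each side of the root split
#'   (default one third of the tips).
#' @return list with \code{tree} (\code{phylo}) and \code{traits}
#'   (named 0/1 vector; 1 marks one root clade).
#' @export
simulate_clade_structured <- function(n_tips = 32, birth_rate = 1,
                                      stretch = 10,
                                      min_clade = max(2L, n_tips %/% 3L)) {
  if (n_tips < 4) stop("n_tips must be >= 4")
  if (2 * min_clade > n_tips) stop("min_clade too large for n_tips")
  repeat {
    tree <- simulate_yule_tree(n_tips, birth_rate)
    root <- n_tips + 1L
    re <- which(tree$edge[, 1] == root)
    ch <- tree$edge[re[1], 2]
    clade <- if (ch <= n_tips) tree$tip.label[ch] else
      ape::extract.clade(tree, ch)$tip.label
    if (length(clade) >= min_clade && length(clade) <= n_tips - min_clade) {
      break
    }
  }
  tree$edge.length[re] <- tree$edge.length[re] + stretch
  list(tree = tree,
       traits = setNames(as.integer(tree$tip.label %in% clade),
                         tree$tip.label))
}

base_alphabet <- c("A", "C", "G", "T")

# draw n bases; order 0 uses base_freqs, order 1 uses the conditional
# P(next | prev) implied by dinucleotide frequencies
draw_bases <- function(n, order, base_freqs, trans, prev = NULL) {
  if (order == 0 || is.null(prev)) {
    first <- sample(base_alphabet, 1, prob = base_freqs)
  } else {
    first <- sample(base_alphabet, 1, prob = trans[prev, ])
  }
  if (n == 1) return(first)
  out <- character(n)
  out[1] <- first
  if (order == 0) {
    out[2:n] <- sample(base_alphabet, n - 1, replace = TRUE,
                       prob = base_freqs)
  } else {
    for (i in 2:n) out[i] <- sample(base_alphabet, 1, prob = trans[out[i - 1], ])
  }
  out
}

#' Simulate a genome with specified avoided motifs
#'
#' Draws a sequence from an i.i.d. (order 0) or first-order Markov model
#' and then removes every occurrence of the avoided motifs on both strands
#' by locally resampling the offending windows from the same model, which
#' emulates the restriction-site avoidance seen in viral genomes.  Local
#' resampling (rather than whole-sequence rejection) keeps long genomes
#' feasible; avoidance is verified post hoc with \code{\link{count_motif}}.
#'
#' @param length genome length (>= 1000).
#' @param order Markov order: 0 (i.i.d. base frequencies) or 1
#'   (first-order chain derived from dinucleotide frequencies).
#' @param base_freqs length-4 probability vector over A/C/G/T (order 0).
#' @param dinuc_freqs optional 4x4 matrix of dinucleotide frequencies
#'   (rows = first base); row-normalized into the transition matrix for
#'   order 1.  Defaults to independence under \code{base_freqs}.
#' @param avoided_motifs character vector of motifs over A/C/G/T whose
#'   occurrences (and reverse complements) are removed.
#' @param max_passes resampling passes before regenerating from scratch;
#'   a handful of full regenerations are attempted before erroring
#'   (infeasible avoidance).
#' @param genome_id id for the returned record.
#' @return named character vector of length 1 (the sequence, named by
#'   \code{genome_id}).
#' @export
simulate_avoided_genome <- function(length, order = 0,
                                    base_freqs = rep(0.25, 4),
                                    dinuc_freqs = NULL,
                                    avoided_motifs = character(),
                                    max_passes = 50,
                                    genome_id = "sim_genome") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (!order %in% c(0, 1)) stop("order must be 0 or 1")
  if (abs(sum(base_freqs) - 1) > 1e-8 || any(base_freqs < 0)) {
    stop("base_freqs must be a probability vector")
  }
  for (m in avoided_motifs) check_motif(m)
  trans <- NULL
  if (order == 1) {
    if (is.null(dinuc_freqs)) dinuc_freqs <- outer(base_freqs, base_freqs)
    dimnames(dinuc_freqs) <- list(base_alphabet, base_alphabet)
    trans <- dinuc_freqs / rowSums(dinuc_freqs)
  }
  targets <- unique(c(avoided_motifs,
                      vapply(avoided_motifs, reverse_complement, "")))
  for (attempt in 1:5) {
    seqv <- draw_bases(length, order, base_freqs, trans)
    pass <- 0L
    repeat {
      s <- paste(seqv, collapse = "")
      hits <- list()
      for (m in targets) {
        st <- gregexpr(m, s, fixed = TRUE)[[1]]
        if (st[1] != -1L) {
          hits[[m]] <- cbind(st, st + nchar(m) - 1L)
        }
      }
      if (!base::length(hits)) {
        return(setNames(s, genome_id))
      }
      pass <- pass + 1L
      if (pass > max_passes) break
      for (h in hits) {
        for (r in seq_len(nrow(h))) {
          i0 <- h[r, 1]; i1 <- h[r, 2]
          prev <- if (order == 1 && i0 > 1) seqv[i0 - 1] else NULL
          seqv[i0:i1] <- draw_bases(i1 - i0 + 1, order, base_freqs, trans,
                                    prev = prev)
        }
      }
    }
  }
  stop("could not generate a genome avoiding the requested motifs ",
       "(retry budget exhausted)")
}

#' Simulate a two-stage infection screen
#'
#' Emulates the spot-on-lawn + plaque-assay pipeline with a known truth
#' matrix.  Every virus-host pair is spot-tested: true positives always
#' inhibit the lawn and go on to yield a plaque titer (log10-normal); true
#' negatives inhibit with probability \code{halocin_rate} (halocin-style
#' false positives) and never yield plaques.  Pairs with spot inhibition
#' are plaque-tested; plaque-negative inhibitions appear as "-" cells.
#' The output table round-trips through
#' \code{\link{build_host_range_matrix}}, whose plaque-confirmation rule
#' recovers the truth matrix exactly for any \code{halocin_rate}.
#'
#' @param n_viruses,n_hosts screen dimensions (defaults: the 95 x 14
#'   design of a large haloarchaeal screen).
#' @param p_susceptible probability a pair is a true virus-host pair.
#' @param halocin_rate probability a true-negative lysate inhibits the
#'   lawn without plaques.
#' @param titer_log10_mean,titer_log10_sd log10 pfu/mL distribution of
#'   positive-pair titers (defaults 9 and 1, spanning the 1e3-1e12 range
#'   seen in real screens).
#' @return list with \code{titers} (long assay table with spot and plaque
#'   rows, ready for \code{\link{build_host_range_matrix}}) and
#'   \code{truth} (logical n_viruses x n_hosts matrix).
#' @export
simulate_infection_tables <- function(n_viruses = 95, n_hosts = 14,
                                      p_susceptible = 0.0075,
                                      halocin_rate = 0.05,
                                      titer_log10_mean = 9,
                                      titer_log10_sd = 1) {
  stopifnot(n_viruses >= 1, n_hosts >= 1,
            p_susceptible >= 0, p_susceptible <= 1,
            halocin_rate >= 0, halocin_rate <= 1)
  vid <- sprintf("V%03d", seq_len(n_viruses))
  hid <- sprintf("H%02d", seq_len(n_hosts))
  truth <- matrix(stats::runif(n_viruses * n_hosts) < p_susceptible,
                  n_viruses, n_hosts, dimnames = list(vid, hid))
  rows <- vector("list", n_viruses * n_hosts * 2)
  k <- 0L
  for (i in seq_len(n_viruses)) {
    for (j in seq_len(n_hosts)) {
      pos <- truth[i, j]
      spot <- pos || stats::runif(1) < halocin_rate
      k <- k + 1L
      rows[[k]] <- data.frame(virus_id = vid[i], host_id = hid[j],
                              assay = "spot",
                              titer = if (spot) "+" else "-",
                              stringsAsFactors = FALSE)
      if (spot) {
        k <- k + 1L
        titer <- if (pos) {
          sprintf("%.3g", 10^stats::rnorm(1, titer_log10_mean, titer_log10_sd))
        } else "-"
        rows[[k]] <- data.frame(virus_id = vid[i], host_id = hid[j],
                                assay = "plaque", titer = titer,
                                stringsAsFactors = FALSE)
      }
    }
  }
  list(titers = rbind_rows(rows[seq_len(k)]), truth = truth)
}
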