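#' Read genome sequences from FASTA
#'
#' Ids are taken from the header up to the first whitespace; sequences are
#' uppercase-normalized.  Duplicate ids and empty files are errors.
#'
#' @param path FASTA file.
#' @return \code{DNAStringSet}.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate FASTA id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Read an aligned protein FASTA
#'
#' As \code{\link{read_genome_fasta}} but for amino-acid alignments; all
#' sequences must have the same aligned length (gap character "-").
#'
#' @param path aligned FASTA file.
#' @return \code{AAStringSet} of equal-width sequences.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate FASTA id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(w), collapse = ", "))
  }
  Biostrings::AAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA
#' @param x named character vector or \code{XStringSet}.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read rooted trees from a newick file
#'
#' One tree per line.  Every edge must carry a branch length (a missing
#' root edge length defaults to 0); unrooted trees and duplicate tip
#' labels are rejected.
#'
#' @param path newick file (one or more trees).
#' @return list of rooted \code{phylo} objects.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees in file: ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  lapply(trees, function(tr) {
    if (!ape::is.rooted(tr)) {
      stop("tree is unrooted; root it (e.g. with an outgroup) before use")
    }
    if (is.null(tr$edge.length)) {
      stop("tree has no branch lengths; lengths are required on all edges")
    }
    if (anyNA(tr$edge.length)) {
      stop("tree has edges without branch lengths")
    }
    if (!is.null(tr$root.edge) && is.na(tr$root.edge)) tr$root.edge <- 0
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicate tip label(s): ",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                 collapse = ", "))
    }
    check_tree(tr)
  })
}

#' Write trees to a newick file, one per line
#' @param trees a \code{phylo} or list of them.
#' @param path output file.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
  invisible(path)
}

#' Read a binary tip-trait table
#'
#' CSV with columns \code{tip_id} and \code{state} (0/1).
#'
#' @param path CSV file.
#' @return named integer vector of 0/1 states.
#' @export
read_trait_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tip_id", "state") %in% names(d))) {
    stop("trait CSV must have columns tip_id, state")
  }
  if (anyDuplicated(d$tip_id)) {
    stop("duplicate tip id(s) in trait table: ",
         paste(unique(d$tip_id[duplicated(d$tip_id)]), collapse = ", "))
  }
  if (!all(d$state %in% c(0, 1))) stop("states must be 0 or 1")
  setNames(as.integer(d$state), d$tip_id)
}

#' Write a binary tip-trait table
#' @param traits named 0/1 vector.
#' @param path output CSV.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(
    data.frame(tip_id = names(traits), state = unname(traits)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a titer/assay table
#'
#' CSV with columns \code{virus_id}, \code{host_id}, \code{assay},
#' \code{titer}; see \code{\link{build_host_range_matrix}} for the cell
#' grammar.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_titer_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  req <- c("virus_id", "host_id", "assay", "titer")
  if (!all(req %in% names(d))) {
    stop("titer CSV must have columns ", paste(req, collapse = ", "))
  }
  d
}

#' Read genome-identity groups
#'
#' CSV with columns \code{group_id}, \code{virus_id}; each group collects
#' isolates whose genome sequences were reported identical.
#'
#' @param path CSV file.
#' @return named list of character vectors (one per group).
#' @export
read_identity_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group_id", "virus_id") %in% names(d))) {
    stop("identity CSV must have columns group_id, virus_id")
  }
  groups <- split(as.character(d$virus_id), d$group_id)
  check_identity_groups(groups)
  groups
}

#' Export a host-range matrix report
#'
#' Writes the per-cell report (call, titer, EOP against each virus's own
#' host when metadata permits) as CSV and, optionally, a JSON report that
#' embeds the run configuration.
#'
#' @param matrix a \code{host_range_matrix}.
#' @param csv_path output CSV path.
#' @param json_path optional JSON report path.
#' @param test_host host used for the EOP columns (default none).
#' @param seed optional seed to record in the JSON report.
#' @return the cell report data.frame, invisibly.
#' @export
write_host_range_report <- function(matrix, csv_path, json_path = NULL,
                                    test_host = NULL, seed = NULL) {
  cells <- matrix$cells
  if (!is.null(test_host) && !is.null(matrix$viruses$own_host)) {
    eop <- eop_table(matrix, test_host)
    cells <- merge(cells,
                   eop[, c("virus_id", "eop_raw", "eop_rounded", "eop_label")],
                   by = "virus_id", all.x = TRUE, sort = FALSE)
    cells$eop_raw[cells$host_id != test_host] <- NA
    cells$eop_rounded[cells$host_id != test_host] <- NA
    cells$eop_label[cells$host_id != test_host] <- NA
  }
  utils::write.csv(cells, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    write_json_report(
      list(cells = cells,
           identity_groups = matrix$identity_groups,
           hosts = matrix$hosts),
      json_path, seed = seed
    )
  }
  invisible(cells)
}

#' Write a JSON run report
#'
#' Standard report envelope used by the analysis drivers: the payload plus
#' package version, seed and any configuration, so every result file
#' records how it was produced.
#'
#' @param payload named list of results.
#' @param path output JSON path.
#' @param seed optional RNG seed used for the run.
#' @param config optional named list of run parameters.
#' @export
write_json_report <- function(payload, path, seed = NULL, config = list()) {
  report <- list(
    package = "halorange",
    version = as.character(utils::packageVersion("halorange")),
    seed = seed,
    config = config,
    results = payload
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a signal-test result as a JSON report
#'
#' @param result a \code{signal_test_result}.
#' @param path output JSON path.
#' @param seed optional seed to record.
#' @export
write_signal_report <- function(result, path, seed = NULL) {
  if (isTRUE(result$degenerate)) {
    payload <- list(degenerate = TRUE, reason = result$reason)
  } else {
    payload <- list(
      degenerate = FALSE,
      decision = result$decision,
      real = list(
        mean_jumps = mean(result$real$jumps),
        hpd = c(result$real$hpd$lower, result$real$hpd$upper),
        mu_hat = result$real$mu_hat
      ),
      null_runs = lapply(result$null_runs, function(r) {
        list(mean_jumps = mean(r$jumps),
             hpd = c(r$hpd$lower, r$hpd$upper),
             mu_hat = r$mu_hat)
      }),
      overlap = result$overlap,
      hpd_mass = result$mass,
      n_map_samples = result$n_map_samples,
      n_null = result$n_null
    )
  }
  write_json_report(payload, path, seed = seed)
}
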