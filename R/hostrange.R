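#' Parse plaque-titer cells
#'
#' Titer tables transcribed from screening studies mix numeric cells in
#' scientific notation with below-detection ("-") and untested ("nd")
#' markers.  Both the plain R form \code{"1.2e9"} and the typeset form
#' \code{"1.2 x 10^9"} (with \code{x} or the multiplication sign) are
#' accepted.
#'
#' @param x character vector of raw cells.
#' @return data.frame with columns \code{value} (numeric, \code{NA} when no
#'   titer is available) and \code{status} (one of \code{"titer"},
#'   \code{"below_detection"}, \code{"untested"}).
#' @export
parse_titer <- function(x) {
  x <- trimws(as.character(x))
  status <- rep("titer", length(x))
  status[x == "-"] <- "below_detection"
  status[x %in% c("nd", "ND", "n.d.", "")] <- "untested"
  status[is.na(x)] <- "untested"
  value <- rep(NA_real_, length(x))
  num <- status == "titer"
  # normalize "a x 10^b" / "a  b" to "aeb"
  norm <- gsub("\\s*[x×]\\s*10\\s*\\^?\\s*", "e", x[num])
  norm <- gsub("\\s+", "", norm)
  value[num] <- suppressWarnings(as.numeric(norm))
  bad <- num & is.na(value)
  if (any(bad)) {
    stop("unparseable titer cell(s): ", paste(x[bad], collapse = ", "))
  }
  if (any(value[num] < 0 | !is.finite(value[num]))) {
    stop("titers must be finite and non-negative")
  }
  data.frame(value = value, status = status, stringsAsFactors = FALSE)
}

#' Round to one significant figure, halves away from zero
#'
#' The convention used for reporting efficiency of plating: the mantissa is
#' rounded to a single digit with ties going away from zero (so 2.5 -> 3),
#' and the exponent carries any overflow (9.6 -> 10 -> 1e1).
#'
#' @param x numeric vector, finite.
#' @return numeric vector rounded to one significant figure.
#' @export
round_signif1 <- function(x) {
  out <- x
  nz <- !is.na(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  m <- abs(x[nz]) / 10^e
  # m in [1, 10); floor(m + 0.5) rounds halves away from zero
  out[nz] <- sign(x[nz]) * floor(m + 0.5) * 10^e
  out
}

#' Efficiency of plating
#'
#' EOP is the ratio of a virus's plaque titer on a test host to its titer on
#' the reference (usually isolation) host; a value of 1 means equal plating
#' efficiency.  Reported values are conventionally rounded to one
#' significant figure (\code{\link{round_signif1}}).
#'
#' @param titer_test numeric titer on the test host (pfu/mL).  \code{NA}
#'   marks a below-detection result, for which the EOP is undefined.
#' @param titer_reference positive numeric titer on the reference host.
#' @param detection_limit optional plaque-assay detection limit (pfu/mL);
#'   when given, below-detection cells get an EOP upper bound
#'   \code{detection_limit / titer_reference}.
#' @return data.frame with columns \code{eop_raw}, \code{eop_rounded},
#'   \code{eop_label} (one-significant-figure string such as
#'   \code{"6 x 10^-6"}) and \code{eop_upper_bound}.
#' @examples
#' compute_eop(6.8e3, 1.2e9)  # EOP 6e-06
#' @export
compute_eop <- function(titer_test, titer_reference, detection_limit = NULL) {
  n <- max(length(titer_test), length(titer_reference))
  titer_test <- rep_len(titer_test, n)
  titer_reference <- rep_len(titer_reference, n)
  if (any(is.na(titer_reference) | titer_reference <= 0 |
            !is.finite(titer_reference))) {
    stop("reference titer must be a positive finite number")
  }
  if (any(!is.na(titer_test) & (titer_test <= 0 | !is.finite(titer_test)))) {
    stop("test titer must be positive and finite when present")
  }
  raw <- titer_test / titer_reference
  rounded <- round_signif1(raw)
  ub <- rep(NA_real_, n)
  if (!is.null(detection_limit)) {
    ub[is.na(titer_test)] <- detection_limit / titer_reference[is.na(titer_test)]
  }
  data.frame(
    eop_raw = raw,
    eop_rounded = rounded,
    eop_label = format_eop(rounded),
    eop_upper_bound = ub,
    stringsAsFactors = FALSE
  )
}

#' Format a one-significant-figure EOP for display
#'
#' @param x numeric vector already rounded to one significant figure.
#' @return character vector: plain digits for values in [1, 10), otherwise
#'   \code{"m x 10^e"}.
#' @export
format_eop <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v == 0) return("0")
    e <- floor(log10(abs(v)))
    m <- round(v / 10^e)
    if (e == 0) as.character(m) else sprintf("%d x 10^%d", m, e)
  }, character(1))
}

#' Classify a virus-host pair from the two-stage screen
#'
#' The screen spots lysate on a host lawn (spot-on-lawn) and follows any
#' growth inhibition with a quantitative plaque assay.  Halocins -
#' antimicrobial proteins co-purifying with some lysates - inhibit lawns
#' without forming plaques, so only plaque-confirmed pairs count as
#' positive; spot-only inhibition is flagged \code{halocin_suspect}.
#'
#' @param spot_inhibition logical, growth inhibition in the spot assay.
#' @param plaques_observed logical, plaques seen in the plaque assay.
#' @return character vector: \code{"positive"}, \code{"halocin_suspect"} or
#'   \code{"negative"}.
#' @export
call_interaction <- function(spot_inhibition, plaques_observed) {
  n <- max(length(spot_inhibition), length(plaques_observed))
  spot_inhibition <- rep_len(as.logical(spot_inhibition), n)
  plaques_observed <- rep_len(as.logical(plaques_observed), n)
  if (any(is.na(spot_inhibition)) || any(is.na(plaques_observed))) {
    stop("spot_inhibition and plaques_observed must be TRUE/FALSE")
  }
  ifelse(plaques_observed, "positive",
         ifelse(spot_inhibition, "halocin_suspect", "negative"))
}

#' Build a host-range matrix from assay tables
#'
#' @param titers data.frame with columns \code{virus_id}, \code{host_id},
#'   \code{assay} (\code{"spot"} or \code{"plaque"}) and \code{titer}.  For
#'   plaque rows the titer cell is a number (plaques observed, titer in
#'   pfu/mL), \code{"-"} (no plaques) or \code{"nd"} (not done).  For spot
#'   rows it is \code{"+"} (inhibition), \code{"-"} (no inhibition) or
#'   \code{"nd"}.  A pair with no row at all is untested.
#' @param viruses optional data.frame of virus metadata (\code{virus_id},
#'   \code{genus}, \code{family}, \code{morphology}, \code{own_host}).
#' @param identity_groups optional list of character vectors of virus ids
#'   declared genome-identical (from sequencing, not computed here); groups
#'   must be disjoint.
#' @return object of class \code{host_range_matrix}: a list with
#'   \code{viruses}, \code{hosts}, \code{cells} (one row per tested pair
#'   with \code{spot_inhibition}, \code{plaques_observed}, \code{call},
#'   \code{titer}, \code{titer_status}) and \code{identity_groups}.
#' @export
build_host_range_matrix <- function(titers, viruses = NULL,
                                    identity_groups = list()) {
  req <- c("virus_id", "host_id", "assay", "titer")
  if (!all(req %in% names(titers))) {
    stop("titers must have columns ", paste(req, collapse = ", "))
  }
  if (!all(titers$assay %in% c("spot", "plaque"))) {
    stop("assay must be 'spot' or 'plaque'")
  }
  check_identity_groups(identity_groups)

  virus_ids <- if (!is.null(viruses)) as.character(viruses$virus_id) else
    unique(as.character(titers$virus_id))
  if (anyDuplicated(virus_ids)) stop("duplicate virus ids in metadata")
  extra <- setdiff(unique(titers$virus_id), virus_ids)
  if (length(extra)) {
    stop("titer table references undeclared virus id(s): ",
         paste(extra, collapse = ", "))
  }
  unknown <- setdiff(unlist(identity_groups), virus_ids)
  if (length(unknown)) {
    stop("identity group references unknown virus id(s): ",
         paste(unknown, collapse = ", "))
  }
  hosts <- unique(as.character(titers$host_id))

  key <- interaction(titers$virus_id, titers$host_id, drop = TRUE)
  cells <- lapply(split(titers, key), function(d) {
    spot <- d[d$assay == "spot", , drop = FALSE]
    plq <- d[d$assay == "plaque", , drop = FALSE]
    if (nrow(spot) > 1 || nrow(plq) > 1) {
      stop("duplicate assay row for pair ", d$virus_id[1], " / ", d$host_id[1])
    }
    spot_cell <- if (nrow(spot)) trimws(as.character(spot$titer)) else "nd"
    spot_tested <- !(spot_cell %in% c("nd", "ND", "")) && !is.na(spot_cell)
    spot_inh <- spot_tested && spot_cell == "+"
    if (spot_tested && !spot_cell %in% c("+", "-")) {
      stop("spot cell must be '+', '-' or 'nd', got: ", spot_cell)
    }
    if (nrow(plq)) {
      pt <- parse_titer(plq$titer)
      plq_tested <- pt$status != "untested"
      plaques <- pt$status == "titer"
      titer <- pt$value
      tstat <- pt$status
    } else {
      plq_tested <- FALSE
      plaques <- FALSE
      titer <- NA_real_
      tstat <- "untested"
    }
    call <- if (!spot_tested && !plq_tested) "untested" else
      call_interaction(spot_inh, plaques)
    data.frame(
      virus_id = as.character(d$virus_id[1]),
      host_id = as.character(d$host_id[1]),
      spot_inhibition = if (spot_tested) spot_inh else NA,
      plaques_observed = plaques,
      call = call,
      titer = titer,
      titer_status = tstat,
      stringsAsFactors = FALSE
    )
  })
  cells <- rbind_rows(cells)
  structure(
    list(viruses = viruses %||% data.frame(virus_id = virus_ids,
                                           stringsAsFactors = FALSE),
         hosts = hosts, cells = cells,
         identity_groups = identity_groups),
    class = "host_range_matrix"
  )
}

check_identity_groups <- function(groups) {
  ids <- unlist(groups)
  if (anyDuplicated(ids)) {
    stop("identity groups overlap: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data.frame rows, dropping NULLs; NULL if nothing to bind
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.host_range_matrix <- function(x, ...) {
  cat("Host-range matrix:", nrow(x$viruses), "viruses x",
      length(x$hosts), "hosts\n")
  tab <- table(x$cells$call)
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$identity_groups)) {
    cat("  identity groups:",
        paste(vapply(x$identity_groups, paste, "", collapse = "+"),
              collapse = "; "), "\n")
  }
  invisible(x)
}

matrix_host_cells <- function(matrix, host_id) {
  if (!inherits(matrix, "host_range_matrix")) {
    stop("matrix must be a host_range_matrix")
  }
  if (!host_id %in% matrix$hosts) stop("unknown host: ", host_id)
  matrix$cells[matrix$cells$host_id == host_id, , drop = FALSE]
}

#' Count plaque-confirmed positive viruses on a host
#'
#' Counts every listed isolate, including members of genome-identity
#' groups; see \code{\link{dedup_unique}} for the deduplicated count.
#'
#' @param matrix a \code{host_range_matrix}.
#' @param host_id host to count positives on.
#' @return integer count.
#' @export
count_positive <- function(matrix, host_id) {
  sum(matrix_host_cells(matrix, host_id)$call == "positive")
}

#' Count unique positive isolates after genome-identity deduplication
#'
#' Each identity group (isolates with identical genome sequences, declared
#' as input metadata) with at least one positive member is collapsed to a
#' single isolate before counting.
#'
#' @inheritParams count_positive
#' @return integer count; always \code{<= count_positive}.
#' @export
dedup_unique <- function(matrix, host_id) {
  check_identity_groups(matrix$identity_groups)
  cells <- matrix_host_cells(matrix, host_id)
  pos <- cells$virus_id[cells$call == "positive"]
  n <- length(pos)
  for (g in matrix$identity_groups) {
    k <- sum(pos %in% g)
    if (k > 1) n <- n - (k - 1L)
  }
  as.integer(n)
}

#' Range of titers over positive cells on a host
#'
#' @inheritParams count_positive
#' @return named numeric vector \code{c(min = , max = )} in pfu/mL.
#' @export
titer_summary <- function(matrix, host_id) {
  cells <- matrix_host_cells(matrix, host_id)
  t <- cells$titer[cells$call == "positive" & !is.na(cells$titer)]
  if (!length(t)) stop("no positive cells with a titer for host ", host_id)
  c(min = min(t), max = max(t))
}

#' EOP table for one test host against each virus's own host
#'
#' For every virus with a measured titer on its own (reference) host, the
#' EOP on \code{test_host} is computed; viruses whose reference titer was
#' not determined are skipped, and below-detection test titers yield an
#' absent EOP (optionally bounded by \code{detection_limit}).
#'
#' @inheritParams count_positive
#' @param test_host host the EOP is computed on.
#' @param detection_limit optional detection limit passed to
#'   \code{\link{compute_eop}}.
#' @return data.frame with one row per virus: reference/test titers and the
#'   \code{\link{compute_eop}} columns.
#' @export
eop_table <- function(matrix, test_host, detection_limit = NULL) {
  if (is.null(matrix$viruses$own_host)) {
    stop("virus metadata with own_host is required for EOP")
  }
  rows <- lapply(seq_len(nrow(matrix$viruses)), function(i) {
    v <- matrix$viruses[i, ]
    ref <- matrix$cells[matrix$cells$virus_id == v$virus_id &
                          matrix$cells$host_id == v$own_host, , drop = FALSE]
    tst <- matrix$cells[matrix$cells$virus_id == v$virus_id &
                          matrix$cells$host_id == test_host, , drop = FALSE]
    if (!nrow(ref) || ref$titer_status != "titer") return(NULL)
    if (!nrow(tst) || tst$titer_status == "untested") return(NULL)
    test_titer <- if (tst$titer_status == "titer") tst$titer else NA_real_
    eop <- compute_eop(test_titer, ref$titer, detection_limit)
    cbind(data.frame(virus_id = v$virus_id, reference_host_id = v$own_host,
                     test_host_id = test_host,
                     titer_reference = ref$titer, titer_test = test_titer,
                     stringsAsFactors = FALSE),
          eop)
  })
  rbind_rows(rows)
}
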