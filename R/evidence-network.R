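#' Construct an evidence network from arm-level outcome records
#'
#' An evidence network is a collection of arm-level randomised-trial outcome
#' records. Nodes are treatment classes; an edge at follow-up time \code{t}
#' is a within-study comparison of two distinct classes that both report an
#' outcome at \code{t}. One record describes one arm of one study at one
#' follow-up time, in one of four reporting forms:
#' \describe{
#'   \item{COUNTS}{\code{y} of \code{n} women below the threshold (80 mL
#'     menstrual blood loss, or 100 PBAC points on the \code{PBAC} scale).}
#'   \item{MEAN_SD}{arm mean and standard deviation of the outcome.}
#'   \item{MEDIAN_RANGE}{arm median, minimum and maximum.}
#'   \item{MEDIAN_IQR}{arm median and quartiles \code{q1}, \code{q3}.}
#' }
#'
#' @param arms data.frame with columns \code{study_id}, \code{class},
#'   \code{time_months}, \code{scale} (\code{"MBL"} or \code{"PBAC"}),
#'   \code{form}, and the numeric fields required by each form (\code{y},
#'   \code{n}, \code{mean}, \code{sd}, \code{median}, \code{min}, \code{max},
#'   \code{q1}, \code{q3}); optional \code{arm} (integer label separating
#'   same-class arms within a study, default 1) and \code{baseline_mean}
#'   (baseline mean MBL in mL, \code{NA} when the study did not report it).
#' @return An object of class \code{evidence_network}: a list with the
#'   validated \code{arms} table and the derived node set.
#' @seealso [load_network()], [direct_comparison_table()],
#'   [connected_components_at_time()]
#' @export
evidence_network <- function(arms) {
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  required <- c("study_id", "class", "time_months", "scale", "form", "n")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- c("time_months", "y", "n", "mean", "sd", "median",
                    "min", "max", "q1", "q3", "baseline_mean")
  for (col in numeric_cols) {
    if (!col %in% names(arms)) arms[[col]] <- NA_real_
    val <- arms[[col]]
    if (!is.numeric(val)) {
      conv <- suppressWarnings(as.numeric(as.character(val)))
      bad <- which(!is.na(val) & nzchar(trimws(as.character(val))) & is.na(conv))
      if (length(bad) > 0L) {
        stop("malformed numeric field '", col, "' in row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      arms[[col]] <- conv
    }
  }
  if (!"arm" %in% names(arms)) arms$arm <- 1L
  arms$arm[is.na(arms$arm)] <- 1L
  arms$study_id <- as.character(arms$study_id)
  arms$class <- canonical_class(arms$class)
  arms$scale <- toupper(trimws(as.character(arms$scale)))
  arms$form <- toupper(trimws(as.character(arms$form)))
  arms$time_months <- as.integer(arms$time_months)

  problems <- validate_arms(arms)
  if (length(problems) > 0L) {
    stop("invalid arm record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  key <- paste(arms$study_id, arms$arm, arms$class, arms$time_months,
               arms$scale, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (study, arm, class, time, scale) record(s) in row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  structure(list(arms = arms, nodes = sort(unique(arms$class))),
            class = "evidence_network")
}

# row-addressed invariant checks; returns character vector of messages
validate_arms <- function(arms) {
  msgs <- character(0)
  bad <- function(rows, what) {
    if (length(rows) > 0L)
      msgs <<- c(msgs, paste0("row ", rows, ": ", what))
  }
  bad(which(!arms$scale %in% c("MBL", "PBAC")), "scale must be MBL or PBAC")
  bad(which(!arms$form %in% c("COUNTS", "MEAN_SD", "MEDIAN_RANGE", "MEDIAN_IQR")),
      "unknown reporting form")
  bad(which(is.na(arms$time_months) | arms$time_months < 1L),
      "time_months must be a positive integer")
  bad(which(is.na(arms$n) | arms$n < 1), "n must be a positive integer")
  cnt <- which(arms$form == "COUNTS")
  bad(cnt[is.na(arms$y[cnt]) | arms$y[cnt] < 0 | arms$y[cnt] > arms$n[cnt]],
      "COUNTS requires 0 <= y <= n")
  ms <- which(arms$form == "MEAN_SD")
  bad(ms[is.na(arms$mean[ms]) | is.na(arms$sd[ms]) | arms$sd[ms] <= 0],
      "MEAN_SD requires mean and sd > 0")
  mr <- which(arms$form == "MEDIAN_RANGE")
  bad(mr[is.na(arms$median[mr]) | is.na(arms$min[mr]) | is.na(arms$max[mr]) |
           !(arms$min[mr] <= arms$median[mr] & arms$median[mr] <= arms$max[mr])],
      "MEDIAN_RANGE requires min <= median <= max")
  mq <- which(arms$form == "MEDIAN_IQR")
  bad(mq[is.na(arms$median[mq]) | is.na(arms$q1[mq]) | is.na(arms$q3[mq]) |
           !(arms$q1[mq] <= arms$median[mq] & arms$median[mq] <= arms$q3[mq])],
      "MEDIAN_IQR requires q1 <= median <= q3")
  bad(which(!is.na(arms$baseline_mean) & arms$baseline_mean <= 0),
      "baseline_mean, when present, must be > 0")
  msgs
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network:", length(unique(x$arms$study_id)), "studies,",
      nrow(x$arms), "arm-time records,", length(x$nodes), "treatment classes\n")
  cat("Classes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Load an evidence network from a CSV or JSON file
#'
#' Reads a table of arm-level outcome records (CSV with a header row, blank
#' cells meaning missing, or an equivalent JSON array of records) and
#' validates it into an [evidence_network()]. Rows violating the arm
#' invariants are rejected with row-addressed messages.
#'
#' @param path path to a \code{.csv} or \code{.json} file.
#' @return An \code{evidence_network}.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    arms <- jsonlite::fromJSON(path)
  } else {
    arms <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  }
  if (NROW(arms) == 0L) stop("empty network file: ", path, call. = FALSE)
  evidence_network(arms)
}

#' Write an evidence network to CSV
#'
#' @param net an \code{evidence_network}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "evidence_network"))
  utils::write.csv(net$arms, path, row.names = FALSE, na = "")
  invisible(path)
}

# unordered class-pair edges at time t, one row per (study, pair)
edges_at_time <- function(net, t) {
  arms <- net$arms[net$arms$time_months == t, , drop = FALSE]
  out <- list()
  for (sid in unique(arms$study_id)) {
    cls <- sort(unique(arms$class[arms$study_id == sid]))
    if (length(cls) >= 2L) {
      cmb <- utils::combn(cls, 2L)
      out[[sid]] <- data.frame(study_id = sid, a = cmb[1L, ], b = cmb[2L, ],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(study_id = character(0), a = character(0),
                      b = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Direct-comparison summary table
#'
#' One row per unordered pair of treatment classes compared within at least
#' one study, with the number of comparing RCTs, the total number of
#' patients in those RCTs, and the number of direct comparisons at each
#' follow-up time. A direct comparison at time \code{t} requires both
#' classes to report an outcome at the same \code{t}; a pair whose arms
#' report at disjoint times therefore contributes a row (and its patients)
#' but no per-time comparisons. The patient total takes, per study and
#' class, the largest arm size over that arm's reported times (the
#' enrolment-level count) and sums over arms and comparing studies.
#'
#' @param net an \code{evidence_network}.
#' @return data.frame with columns \code{pair}, \code{n_rcts},
#'   \code{total_patients}, and one \code{t<time>} column per follow-up time
#'   present in the network, sorted by pair label.
#' @export
direct_comparison_table <- function(net) {
  stopifnot(inherits(net, "evidence_network"))
  arms <- net$arms
  times <- sort(unique(arms$time_months))
  # studies containing each unordered class pair (any times)
  pair_rows <- list()
  for (sid in unique(arms$study_id)) {
    sub <- arms[arms$study_id == sid, , drop = FALSE]
    cls <- sort(unique(sub$class))
    if (length(cls) < 2L) next
    cmb <- utils::combn(cls, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      # per-class enrolment: max arm n over times, summed over same-class arms
      n_of <- function(cl) {
        s <- sub[sub$class == cl, , drop = FALSE]
        sum(tapply(s$n, s$arm, max))
      }
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        study_id = sid, pair = pair_label(a, b), a = a, b = b,
        patients = n_of(a) + n_of(b), stringsAsFactors = FALSE)
    }
  }
  if (length(pair_rows) == 0L) {
    out <- data.frame(pair = character(0), n_rcts = integer(0),
                      total_patients = numeric(0))
    for (t in times) out[[paste0("t", t)]] <- integer(0)
    return(out)
  }
  pr <- do.call(rbind, pair_rows)
  pairs <- sort(unique(pr$pair))
  out <- data.frame(pair = pairs,
                    n_rcts = as.integer(table(pr$pair)[pairs]),
                    total_patients = as.numeric(
                      tapply(pr$patients, pr$pair, sum)[pairs]),
                    stringsAsFactors = FALSE)
  for (t in times) {
    ed <- edges_at_time(net, t)
    lab <- if (nrow(ed)) pair_label(ed$a, ed$b) else character(0)
    out[[paste0("t", t)]] <- as.integer(
      vapply(pairs, function(p) sum(lab == p), integer(1)))
  }
  rownames(out) <- NULL
  out
}

#' Treatment classes involved in a direct comparison at a time
#'
#' @param net an \code{evidence_network}.
#' @param t follow-up time in months.
#' @return Character vector of canonical class codes appearing in at least
#'   one direct comparison at time \code{t} (empty if none).
#' @export
classes_at_time <- function(net, t) {
  stopifnot(inherits(net, "evidence_network"), t > 0)
  ed <- edges_at_time(net, t)
  sort(unique(c(ed$a, ed$b)))
}

#' Connected components of the evidence network at a time
#'
#' Partitions the classes involved in direct comparisons at time \code{t}
#' into maximal connected components of the comparison graph.
#'
#' @inheritParams classes_at_time
#' @return List of character vectors (class sets), largest first.
#' @export
connected_components_at_time <- function(net, t) {
  stopifnot(inherits(net, "evidence_network"), t > 0)
  ed <- edges_at_time(net, t)
  if (nrow(ed) == 0L) return(list())
  g <- igraph::graph_from_data_frame(unique(ed[, c("a", "b")]),
                                     directed = FALSE)
  comp <- igraph::components(g)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(unname(sets), sort)
  sets[order(-vapply(sets, length, integer(1)),
             vapply(sets, `[`, character(1), 1L))]
}

#' Export network structure as JSON
#'
#' Writes the node set and the per-time edge lists (one entry per follow-up
#' time with at least one direct comparison) to a JSON file.
#'
#' @param net an \code{evidence_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_network_json <- function(net, path) {
  stopifnot(inherits(net, "evidence_network"))
  times <- sort(unique(net$arms$time_months))
  edges <- list()
  for (t in times) {
    ed <- edges_at_time(net, t)
    if (nrow(ed) > 0L) {
      edges[[as.character(t)]] <- unique(ed[, c("a", "b")])
    }
  }
  jsonlite::write_json(list(nodes = net$nodes, edges_by_time = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
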