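#' @keywords internal
SOURCE_LABEL <- "SOURCE"

#' Construct a colony interaction schedule
#'
#' A `colony_schedule` holds the time-ordered record of trophallactic events in
#' one colony: who gave, who received, when, and how much. Source-feeding
#' events, in which a forager loads food at the external source, are encoded
#' with the reserved donor label `"SOURCE"`. Events are stored sorted by time;
#' ties keep their input order so that the event index defines a deterministic
#' total order (analyses are indexed by interaction number, not wall-clock
#' time).
#'
#' @param events data.frame with columns `time`, `donor`, `recipient`,
#'   `volume` and optionally `ambiguous` (logical; direction/volume below
#'   detection error).
#' @param colony_id label for the colony.
#' @param foragers optional character vector naming the foragers. When `NULL`,
#'   foragers are identified from SOURCE events (see [identify_foragers()]).
#' @param capacities optional named numeric vector of per-ant crop capacities
#'   in the same volume units as `volume`.
#' @return an object of class `colony_schedule` with elements `colony_id`,
#'   `events`, `ants`, `foragers`, `capacities`.
#' @seealso [read_interactions()], [write_interactions()]
#' @export
colony_schedule <- function(events, colony_id = "colony",
                            foragers = NULL, capacities = NULL) {
  required <- c("time", "donor", "recipient", "volume")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  events$donor <- as.character(events$donor)
  events$recipient <- as.character(events$recipient)
  events$time <- as.numeric(events$time)
  events$volume <- as.numeric(events$volume)
  if (is.null(events$ambiguous)) {
    events$ambiguous <- FALSE
  } else {
    events$ambiguous <- as.logical(events$ambiguous)
  }

  bad <- which(events$volume < 0)
  if (length(bad) > 0) {
    stop("negative volume at row ", bad[1])
  }
  bad <- which(events$time < 0)
  if (length(bad) > 0) {
    stop("negative time at row ", bad[1])
  }
  bad <- which(events$donor == events$recipient)
  if (length(bad) > 0) {
    stop("donor equals recipient at row ", bad[1])
  }
  if (any(events$recipient == SOURCE_LABEL)) {
    stop("recipient must not be SOURCE (row ",
         which(events$recipient == SOURCE_LABEL)[1], ")")
  }

  # stable sort: ties broken by original row order
  ord <- order(events$time, seq_len(nrow(events)))
  events <- events[ord, c("time", "donor", "recipient", "volume", "ambiguous"),
                   drop = FALSE]
  rownames(events) <- NULL

  ants <- sort(unique(c(
    setdiff(events$donor, SOURCE_LABEL), events$recipient
  )))
  sched <- structure(
    list(colony_id = as.character(colony_id), events = events, ants = ants,
         foragers = NULL, capacities = capacities),
    class = "colony_schedule"
  )
  sched$foragers <- tryCatch(
    identify_foragers(sched, override = foragers),
    error = function(e) character(0)
  )
  sched
}

#' @export
print.colony_schedule <- function(x, ...) {
  cat("colony_schedule '", x$colony_id, "': ",
      nrow(x$events), " events, ", length(x$ants), " ants, ",
      length(x$foragers), " foragers\n", sep = "")
  n_src <- sum(x$events$donor == SOURCE_LABEL)
  cat("  ", n_src, " source-feeding events, ",
      nrow(x$events) - n_src, " ant-to-ant transfers\n", sep = "")
  if (!is.null(x$capacities)) {
    cat("  capacities attached for ", length(x$capacities), " ants\n",
        sep = "")
  }
  invisible(x)
}

#' Read interaction schedules from the canonical CSV dialect
#'
#' The canonical dialect is UTF-8 comma-separated text with a header row and
#' columns `colony_id`, `time_s`, `donor`, `recipient`, `volume` and optional
#' `ambiguous`; the external food source is spelled exactly `"SOURCE"` in the
#' donor column. A plain `time` column is accepted as a synonym for `time_s`.
#' Files holding several colonies yield a named list of schedules.
#'
#' @param path file path (or connection) to read.
#' @return a single `colony_schedule`, or a named list of them when the file
#'   contains more than one `colony_id`.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_s" %in% names(tab) && !("time" %in% names(tab))) {
    names(tab)[names(tab) == "time_s"] <- "time"
  }
  required <- c("colony_id", "time", "donor", "recipient", "volume")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(sub("^time$", "time_s", missing_cols), collapse = ", "))
  }
  split_tabs <- split(tab, tab$colony_id)
  schedules <- lapply(names(split_tabs), function(cid) {
    colony_schedule(split_tabs[[cid]], colony_id = cid)
  })
  names(schedules) <- names(split_tabs)
  if (length(schedules) == 1L) schedules[[1L]] else schedules
}

#' Write a schedule in the canonical CSV dialect
#'
#' Volumes and times are written with 17 significant digits so that a
#' write/read round trip reproduces every field exactly.
#'
#' @param schedule a `colony_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(schedule, path) {
  stopifnot(inherits(schedule, "colony_schedule"))
  ev <- schedule$events
  out <- data.frame(
    colony_id = schedule$colony_id,
    time_s = sprintf("%.17g", ev$time),
    donor = ev$donor,
    recipient = ev$recipient,
    volume = sprintf("%.17g", ev$volume),
    ambiguous = ev$ambiguous,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identify the foragers of a colony
#'
#' Foragers are the ants that load food directly at the external source; in a
#' schedule they are the recipients of SOURCE events. An explicit `override`
#' takes precedence (e.g. when forager identity is known from observation but
#' source feedings were not recorded).
#'
#' @param schedule a `colony_schedule`.
#' @param override optional character vector of forager labels.
#' @return character vector of forager labels, sorted.
#' @export
identify_foragers <- function(schedule, override = NULL) {
  stopifnot(inherits(schedule, "colony_schedule"))
  if (!is.null(override)) {
    return(sort(unique(as.character(override))))
  }
  ev <- schedule$events
  foragers <- sort(unique(ev$recipient[ev$donor == SOURCE_LABEL]))
  if (length(foragers) == 0) {
    stop("no foragers identifiable: no SOURCE events and no override given")
  }
  foragers
}

#' Estimate per-ant crop capacities from a provenance trace
#'
#' Crop capacity is a physiological quantity the schedule itself cannot fully
#' reveal; the only schedule-derivable proxy is the maximum crop load each ant
#' was ever observed to hold, which bounds the true capacity from below. Ants
#' that never held food get `NA` and are listed in the `undefined` attribute.
#'
#' @param trace a `provenance_trace` from [track_provenance()].
#' @return named numeric vector of capacity estimates (crop-volume units),
#'   `NA` for ants never observed holding food, with attribute `undefined`
#'   naming those ants.
#' @export
estimate_capacities <- function(trace) {
  stopifnot(inherits(trace, "provenance_trace"))
  loads <- apply(trace$amounts, c(1, 2), sum)   # K x ants total loads
  caps <- apply(loads, 2, max)
  caps[caps <= 0] <- NA_real_
  structure(caps, undefined = names(caps)[is.na(caps)])
}

#' Import interaction workbooks (one sheet per colony)
#'
#' Helper for spreadsheet supplements that ship interaction tables as one
#' worksheet per colony. Column names are matched case-insensitively against
#' the canonical names (`time`/`time_s`, `donor`/`giver`, `recipient`/
#' `receiver`, `volume`/`size`/`amount`, `ambiguous`); whatever cannot be
#' matched is reported rather than guessed.
#'
#' @param path path to an `.xlsx` workbook.
#' @param sheets optional character vector of sheet names (default: all).
#' @return named list of `colony_schedule` objects, one per sheet.
#' @export
read_colony_workbook <- function(path, sheets = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx workbooks requires the 'readxl' package")
  }
  if (is.null(sheets)) sheets <- readxl::excel_sheets(path)
  synonyms <- list(
    time = c("time", "time_s", "interaction_time", "t"),
    donor = c("donor", "giver", "from"),
    recipient = c("recipient", "receiver", "to"),
    volume = c("volume", "size", "amount", "interaction_size"),
    ambiguous = c("ambiguous", "uncertain")
  )
  out <- lapply(sheets, function(sh) {
    tab <- as.data.frame(readxl::read_excel(path, sheet = sh))
    lowered <- tolower(names(tab))
    mapped <- vapply(synonyms, function(alts) {
      hit <- which(lowered %in% alts)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
    need <- c("time", "donor", "recipient", "volume")
    if (anyNA(mapped[need])) {
      stop("sheet '", sh, "': could not match column(s) ",
           paste(need[is.na(mapped[need])], collapse = ", "),
           "; found: ", paste(names(tab), collapse = ", "))
    }
    ev <- data.frame(
      time = tab[[mapped[["time"]]]],
      donor = tab[[mapped[["donor"]]]],
      recipient = tab[[mapped[["recipient"]]]],
      volume = tab[[mapped[["volume"]]]],
      stringsAsFactors = FALSE
    )
    if (!is.na(mapped[["ambiguous"]])) {
      ev$ambiguous <- tab[[mapped[["ambiguous"]]]]
    }
    colony_schedule(ev, colony_id = sh)
  })
  names(out) <- sheets
  out
}
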