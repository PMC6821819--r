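#' Read and validate a scan-sampling contact table
#'
#' Reads a per-minute scan table of ongoing trophallactic contacts. Each row
#' records one directed contact observed on one scan: the minute index
#' (0-based from food introduction), the donor, the receiver, and the nest
#' position of the mandible contact point in mm.
#'
#' @param path Path to a CSV file with columns `minute`, `donor`, `receiver`,
#'   `x_mm`, `y_mm` (header required, comma-separated, '.' decimal).
#' @param roster Character vector of all colony members. Scan rows naming an
#'   ant outside the roster are rejected.
#' @param geometry Optional [nest_geometry()]; when supplied, positions
#'   outside the nest bounds are rejected.
#' @return A data.frame of scan records sorted by (minute, donor, receiver).
#' @seealso [merge_consecutive_scans()] to collapse scans into events.
#' @export
read_scan_table <- function(path, roster, geometry = NULL) {
  if (!file.exists(path)) stop("scan table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scan_records(df, roster, geometry)
}

#' Validate scan records held in a data.frame
#'
#' @param scans data.frame with columns `minute`, `donor`, `receiver`,
#'   `x_mm`, `y_mm`.
#' @inheritParams read_scan_table
#' @return The validated data.frame, sorted by (minute, donor, receiver),
#'   with ids coerced to character and `minute` to integer.
#' @export
validate_scan_records <- function(scans, roster, geometry = NULL) {
  required <- c("minute", "donor", "receiver", "x_mm", "y_mm")
  missing <- setdiff(required, names(scans))
  if (length(missing) > 0) {
    stop("scan table is missing column(s): ", paste(missing, collapse = ", "))
  }
  scans <- scans[required]
  scans$donor <- as.character(scans$donor)
  scans$receiver <- as.character(scans$receiver)
  scans$minute <- as.integer(scans$minute)

  if (nrow(scans) == 0) {
    return(scans[order(scans$minute), , drop = FALSE])
  }
  if (anyNA(scans$minute) || any(scans$minute < 0)) {
    stop("scan minutes must be non-negative integers")
  }
  bad <- which(scans$donor == scans$receiver)
  if (length(bad) > 0) {
    stop("donor equals receiver in scan row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  unknown <- setdiff(unique(c(scans$donor, scans$receiver)), roster)
  if (length(unknown) > 0) {
    stop("scan table names ant(s) not in the roster: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (!is.null(geometry)) {
    out <- which(scans$x_mm < 0 | scans$x_mm > geometry$width_mm |
                 scans$y_mm < 0 | scans$y_mm > geometry$height_mm)
    if (length(out) > 0) {
      stop("position outside nest bounds in scan row(s): ",
           paste(utils::head(out, 5L), collapse = ", "))
    }
  }
  scans <- scans[order(scans$minute, scans$donor, scans$receiver), ,
                 drop = FALSE]
  rownames(scans) <- NULL
  scans
}

#' Collapse consecutive scans of the same directed pair into events
#'
#' A contact between the same ordered (donor, receiver) pair observed on two
#' or more strictly consecutive minute scans is a single trophallactic event
#' whose duration is the length of the run. A role swap between consecutive
#' scans, or a gap of one or more missing minutes, starts a new event. The
#' event position is that of the first scan of the run.
#'
#' @param scans Validated scan data.frame (see [validate_scan_records()]).
#' @return data.frame of events with columns `donor`, `receiver`,
#'   `start_min`, `duration_min`, `x_mm`, `y_mm`, sorted by
#'   (start_min, donor, receiver).
#' @export
merge_consecutive_scans <- function(scans) {
  empty <- data.frame(donor = character(), receiver = character(),
                      start_min = integer(), duration_min = integer(),
                      x_mm = numeric(), y_mm = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(scans) == 0) return(empty)

  o <- order(scans$donor, scans$receiver, scans$minute)
  s <- scans[o, , drop = FALSE]
  # a new run starts when the pair changes or the minute is not the successor
  new_run <- c(TRUE,
               s$donor[-1] != s$donor[-nrow(s)] |
               s$receiver[-1] != s$receiver[-nrow(s)] |
               s$minute[-1] != s$minute[-nrow(s)] + 1L)
  run_id <- cumsum(new_run)
  first <- which(new_run)
  events <- data.frame(
    donor = s$donor[first],
    receiver = s$receiver[first],
    start_min = s$minute[first],
    duration_min = as.integer(tabulate(run_id)),
    x_mm = s$x_mm[first],
    y_mm = s$y_mm[first],
    stringsAsFactors = FALSE
  )
  events <- events[order(events$start_min, events$donor, events$receiver), ,
                   drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Expand merged events back into per-minute scan rows
#'
#' Inverse of [merge_consecutive_scans()]; used for round-trip checks and for
#' emitting simulated scan tables.
#'
#' @param events Event data.frame from [merge_consecutive_scans()].
#' @return Scan data.frame, one row per (event, minute).
#' @export
events_to_scans <- function(events) {
  if (nrow(events) == 0) {
    return(data.frame(minute = integer(), donor = character(),
                      receiver = character(), x_mm = numeric(),
                      y_mm = numeric(), stringsAsFactors = FALSE))
  }
  idx <- rep.int(seq_len(nrow(events)), events$duration_min)
  offset <- sequence(events$duration_min) - 1L
  scans <- data.frame(
    minute = events$start_min[idx] + offset,
    donor = events$donor[idx],
    receiver = events$receiver[idx],
    x_mm = events$x_mm[idx],
    y_mm = events$y_mm[idx],
    stringsAsFactors = FALSE
  )
  scans[order(scans$minute, scans$donor, scans$receiver), , drop = FALSE]
}

#' Read a feeding-visit table
#'
#' @param path CSV with columns `ant`, `start_s`, `duration_s`: one row per
#'   uninterrupted stay of one ant at the food source, timed in seconds from
#'   trial start.
#' @return data.frame of visits.
#' @export
read_feeding_visits <- function(path) {
  if (!file.exists(path)) stop("feeding-visit table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ant", "start_s", "duration_s")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("visit table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$ant <- as.character(df$ant)
  if (nrow(df) > 0 && any(df$duration_s <= 0)) {
    stop("visit durations must be positive")
  }
  df[required]
}

#' Classify foragers by feeding visits
#'
#' An ant is a forager (caste `"F"`) if at least one single visit to the food
#' source lasted `threshold_s` consecutive seconds or more; all other colony
#' members are non-foragers (`"NF"`). Summed shorter visits do not qualify.
#'
#' @param visits Visit data.frame (see [read_feeding_visits()]); may have
#'   zero rows.
#' @param roster Character vector of all colony members.
#' @param threshold_s Minimum single-visit duration in seconds (default 5).
#' @return A caste map: data.frame with columns `ant` and `caste`
#'   (`"F"`/`"NF"`), one row per roster member.
#' @export
assign_castes <- function(visits, roster, threshold_s = 5) {
  stopifnot(threshold_s > 0)
  unknown <- setdiff(unique(visits$ant), roster)
  if (length(unknown) > 0) {
    stop("visit table names ant(s) not in the roster: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  foragers <- unique(visits$ant[visits$duration_s >= threshold_s])
  data.frame(ant = roster,
             caste = ifelse(roster %in% foragers, "F", "NF"),
             stringsAsFactors = FALSE)
}

caste_of <- function(castes, ids) {
  castes$caste[match(ids, castes$ant)]
}

first_or_na <- function(x) if (length(x) == 0) NA_real_ else min(x)

#' Per-individual activity profiles
#'
#' Tallies each colony member's trophallactic activity: events given and
#' received, balance (given minus received), first-event times by role,
#' number of distinct partners, feeding visits, and total minutes spent in
#' trophallaxis. Every roster member gets a profile; ants with no events have
#' zero counts, absent (NA) first times, and `active = FALSE`.
#'
#' @param events Merged event data.frame.
#' @param visits Feeding-visit data.frame (may have zero rows).
#' @param castes Caste map from [assign_castes()].
#' @return data.frame, one row per roster member.
#' @export
build_profiles <- function(events, visits, castes) {
  roster <- castes$ant
  tab <- function(ids) {
    out <- integer(length(roster))
    if (length(ids) > 0) {
      t <- table(factor(ids, levels = roster))
      out <- as.integer(t)
    }
    out
  }
  n_given <- tab(events$donor)
  n_received <- tab(events$receiver)

  fg <- vapply(roster, function(a)
    first_or_na(events$start_min[events$donor == a]), numeric(1))
  fr <- vapply(roster, function(a)
    first_or_na(events$start_min[events$receiver == a]), numeric(1))
  fa <- pmin(fg, fr, na.rm = TRUE)
  fa[is.na(fg) & is.na(fr)] <- NA_real_

  partners <- vapply(roster, function(a) {
    p <- c(events$receiver[events$donor == a], events$donor[events$receiver == a])
    length(unique(p))
  }, integer(1))

  troph_min <- vapply(roster, function(a)
    sum(events$duration_min[events$donor == a | events$receiver == a]),
    numeric(1))

  n_visits <- integer(length(roster))
  first_visit <- rep(NA_real_, length(roster))
  if (nrow(visits) > 0) {
    n_visits <- tab(visits$ant)
    first_visit <- vapply(roster, function(a)
      first_or_na(visits$start_s[visits$ant == a]), numeric(1))
  }

  data.frame(
    ant = roster,
    caste = castes$caste,
    n_given = n_given,
    n_received = n_received,
    n_total = n_given + n_received,
    balance = n_given - n_received,
    first_given_min = fg,
    first_received_min = fr,
    first_any_min = fa,
    n_partners = partners,
    n_visits = n_visits,
    first_visit_s = first_visit,
    total_troph_min = troph_min,
    active = (n_given + n_received) > 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
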