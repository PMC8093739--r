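# Detection-log QC, resident events and residency statistics.
#
# A detection is one decoded tag transmission at one receiver. All analyses
# work on a plain data.frame with columns timestamp (POSIXct, UTC), tag_id
# and receiver_id, sorted by timestamp.

#' Read an acoustic detection log
#'
#' Reads a delimited detection export (one row per decoded transmission),
#' parses timestamps (ISO-8601 or `DD/MM/YYYY HH:MM:SS`, both UTC), drops
#' exact duplicate rows with a message, and returns detections sorted by time.
#'
#' @param path Path to a delimited text file with a header.
#' @param col_map Named character vector mapping the roles `timestamp`,
#'   `receiver`, `transmitter` to the file's column names.
#' @param sep Field separator.
#' @return A data.frame with columns `timestamp`, `tag_id`, `receiver_id`,
#'   sorted ascending by `timestamp`. The number of duplicates removed is
#'   attached as attribute `n_duplicates`.
#' @export
read_detections <- function(path,
                            col_map = c(timestamp = "timestamp",
                                        receiver = "receiver",
                                        transmitter = "transmitter"),
                            sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(raw) == 0) {
    warning("empty detection log: ", path)
    return(structure(
      data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                 tag_id = character(), receiver_id = character()),
      n_duplicates = 0L))
  }
  need <- c("timestamp", "receiver", "transmitter")
  if (!all(need %in% names(col_map))) {
    stop("col_map must name columns for: ", paste(need, collapse = ", "))
  }
  missing_cols <- setdiff(unname(col_map[need]), names(raw))
  if (length(missing_cols)) {
    stop("detection log lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ts <- parse_timestamp(raw[[col_map[["timestamp"]]]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("unparsable timestamp at data line(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  dets <- data.frame(timestamp = ts,
                     tag_id = as.character(raw[[col_map[["transmitter"]]]]),
                     receiver_id = as.character(raw[[col_map[["receiver"]]]]),
                     stringsAsFactors = FALSE)
  dup <- duplicated(dets)
  if (any(dup)) {
    message(sum(dup), " duplicate detection row(s) removed")
    dets <- dets[!dup, , drop = FALSE]
  }
  dets <- dets[order(dets$timestamp, dets$tag_id, dets$receiver_id), ,
               drop = FALSE]
  rownames(dets) <- NULL
  structure(dets, n_duplicates = sum(dup))
}

#' Screen suspected false detections
#'
#' Applies an interval-ratio screen per (tag, receiver) detection stream.
#' Inter-detection intervals are classed short (< `short`) or long
#' (> `long`). A detection is flagged as suspected-false when it is
#' temporally isolated -- the interval to both its previous and next
#' neighbour in the stream exceeds `long` (stream endpoints: their single
#' neighbouring interval; singleton streams are always isolated) -- AND the
#' stream's short:long interval count ratio is below 1. Streams rich in
#' short intervals are thereby protected: genuine occupancy produces bursts
#' of pings 30-90 s apart.
#'
#' @param dets Detection data.frame (see [read_detections()]), sorted.
#' @param short Short-interval threshold in seconds (default 30 min).
#' @param long Long-interval threshold in seconds (default 12 h).
#' @return A list with elements `kept` and `flagged` (both detection
#'   data.frames); together they partition the input exactly.
#' @export
filter_false_detections <- function(dets, short = 30 * 60, long = 12 * 3600) {
  stopifnot(short < long)
  if (nrow(dets) == 0) return(list(kept = dets, flagged = dets))
  key <- paste(dets$tag_id, dets$receiver_id, sep = "\r")
  flagged <- logical(nrow(dets))
  for (k in unique(key)) {
    i <- which(key == k)
    t <- as.numeric(dets$timestamp[i])
    iv <- diff(t)
    n_short <- sum(iv < short)
    n_long <- sum(iv > long)
    ratio <- if (n_short == 0) 0 else if (n_long == 0) Inf else n_short / n_long
    if (ratio >= 1) next
    m <- length(i)
    if (m == 1) {
      flagged[i] <- TRUE
      next
    }
    prev_long <- c(TRUE, iv > long) # interval to previous (endpoint: none)
    next_long <- c(iv > long, TRUE)
    flagged[i[prev_long & next_long]] <- TRUE
  }
  list(kept = dets[!flagged, , drop = FALSE],
       flagged = dets[flagged, , drop = FALSE])
}

#' Detect resident events
#'
#' A resident event is a contiguous occupancy interval of one tag at one
#' receiver: it begins with two or more successive detections at the same
#' receiver separated by no more than `timeout`, extends while same-receiver
#' detections keep arriving within `timeout` of the last, and terminates at
#' the time of its last member detection either when no further detection at
#' that receiver arrives within `timeout`, or when the tag is detected at
#' least `switch_count` times at another receiver first. Intervening single
#' detections at another receiver do not close an event.
#'
#' @param dets Detection data.frame, sorted by timestamp.
#' @param timeout Maximum within-event gap in seconds (default 60 min).
#' @param switch_count Number of detections at another receiver that closes
#'   an open event (default 2).
#' @return data.frame with columns `tag_id`, `receiver_id`, `start`, `end`,
#'   `n_detections`, `duration_min`.
#' @export
detect_resident_events <- function(dets, timeout = 3600, switch_count = 2L) {
  out <- list()
  for (tag in unique(dets$tag_id)) {
    d <- dets[dets$tag_id == tag, , drop = FALSE]
    d <- d[order(d$timestamp), , drop = FALSE]
    t <- as.numeric(d$timestamp)
    r <- d$receiver_id
    # current open run at one receiver + candidate runs at the others
    cur <- NULL # list(recv, start, last, n)
    cand <- list() # per-receiver: c(start, last, n) since last `cur` detection
    close_cur <- function(cur) {
      if (!is.null(cur) && cur$n >= 2) {
        out[[length(out) + 1]] <<- data.frame(
          tag_id = tag, receiver_id = cur$recv,
          start = as.POSIXct(cur$start, origin = "1970-01-01", tz = "UTC"),
          end = as.POSIXct(cur$last, origin = "1970-01-01", tz = "UTC"),
          n_detections = cur$n, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(t)) {
      ti <- t[i]; ri <- r[i]
      if (is.null(cur)) {
        cur <- list(recv = ri, start = ti, last = ti, n = 1L)
        cand <- list()
        next
      }
      if (ri == cur$recv) {
        if (ti - cur$last <= timeout) {
          cur$last <- ti
          cur$n <- cur$n + 1L
        } else {
          close_cur(cur)
          cur <- list(recv = ri, start = ti, last = ti, n = 1L)
        }
        cand <- list() # run at cur receiver resets switch tallies
      } else {
        cr <- cand[[ri]]
        if (is.null(cr) || ti - cr[2] > timeout) {
          cr <- c(ti, ti, 1)
        } else {
          cr[2] <- ti
          cr[3] <- cr[3] + 1
        }
        cand[[ri]] <- cr
        if (cr[3] >= switch_count) {
          close_cur(cur) # closes at its own last detection time
          cur <- list(recv = ri, start = cr[1], last = cr[2], n = as.integer(cr[3]))
          cand <- list()
        }
      }
    }
    close_cur(cur)
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(), receiver_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer(), duration_min = numeric()))
  }
  ev <- do.call(rbind, out)
  ev$duration_min <- as.numeric(ev$end - ev$start, units = "mins")
  ev <- ev[order(ev$tag_id, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Residency index
#'
#' Percentage of days an animal was detected out of the days spanned by its
#' first and last detection: `100 * detection_days / tracking_days`.
#'
#' @param detection_days Count of distinct calendar days with at least one
#'   detection.
#' @param tracking_days Inclusive day span, first to last detection.
#' @return Residency index in percent (full precision; round for reports).
#' @export
residency_index <- function(detection_days, tracking_days) {
  if (any(tracking_days < 1)) stop("tracking_days must be >= 1")
  if (any(detection_days > tracking_days)) {
    stop("detection_days cannot exceed tracking_days")
  }
  100 * detection_days / tracking_days
}

#' Per-tag tracking and residency summary
#'
#' For each tagged animal: tracking days (day span from first to last
#' detection; by default the ceiling of the fractional-day difference, with a
#' same-day span counting as 1), distinct detection days, total days from
#' deployment to data download, detection count, and the residency index.
#' Tags present in the metadata but never detected are excluded with a
#' message.
#'
#' @param dets Detection data.frame (kept detections).
#' @param tags Tag metadata data.frame with columns `tag_id`, `manta_id`,
#'   `sex`, `maturity`, `deploy_date` (Date or parseable).
#' @param download_date Date the receivers were downloaded (end of study).
#' @param span Day-span convention: `"ceiling"` (default; ceiling of the
#'   difference in fractional days, minimum 1) or `"calendar"` (count of
#'   calendar dates from first to last inclusive).
#' @return data.frame, one row per detected tag, with columns `manta_id`,
#'   `tag_id`, `sex`, `maturity`, `n_detections`, `tracking_days`,
#'   `detection_days`, `total_time_days`, `ri_percent`.
#' @seealso [cohort_stats()] for report-style cohort summaries.
#' @export
summarize_tracking <- function(dets, tags, download_date,
                               span = c("ceiling", "calendar")) {
  span <- match.arg(span)
  download_date <- as.Date(download_date)
  missing_meta <- setdiff(unique(dets$tag_id), tags$tag_id)
  if (length(missing_meta)) {
    stop("detections for tag(s) without metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  rows <- list()
  for (j in seq_len(nrow(tags))) {
    tag <- tags$tag_id[j]
    d <- dets[dets$tag_id == tag, , drop = FALSE]
    if (nrow(d) == 0) {
      message("tag ", tag, " has no detections; excluded from summary")
      next
    }
    first <- min(d$timestamp); last <- max(d$timestamp)
    tracking <- if (span == "ceiling") {
      max(1, ceiling(as.numeric(difftime(last, first, units = "days"))))
    } else {
      as.numeric(as.Date(last) - as.Date(first)) + 1
    }
    detection_days <- length(unique(as.Date(d$timestamp)))
    deploy <- as.Date(tags$deploy_date[j])
    rows[[length(rows) + 1]] <- data.frame(
      manta_id = as.character(tags$manta_id[j]), tag_id = as.character(tag),
      sex = as.character(tags$sex[j]), maturity = as.character(tags$maturity[j]),
      n_detections = nrow(d), tracking_days = tracking,
      detection_days = detection_days,
      total_time_days = as.numeric(download_date - deploy),
      ri_percent = residency_index(detection_days, tracking),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary statistics for a residency table
#'
#' Means, sample standard deviations (n - 1) and ranges for the numeric
#' residency columns, rounded half-up as in report tables, overall and
#' (optionally) per maturity class. `adult` covers maturity `"adult"` only;
#' `juvenile` pools `"juvenile"` and `"sub-adult"`.
#'
#' @param summary_df Output of [summarize_tracking()] (or any table with the
#'   same numeric columns; `ri_percent` may carry printed report values).
#' @param digits Decimal places for the rounded report values (default 0 for
#'   means, SDs reported at 1 decimal).
#' @return A list with elements `overall`, `adult`, `juvenile`, each a
#'   data.frame of statistic rows, plus `total_detections`.
#' @export
cohort_stats <- function(summary_df, digits = 0) {
  stat_block <- function(df) {
    num <- function(col) df[[col]]
    cols <- c("ri_percent", "detection_days", "tracking_days",
              "total_time_days")
    cols <- intersect(cols, names(df))
    data.frame(
      variable = cols,
      mean = round_half_up(vapply(cols, function(cl) mean(num(cl)), 0), digits),
      sd = round_half_up(vapply(cols, function(cl) sd(num(cl)), 0), 1),
      min = vapply(cols, function(cl) min(num(cl)), 0),
      max = vapply(cols, function(cl) max(num(cl)), 0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  mat <- tolower(summary_df$maturity %||% character())
  list(
    overall = stat_block(summary_df),
    adult = if (length(mat)) stat_block(summary_df[mat == "adult", , drop = FALSE]),
    juvenile = if (length(mat))
      stat_block(summary_df[mat %in% c("juvenile", "sub-adult"), , drop = FALSE]),
    total_detections = if ("n_detections" %in% names(summary_df))
      sum(summary_df$n_detections))
}

#' Diel distribution of detections
#'
#' Percentage of detections per hour of day (24 bins summing to 100) and the
#' day/night split over the configured hour sets. The printed day range
#' 06:00-18:00 includes the 18:00-18:59 hour; night 19:00-05:00 includes
#' 05:00-05:59.
#'
#' @param dets Detection data.frame.
#' @param day_hours Integer hours belonging to "day" (default 6:18).
#' @param night_hours Integer hours belonging to "night"
#'   (default c(19:23, 0:5)).
#' @return List with `by_hour` (data.frame hour/percent) and `day_night`
#'   (data.frame period/percent over the union of the two hour sets).
#' @export
diel_distribution <- function(dets, day_hours = 6:18,
                              night_hours = c(19:23, 0:5)) {
  hr <- as.integer(format(dets$timestamp, "%H", tz = "UTC"))
  counts <- tabulate(hr + 1L, nbins = 24L)
  by_hour <- data.frame(hour = 0:23, percent = 100 * counts / max(1, sum(counts)))
  in_day <- hr %in% day_hours
  in_night <- hr %in% night_hours
  denom <- sum(in_day | in_night)
  day_night <- data.frame(
    period = c("day", "night"),
    percent = 100 * c(sum(in_day), sum(in_night)) / max(1, denom))
  list(by_hour = by_hour, day_night = day_night)
}

#' Share of detections per site
#'
#' @param dets Detection data.frame.
#' @param receivers Receiver metadata data.frame with columns `receiver_id`
#'   and `site_name`.
#' @return data.frame `site`, `n`, `percent`; percentages sum to 100 over
#'   sites with at least one detection.
#' @export
site_share <- function(dets, receivers) {
  unknown <- setdiff(unique(dets$receiver_id), receivers$receiver_id)
  if (length(unknown)) {
    stop("unknown receiver_id: ", paste(unknown, collapse = ", "))
  }
  site <- receivers$site_name[match(dets$receiver_id, receivers$receiver_id)]
  tab <- table(site)
  data.frame(site = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published residency summary table
#'
#' The per-individual tag deployment, tracking and residency summary for
#' the 19 usable tags (printed report values; detections were downloaded on
#' 2020-03-17). The `ri_percent` column carries the values as printed; one
#' row (CG-MA-0120) is internally inconsistent with its own detection-day
#' and tracking-day counts.
#'
#' @return data.frame with one row per tagged individual; attribute
#'   `download_date`.
#' @export
residency_table <- function() {
  path <- system.file("extdata", "residency_table.csv", package = "tidaltag",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(tag_id = "character"))
  tab$deploy_date <- as.Date(tab$deploy_date, format = "%d/%m/%Y")
  tab$last_detection <- as.Date(tab$last_detection, format = "%d/%m/%Y")
  tab$total_time_days <- as.numeric(as.Date("2020-03-17") - tab$deploy_date)
  structure(tab, download_date = as.Date("2020-03-17"))
}
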