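#' Interaction channels of the multiplex cohort network
#'
#' The five channels through which participants interact: physical proximity
#' (person-to-person), online friendship and online feed activity, phone
#' calls and text messages. Calls additionally carry direction and duration.
#'
#' @export
CHANNELS <- c("proximity", "facebook_friend", "facebook_interaction",
              "call", "text")

GENDERS <- c("F", "M")

#' Construct a cohort
#'
#' A cohort bundles the participant table (one row per participant with a
#' binary gender label) with the observation window (a contiguous range of
#' week indices) and each participant's set of active weeks. A week counts
#' as active for a participant if they produced at least one interaction
#' record in any channel or at least one location observation in that week.
#'
#' @param participants data frame with columns `id` (unique character) and
#'   `gender` (`"F"` or `"M"`).
#' @param week_range integer vector of contiguous week indices
#'   (`0:(n_weeks-1)` by convention).
#' @param active_weeks named list mapping participant id to an integer
#'   vector of active week indices (subset of `week_range`).
#' @return An object of class `cohort`.
#' @export
cohort <- function(participants, week_range,
                   active_weeks = setNames(vector("list", nrow(participants)),
                                           participants$id)) {
  stopifnot(is.data.frame(participants),
            all(c("id", "gender") %in% names(participants)))
  participants$id <- as.character(participants$id)
  participants$gender <- as.character(participants$gender)
  if (anyDuplicated(participants$id))
    stop("participant ids must be unique")
  if (!all(participants$gender %in% GENDERS))
    stop("gender must be one of ", paste(GENDERS, collapse = ", "))
  week_range <- sort(as.integer(week_range))
  if (length(week_range) == 0L)
    stop("week_range must be non-empty")
  if (!all(diff(week_range) == 1L))
    stop("week_range must be contiguous")
  active_weeks <- active_weeks[participants$id]
  names(active_weeks) <- participants$id
  active_weeks <- lapply(active_weeks, function(w) {
    w <- sort(unique(as.integer(w)))
    if (!all(w %in% week_range))
      stop("active weeks must lie within week_range")
    w
  })
  structure(list(participants = participants,
                 week_range = week_range,
                 active_weeks = active_weeks),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$participants$gender, levels = GENDERS))
  cat(sprintf("<cohort> %d participants (%d F / %d M), weeks %d..%d\n",
              nrow(x$participants), tab[["F"]], tab[["M"]],
              min(x$week_range), max(x$week_range)))
  invisible(x)
}

#' Gender labels of a cohort
#'
#' @param x a `cohort`.
#' @return Named character vector (`"F"`/`"M"`) indexed by participant id.
#' @export
gender_labels <- function(x) {
  setNames(x$participants$gender, x$participants$id)
}

#' Aggregate interaction records into weekly graphs
#'
#' Collapses event-level interaction records of one channel into one
#' undirected labeled graph per week: each unordered participant pair gets a
#' single edge whose weight is the sum of the record weights for that week.
#' For calls, the directed event list (initiator, receiver, duration) is
#' retained alongside the undirected structure, since call-duration
#' statistics depend on who initiated.
#'
#' @param records data frame with columns `channel`, `week`, `source`,
#'   `target`, `weight` and, for calls, `duration_s` and
#'   `initiator_is_source`.
#' @param channel one of [CHANNELS].
#' @param cohort a [cohort()]; weekly graphs are defined over all its
#'   participants (isolates included).
#' @return An object of class `channel_series`: list with elements
#'   `channel`, `weekly_graphs` (named list week -> igraph graph with vertex
#'   attribute `gender` and edge attribute `weight`) and `events` (directed
#'   event data frame, calls/texts only).
#' @export
aggregate_weekly <- function(records, channel, cohort) {
  stopifnot(channel %in% CHANNELS)
  ids <- cohort$participants$id
  if (nrow(records) > 0) {
    records <- records[records$channel == channel, , drop = FALSE]
    bad <- !(records$source %in% ids) | !(records$target %in% ids)
    if (any(bad))
      stop("interaction records reference unknown participant ids: ",
           paste(unique(c(records$source[bad], records$target[bad])),
                 collapse = ", "))
    if (any(records$source == records$target))
      stop("self-interactions are not allowed")
    if (any(records$weight < 1))
      stop("record weights must be >= 1")
  }
  weekly <- list()
  if (nrow(records) > 0) {
    a <- pmin(records$source, records$target)
    b <- pmax(records$source, records$target)
    key <- paste(records$week, a, b, sep = "\r")
    wsum <- rowsum(as.numeric(records$weight), key)
    parts <- strsplit(rownames(wsum), "\r", fixed = TRUE)
    agg <- data.frame(week = as.integer(vapply(parts, `[`, "", 1L)),
                      a = vapply(parts, `[`, "", 2L),
                      b = vapply(parts, `[`, "", 3L),
                      weight = wsum[, 1L], stringsAsFactors = FALSE)
    for (w in sort(unique(agg$week))) {
      rows <- agg[agg$week == w, , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        data.frame(from = rows$a, to = rows$b, weight = rows$weight),
        directed = FALSE,
        vertices = data.frame(name = ids, gender = cohort$participants$gender))
      weekly[[as.character(w)]] <- g
    }
  }
  events <- NULL
  if (channel %in% c("call", "text") && nrow(records) > 0) {
    init <- ifelse(records$initiator_is_source, records$source,
                   records$target)
    recv <- ifelse(records$initiator_is_source, records$target,
                   records$source)
    events <- data.frame(week = records$week, initiator = init,
                         receiver = recv, weight = records$weight,
                         duration_s = if ("duration_s" %in% names(records))
                           records$duration_s else NA_real_,
                         stringsAsFactors = FALSE)
  }
  structure(list(channel = channel, weekly_graphs = weekly, events = events),
            class = "channel_series")
}

#' Retain participants with enough active weeks
#'
#' Participants with fewer than `min_active_weeks` active weeks over the
#' observation window are dropped; the study protocol excludes anyone with
#' three active weeks or less, hence the default of 4.
#'
#' @param x a [cohort()].
#' @param min_active_weeks minimum number of active weeks to retain.
#' @return Filtered `cohort`.
#' @export
filter_active <- function(x, min_active_weeks = 4L) {
  n_active <- vapply(x$active_weeks, length, integer(1))
  keep <- n_active >= min_active_weeks
  cohort(x$participants[keep, , drop = FALSE], x$week_range,
         x$active_weeks[keep])
}

#' Average a weekly indicator over the weeks in which it is defined
#'
#' Weeks where the indicator is undefined (`NA`) are skipped rather than
#' treated as zeros; an indicator defined in no week averages to `NA`
#' (missing), which propagates into the feature table.
#'
#' @param indicator_by_week numeric vector (possibly named by week) of
#'   weekly indicator values, `NA` for undefined weeks.
#' @return Scalar mean, or `NA` if no week is defined.
#' @export
weekly_average <- function(indicator_by_week) {
  v <- indicator_by_week[!is.na(indicator_by_week)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

compute_active_weeks <- function(ids, week_range, interactions, locations) {
  active <- setNames(vector("list", length(ids)), ids)
  pairs <- rbind(
    if (nrow(interactions) > 0)
      data.frame(id = c(interactions$source, interactions$target),
                 week = c(interactions$week, interactions$week)),
    if (nrow(locations) > 0)
      data.frame(id = locations$id, week = locations$week))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pairs <- unique(pairs[pairs$id %in% ids, , drop = FALSE])
    sp <- split(as.integer(pairs$week), pairs$id)
    active[names(sp)] <- lapply(sp, function(w) sort(unique(w)))
  }
  active[vapply(active, is.null, logical(1))] <- list(integer(0))
  active
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("malformed file ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Read a cohort fixture directory
#'
#' Reads the four CSV tables (`participants.csv`, `interactions.csv`,
#' `locations.csv`, `traits.csv`) plus an optional `config.yaml` from a
#' directory, cross-references them, and returns the full in-memory model.
#' Interaction or location rows referencing ids absent from the participant
#' table are a referential-integrity error.
#'
#' @param dir directory containing the fixture files.
#' @param n_weeks number of weeks in the observation window; defaults to the
#'   value in `config.yaml` or, failing that, the largest week index seen
#'   plus one.
#' @return List with elements `cohort`, `networks` (named list of
#'   `channel_series`, one per [CHANNELS]), `locations`, `traits`, `config`.
#' @export
read_cohort <- function(dir, n_weeks = NULL) {
  participants <- read_csv_checked(file.path(dir, "participants.csv"),
                                   c("id", "gender"))
  participants$id <- as.character(participants$id)
  interactions <- read_csv_checked(
    file.path(dir, "interactions.csv"),
    c("channel", "week", "source", "target", "weight"))
  if (nrow(interactions) > 0) {
    interactions$source <- as.character(interactions$source)
    interactions$target <- as.character(interactions$target)
  }
  locations <- read_csv_checked(file.path(dir, "locations.csv"),
                                c("id", "week", "location_id",
                                  "time_fraction"))
  if (nrow(locations) > 0) locations$id <- as.character(locations$id)
  traits <- read_csv_checked(file.path(dir, "traits.csv"), "id")
  traits$id <- as.character(traits$id)

  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) config <- yaml::read_yaml(cfg_path)
  if (is.null(n_weeks)) n_weeks <- config$n_weeks
  if (is.null(n_weeks)) {
    n_weeks <- max(c(interactions$week, locations$week, 0L)) + 1L
  }
  week_range <- 0:(n_weeks - 1L)

  ids <- participants$id
  if (nrow(interactions) > 0) {
    bad <- !(interactions$source %in% ids) | !(interactions$target %in% ids)
    if (any(bad))
      stop("referential-integrity error: interactions.csv references ",
           "unknown ids: ",
           paste(unique(c(interactions$source[bad],
                          interactions$target[bad])), collapse = ", "))
    if (!(all(interactions$channel %in% CHANNELS)))
      stop("parse error in interactions.csv: unknown channel ",
           paste(setdiff(unique(interactions$channel), CHANNELS),
                 collapse = ", "))
  }
  if (nrow(locations) > 0 && any(!(locations$id %in% ids)))
    stop("referential-integrity error: locations.csv references unknown ids")
  if (any(!(traits$id %in% ids)))
    stop("referential-integrity error: traits.csv references unknown ids")

  active <- compute_active_weeks(ids, week_range, interactions, locations)
  coh <- cohort(participants, week_range, active)
  networks <- setNames(lapply(CHANNELS, function(ch)
    aggregate_weekly(interactions, ch, coh)), CHANNELS)
  list(cohort = coh, networks = networks, locations = locations,
       traits = traits, config = config)
}
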