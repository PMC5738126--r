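#' Shannon entropy of a weekly location-visit distribution
#'
#' \eqn{H_u = -\sum_{l \in L(u)} P_u(l) \log P_u(l)}, the entropy of the
#' relative time a participant spent across their visited locations in one
#' week. Higher entropy means time is spread more evenly over places.
#'
#' @param p numeric vector of relative time fractions (must be positive and
#'   sum to 1 within 1e-9).
#' @param base logarithm base; natural log by default, so the result is in
#'   nats.
#' @return Entropy, or `NA` for an empty distribution (undefined week).
#' @export
location_entropy <- function(p, base = exp(1)) {
  if (length(p) == 0) return(NA_real_)
  validate_distribution(p)
  -sum(p * log(p, base = base))
}

validate_distribution <- function(p) {
  if (any(p <= 0))
    stop("distribution entries must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9)
    stop("distribution must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Number of unique locations in a weekly distribution
#'
#' @param p numeric vector of relative time fractions, one per visited
#'   location.
#' @return Integer count `|L(u)|`, or `NA` for an empty week.
#' @export
unique_locations <- function(p) {
  if (length(p) == 0) return(NA_integer_)
  length(p)
}

#' Per-participant mobility indicator table
#'
#' Computes weekly location entropy and unique-location counts from the
#' long-format location table and averages each indicator over the weeks in
#' which the participant has location data.
#'
#' @param cohort a [cohort()] (already filtered for activity).
#' @param locations data frame with columns `id`, `week`, `location_id`,
#'   `time_fraction`; fractions of each id-week sum to 1.
#' @param base entropy log base, passed to [location_entropy()].
#' @return Data frame with rownames = participant id and columns
#'   `location_entropy`, `n_unique_locations` (`NA` where no location data).
#' @export
mobility_indicator_table <- function(cohort, locations, base = exp(1)) {
  ids <- cohort$participants$id
  out <- data.frame(location_entropy = rep(NA_real_, length(ids)),
                    n_unique_locations = rep(NA_real_, length(ids)),
                    row.names = ids)
  if (nrow(locations) == 0) return(out)
  locations <- locations[locations$id %in% ids, , drop = FALSE]
  by_user <- split(locations, locations$id)
  for (id in names(by_user)) {
    weeks <- split(by_user[[id]]$time_fraction, by_user[[id]]$week)
    ent <- vapply(weeks, location_entropy, numeric(1), base = base)
    nl <- vapply(weeks, function(p) as.numeric(unique_locations(p)),
                 numeric(1))
    out[id, "location_entropy"] <- weekly_average(ent)
    out[id, "n_unique_locations"] <- weekly_average(nl)
  }
  out
}
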