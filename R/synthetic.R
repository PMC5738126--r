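#' Configuration for the synthetic cohort generator
#'
#' The defaults encode the study conditions the pipeline is designed for:
#' a 166/601 female/male cohort (78% male), trait scores shifted between
#' genders by the pooled-SD effect sizes reported for this kind of student
#' cohort, location-visit distributions whose entropy and support size
#' differ by gender, five interaction channels with very different weekly
#' densities (proximity much denser than online, online denser than
#' telecom; the weekly densities are chosen so that four-week unions
#' reproduce the familiar ~40% / 2-3% / <1% monthly figures), a planted
#' same-gender dyad preference per channel, gender-pair-specific call
#' durations, and per-category missingness calibrated so about 21.5% of
#' participants miss at least one of the five feature categories.
#'
#' @param n_female,n_male group sizes.
#' @param n_weeks number of observation weeks.
#' @param n_inactive extra participants given at most 3 active weeks (they
#'   exist to exercise the activity filter; 0 by default).
#' @param trait_effects named vector of planted male-minus-female trait
#'   shifts in pooled-SD units (both genders have unit variance, so the
#'   planted shift *is* the expected effect size).
#' @param location_profile per-gender list with `mean_unique` (mean of the
#'   person-level weekly unique-location rate) and `concentration`
#'   (symmetric Dirichlet parameter controlling entropy; larger = more even
#'   = higher entropy).
#' @param person_heterogeneity person-level variation around the gender
#'   means: `sd_unique` (SD of the personal unique-location rate),
#'   `sdlog_concentration` (log-scale SD of the personal Dirichlet
#'   concentration) and `sdlog_activity` (log-scale SD of a personal
#'   interaction-activity multiplier applied to every channel). Without
#'   these, within-gender variance collapses and any gender gap turns into
#'   an implausibly large effect size.
#' @param channel_profiles per-channel list with `density` (weekly edge
#'   probability), `homophily` (h in `[0,1]`: same-gender dyads accepted
#'   proportional to 1+h, mixed to 1-h), `weight_mean` (Poisson mean of
#'   edge weight minus 1), and for calls `duration_means` (mean seconds per
#'   ordered initiator/receiver gender pair) and `duration_sdlog`.
#' @param p_active probability that a participant is active in a week.
#' @param missing_rate per-(participant, category) MCAR masking
#'   probability.
#' @param seed RNG seed; all generator randomness derives from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_female = 166L, n_male = 601L, n_weeks = 12L, n_inactive = 0L,
    trait_effects = c(
      neuroticism = -0.635, conscientiousness = -0.436,
      agreeableness = -0.259, extraversion = -0.118, openness = 0.143,
      self_esteem = 0.423, narcissism_total = 0.349,
      narcissism_admiration = 0.241, narcissism_rivalry = 0.334,
      stress = -0.451, locus_of_control = -0.157, satisfaction = -0.149,
      loneliness = 0.095),
    location_profile = list(
      F = list(mean_unique = 11, concentration = 1.0),
      M = list(mean_unique = 10, concentration = 0.85)),
    person_heterogeneity = list(sd_unique = 3, sdlog_concentration = 0.4,
                                sdlog_activity = 0.5),
    channel_profiles = list(
      proximity = list(density = 0.12, homophily = 0.15, weight_mean = 5),
      facebook_friend = list(density = 0.006, homophily = 0.20,
                             weight_mean = 1),
      facebook_interaction = list(density = 0.0025, homophily = 0.20,
                                  weight_mean = 2),
      call = list(density = 0.002, homophily = 0.25, weight_mean = 1,
                  duration_means = c(MF = 117, FF = 114.56, MM = 71.52,
                                     FM = 105),
                  duration_sdlog = 0.6),
      text = list(density = 0.002, homophily = 0.25, weight_mean = 4)),
    p_active = 0.95, missing_rate = 0.047, seed = 1L) {
  stopifnot(n_female > 0, n_male > 0, n_weeks > 0,
            missing_rate >= 0, missing_rate < 1)
  for (ch in names(channel_profiles)) {
    h <- channel_profiles[[ch]]$homophily
    if (h < 0 || h > 1) stop("homophily must be in [0, 1]")
  }
  structure(list(n_female = as.integer(n_female),
                 n_male = as.integer(n_male),
                 n_weeks = as.integer(n_weeks),
                 n_inactive = as.integer(n_inactive),
                 trait_effects = trait_effects,
                 location_profile = location_profile,
                 person_heterogeneity = person_heterogeneity,
                 channel_profiles = channel_profiles,
                 p_active = p_active, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Expected same-gender dyad fraction
#'
#' Under random mixing (`h = 0`) the expected fraction of same-gender edges
#' equals the same-gender share of all dyads,
#' `q = (C(nF,2)+C(nM,2)) / C(n,2)`. With planted homophily h, acceptance
#' odds are tilted by (1+h) for same-gender and (1-h) for mixed dyads,
#' giving `q(1+h) / (q(1+h) + (1-q)(1-h))` — strictly increasing in h.
#'
#' @param n_female,n_male group sizes.
#' @param h homophily parameter in `[0, 1]`.
#' @return Expected same-gender edge fraction.
#' @export
expected_same_gender_fraction <- function(n_female, n_male, h = 0) {
  q <- (choose(n_female, 2) + choose(n_male, 2)) /
    choose(n_female + n_male, 2)
  q * (1 + h) / (q * (1 + h) + (1 - q) * (1 - h))
}

FEATURE_CATEGORIES <- c("personality", "location", "call", "facebook",
                        "person_to_person")

#' Generate a synthetic cohort
#'
#' Draws a full synthetic data bundle — participants, weekly interaction
#' records for the five channels, weekly location-visit distributions and
#' trait scores — with the statistical structure the downstream analysis
#' assumes, plus a truth record of every planted parameter. Same seed,
#' same output, bit for bit.
#'
#' @param config a [generator_config()].
#' @return List with `cohort`, `networks` (per-channel `channel_series`),
#'   `interactions` (raw records), `locations`, `traits`,
#'   `missing_categories` (participant x category logical mask) and
#'   `truth`.
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nF <- config$n_female; nM <- config$n_male
  n <- nF + nM + config$n_inactive
  ids <- sprintf("p%04d", seq_len(n))
  extra_gender <- if (config$n_inactive > 0)
    sample(GENDERS, config$n_inactive, replace = TRUE) else character(0)
  genders <- c(rep("F", nF), rep("M", nM), extra_gender)
  weeks <- 0:(config$n_weeks - 1L)

  # per-participant weekly activity; "inactive" extras get <= 3 weeks
  activity <- matrix(rbinom(n * config$n_weeks, 1, config$p_active) == 1,
                     nrow = n)
  if (config$n_inactive > 0) {
    for (i in (nF + nM + 1):n) {
      k <- sample(0:3, 1)
      activity[i, ] <- FALSE
      if (k > 0) activity[i, sample(config$n_weeks, k)] <- TRUE
    }
  }

  # traits: Normal(0,1) for women, Normal(effect,1) for men
  traits <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (tr in names(config$trait_effects)) {
    mu <- ifelse(genders == "M", config$trait_effects[[tr]], 0)
    traits[[tr]] <- rnorm(n, mean = mu, sd = 1)
  }

  # person-level parameters drawn around the gender means; without this
  # heterogeneity every planted gender gap becomes a degenerate separator
  het <- config$person_heterogeneity
  gm_unique <- vapply(genders, function(g)
    config$location_profile[[g]]$mean_unique, numeric(1))
  gm_conc <- vapply(genders, function(g)
    config$location_profile[[g]]$concentration, numeric(1))
  p_unique <- pmax(2, rnorm(n, gm_unique, het$sd_unique))
  p_conc <- exp(rnorm(n, log(gm_conc), het$sdlog_concentration))
  # interaction-activity multiplier, mean 1 on the natural scale
  p_act <- rlnorm(n, -het$sdlog_activity^2 / 2, het$sdlog_activity)

  # weekly location distributions: symmetric Dirichlet via gamma draws
  loc_id <- character(0); loc_week <- integer(0)
  loc_lab <- character(0); loc_frac <- numeric(0)
  for (i in seq_len(n)) {
    for (w in weeks) {
      if (!activity[i, w + 1]) next
      L <- max(1L, rpois(1, p_unique[i]))
      gam <- rgamma(L, shape = p_conc[i])
      if (sum(gam) == 0) gam <- rep(1, L)
      loc_id <- c(loc_id, rep(ids[i], L))
      loc_week <- c(loc_week, rep(w, L))
      loc_lab <- c(loc_lab, sprintf("%s_loc%02d", ids[i], seq_len(L)))
      loc_frac <- c(loc_frac, gam / sum(gam))
    }
  }
  locations <- data.frame(id = loc_id, week = loc_week,
                          location_id = loc_lab, time_fraction = loc_frac,
                          stringsAsFactors = FALSE)

  # all unordered dyads, typed by gender composition
  pair_idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pi_ <- pair_idx[, 1]; pj <- pair_idx[, 2]
  same_pair <- genders[pi_] == genders[pj]

  rec <- list()
  for (ch in names(config$channel_profiles)) {
    prof <- config$channel_profiles[[ch]]
    d <- prof$density; h <- prof$homophily
    for (w in weeks) {
      act <- activity[, w + 1]
      mask <- act[pi_] & act[pj]
      if (!any(mask)) next
      q <- mean(same_pair[mask])
      norm <- q * (1 + h) + (1 - q) * (1 - h)
      p_edge <- ifelse(same_pair[mask], d * (1 + h) / norm,
                       d * (1 - h) / norm)
      if (any(p_edge > 1))
        stop("infeasible density/homophily combination for channel ", ch)
      # personal activity multipliers (mean 1) spread degrees within gender
      p_edge <- pmin(1, p_edge * p_act[pi_[mask]] * p_act[pj[mask]])
      hit <- rbinom(sum(mask), 1, p_edge) == 1
      if (!any(hit)) next
      src <- ids[pi_[mask][hit]]
      tgt <- ids[pj[mask][hit]]
      if (ch == "call") {
        n_ev <- 1L + rpois(length(src), prof$weight_mean)
        src <- rep(src, n_ev); tgt <- rep(tgt, n_ev)
        init_src <- runif(length(src)) < 0.5
        gi <- ifelse(init_src, genders[match(src, ids)],
                     genders[match(tgt, ids)])
        gr <- ifelse(init_src, genders[match(tgt, ids)],
                     genders[match(src, ids)])
        key <- paste0(gi, gr)
        mu_s <- prof$duration_means[key]
        sdl <- prof$duration_sdlog
        dur <- rlnorm(length(src), meanlog = log(mu_s) - sdl^2 / 2,
                      sdlog = sdl)
        rec[[length(rec) + 1L]] <- data.frame(
          channel = ch, week = w, source = src, target = tgt,
          weight = 1L, duration_s = dur, initiator_is_source = init_src,
          stringsAsFactors = FALSE)
      } else {
        wts <- 1L + rpois(length(src), prof$weight_mean)
        init_src <- if (ch == "text") runif(length(src)) < 0.5 else NA
        rec[[length(rec) + 1L]] <- data.frame(
          channel = ch, week = w, source = src, target = tgt,
          weight = wts, duration_s = NA_real_,
          initiator_is_source = init_src, stringsAsFactors = FALSE)
      }
    }
  }
  interactions <- if (length(rec) > 0) do.call(rbind, rec) else
    data.frame(channel = character(0), week = integer(0),
               source = character(0), target = character(0),
               weight = integer(0), duration_s = numeric(0),
               initiator_is_source = logical(0))

  # per-category MCAR masks applied to the raw tables
  miss <- matrix(runif(n * length(FEATURE_CATEGORIES)) <
                   config$missing_rate,
                 nrow = n, dimnames = list(ids, FEATURE_CATEGORIES))
  if (any(miss[, "personality"]))
    traits[miss[, "personality"],
           names(config$trait_effects)] <- NA_real_
  if (any(miss[, "location"]))
    locations <- locations[!(locations$id %in% ids[miss[, "location"]]), ,
                           drop = FALSE]
  drop_channels <- list(call = c("call", "text"),
                        facebook = c("facebook_friend",
                                     "facebook_interaction"),
                        person_to_person = "proximity")
  for (cat in names(drop_channels)) {
    gone <- ids[miss[, cat]]
    if (length(gone) > 0 && nrow(interactions) > 0)
      interactions <- interactions[
        !(interactions$channel %in% drop_channels[[cat]] &
            (interactions$source %in% gone |
               interactions$target %in% gone)), , drop = FALSE]
  }

  participants <- data.frame(id = ids, gender = genders,
                             stringsAsFactors = FALSE)
  active <- compute_active_weeks(ids, weeks, interactions, locations)
  coh <- cohort(participants, weeks, active)
  networks <- setNames(lapply(CHANNELS, function(ch)
    aggregate_weekly(interactions, ch, coh)), CHANNELS)

  truth <- list(
    seed = config$seed, n_female = nF, n_male = nM,
    n_weeks = config$n_weeks,
    trait_effects = as.list(config$trait_effects),
    homophily = lapply(config$channel_profiles, `[[`, "homophily"),
    density = lapply(config$channel_profiles, `[[`, "density"),
    expected_same_gender_fraction = lapply(
      config$channel_profiles, function(p)
        expected_same_gender_fraction(nF, nM, p$homophily)),
    missing_rate = config$missing_rate,
    n_masked_by_category = as.list(colSums(miss)))

  list(cohort = coh, networks = networks, interactions = interactions,
       locations = locations, traits = traits,
       missing_categories = miss, truth = truth, config = config)
}

#' Serialize a generated cohort to a fixture directory
#'
#' Writes `participants.csv`, `interactions.csv`, `locations.csv`,
#' `traits.csv`, `config.yaml` and `truth.json` in the CSV dialects that
#' [read_cohort()] consumes; the written fixture round-trips through
#' `read_cohort()`.
#'
#' @param model output of [generate()].
#' @param dir target directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixture <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "interactions.csv",
                            "locations.csv", "traits.csv", "config.yaml",
                            "truth.json"))
  utils::write.csv(model$cohort$participants, paths[1], row.names = FALSE)
  utils::write.csv(model$interactions, paths[2], row.names = FALSE,
                   na = "")
  utils::write.csv(model$locations, paths[3], row.names = FALSE)
  utils::write.csv(model$traits, paths[4], row.names = FALSE, na = "")
  yaml::write_yaml(list(n_weeks = model$config$n_weeks,
                        min_active_weeks = 4L,
                        seed = model$config$seed), paths[5])
  jsonlite::write_json(model$truth, paths[6], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
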