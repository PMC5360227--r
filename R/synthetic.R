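# Synthetic focal-sampling data generator.
#
# The default troop emulates a 25-subject olive-baboon study group: 3 adult
# males, 7 adult females, 4 subadult females, 1 subadult male, 8 juvenile
# males and 2 juvenile females, observed for ~8 focal hours each
# (SD 0.52 h). Interactions are generated dyad by dyad: grooming bout
# counts and aggression counts are Poisson in (rate x dyad focal hours x
# class multipliers); grooming bout durations are lognormal. The class
# multipliers plant the qualitative signal the analyses are designed to
# detect: juveniles groom many partners briefly and receive aggression
# often, adults initiate aggression, females do most of the grooming, and
# adult males and juveniles rarely interact. Baseline rates are calibrated
# so a default troop yields roughly 320 grooming bouts and 270 agonistic
# events in expectation (a sanity anchor, not a fitted quantity).

#' Troop configuration
#'
#' @param composition named integer vector of age-sex class counts. The
#'   default reproduces the canonical 25-subject study composition.
#' @param focal_hours_mean mean focal hours per individual (default 8 h).
#' @param focal_hours_sd SD of focal hours (default 0.52 h).
#' @return a `troop_config` list.
#' @export
troop_config <- function(composition = c(adult_male = 3, adult_female = 7,
                                         subadult_female = 4,
                                         subadult_male = 1,
                                         juvenile_male = 8,
                                         juvenile_female = 2),
                         focal_hours_mean = 8, focal_hours_sd = 0.52) {
  if (any(composition < 0) || any(composition != round(composition)))
    stop("composition counts must be non-negative integers")
  if (sum(composition) < 4) stop("troop must have at least 4 individuals")
  if (focal_hours_sd < 0) stop("focal_hours_sd must be >= 0")
  if (focal_hours_mean <= 0) stop("focal_hours_mean must be positive")
  known <- c("adult_male", "adult_female", "subadult_male",
             "subadult_female", "juvenile_male", "juvenile_female")
  bad <- setdiff(names(composition), known)
  if (length(bad)) stop("unknown age-sex class(es): ",
                        paste(bad, collapse = ", "))
  structure(list(composition = composition,
                 focal_hours_mean = focal_hours_mean,
                 focal_hours_sd = focal_hours_sd),
            class = "troop_config")
}

#' Baseline interaction rates
#'
#' Rates are per ordered dyad and per dyad focal hour. `grooming_rate` is
#' in bouts per dyad-hour, `aggression_rate` in events per dyad-hour;
#' `bout_mean_s` is the mean grooming bout duration in seconds and
#' `bout_sdlog` the lognormal dispersion of durations. Defaults give a
#' default-composition troop ~320 grooming bouts and ~270 agonistic events
#' in expectation.
#'
#' @param grooming_rate baseline grooming bouts per dyad-hour.
#' @param bout_mean_s mean grooming bout duration (s).
#' @param bout_sdlog lognormal sdlog of bout durations.
#' @param aggression_rate baseline agonistic events per dyad-hour.
#' @return a `rate_matrix` list.
#' @export
rate_matrix <- function(grooming_rate = 0.0235, bout_mean_s = 150,
                        bout_sdlog = 0.8, aggression_rate = 0.014) {
  if (grooming_rate < 0 || aggression_rate < 0)
    stop("rates must be >= 0")
  if (bout_mean_s <= 0 || bout_sdlog < 0)
    stop("bout duration parameters must be positive")
  structure(list(grooming_rate = grooming_rate, bout_mean_s = bout_mean_s,
                 bout_sdlog = bout_sdlog, aggression_rate = aggression_rate),
            class = "rate_matrix")
}

#' Class-structured effect multipliers
#'
#' Multipliers (> 0, with 1 = no effect) applied to the baseline rates:
#'
#' * `juvenile_outreach` — juvenile actors start more grooming bouts, each
#'   proportionally shorter (many partners, briefly).
#' * `juvenile_grooming_received` — grooming directed at juveniles is rarer
#'   (juveniles are groomed by few partners, chiefly their mothers).
#' * `juvenile_aggression_received` — juvenile recipients attract more
#'   aggression.
#' * `adult_aggression_initiated` — adult actors initiate more aggression.
#' * `female_grooming_dominance` — female actors groom more.
#' * `male_juvenile_avoidance` — both grooming and aggression between adult
#'   males and juveniles (either direction) are rarer.
#'
#' `effect_profile()` with no arguments is the planted ("paper-like")
#' signal; `null_effect_profile()` sets every multiplier to 1.
#'
#' @param juvenile_outreach,juvenile_grooming_received,juvenile_aggression_received,adult_aggression_initiated,female_grooming_dominance,male_juvenile_avoidance
#'   positive multipliers.
#' @return an `effect_profile` list.
#' @export
effect_profile <- function(juvenile_outreach = 2,
                           juvenile_grooming_received = 0.4,
                           juvenile_aggression_received = 2,
                           adult_aggression_initiated = 2.5,
                           female_grooming_dominance = 2,
                           male_juvenile_avoidance = 0.25) {
  vals <- c(juvenile_outreach = juvenile_outreach,
            juvenile_grooming_received = juvenile_grooming_received,
            juvenile_aggression_received = juvenile_aggression_received,
            adult_aggression_initiated = adult_aggression_initiated,
            female_grooming_dominance = female_grooming_dominance,
            male_juvenile_avoidance = male_juvenile_avoidance)
  if (any(vals <= 0)) stop("effect multipliers must be positive")
  structure(as.list(vals), class = "effect_profile")
}

#' @rdname effect_profile
#' @export
null_effect_profile <- function() {
  effect_profile(1, 1, 1, 1, 1, 1)
}

#' Generate a roster
#'
#' Individuals get sequential ids prefixed by class (e.g. `AF1`, `JM3`)
#' and are all study subjects.
#'
#' @param config a [troop_config()].
#' @return a roster.
#' @export
generate_roster <- function(config = troop_config()) {
  stopifnot(inherits(config, "troop_config"))
  comp <- config$composition
  prefix <- c(adult_male = "AM", adult_female = "AF", subadult_male = "SM",
              subadult_female = "SF", juvenile_male = "JM",
              juvenile_female = "JF")
  rows <- lapply(names(comp), function(cl) {
    k <- comp[[cl]]
    if (k == 0) return(NULL)
    parts <- strsplit(cl, "_")[[1]]
    data.frame(id = paste0(prefix[[cl]], seq_len(k)),
               sex = parts[2], age_class = parts[1],
               is_study_subject = TRUE, stringsAsFactors = FALSE)
  })
  as_roster(do.call(rbind, rows))
}

#' Generate observation effort
#'
#' Focal hours per individual are drawn from a normal distribution
#' truncated to positive values (non-positive draws are redrawn).
#'
#' @param roster a roster.
#' @param config a [troop_config()] supplying mean and SD.
#' @param seed integer seed.
#' @return named numeric vector of focal hours.
#' @export
generate_effort <- function(roster, config = troop_config(), seed = NULL) {
  roster <- as_roster(roster)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(roster)
  h <- stats::rnorm(n, config$focal_hours_mean, config$focal_hours_sd)
  while (any(h <= 0))
    h[h <= 0] <- stats::rnorm(sum(h <= 0), config$focal_hours_mean,
                              config$focal_hours_sd)
  as_effort(stats::setNames(h, roster$id))
}

groom_rate_multiplier <- function(actor_cls, recip_cls, eff) {
  m <- rep(1, length(actor_cls))
  m[grepl("^juvenile", actor_cls)] <-
    m[grepl("^juvenile", actor_cls)] * eff$juvenile_outreach
  m[grepl("female$", actor_cls)] <-
    m[grepl("female$", actor_cls)] * eff$female_grooming_dominance
  m[grepl("^juvenile", recip_cls)] <-
    m[grepl("^juvenile", recip_cls)] * eff$juvenile_grooming_received
  am_juv <- (actor_cls == "adult_male" & grepl("^juvenile", recip_cls)) |
    (recip_cls == "adult_male" & grepl("^juvenile", actor_cls))
  m[am_juv] <- m[am_juv] * eff$male_juvenile_avoidance
  m
}

aggr_rate_multiplier <- function(actor_cls, recip_cls, eff) {
  m <- rep(1, length(actor_cls))
  m[grepl("^adult", actor_cls)] <-
    m[grepl("^adult", actor_cls)] * eff$adult_aggression_initiated
  m[grepl("^juvenile", recip_cls)] <-
    m[grepl("^juvenile", recip_cls)] * eff$juvenile_aggression_received
  am_juv <- (actor_cls == "adult_male" & grepl("^juvenile", recip_cls)) |
    (recip_cls == "adult_male" & grepl("^juvenile", actor_cls))
  m[am_juv] <- m[am_juv] * eff$male_juvenile_avoidance
  m
}

#' Generate interaction events
#'
#' For every ordered dyad, grooming bout counts are Poisson with mean
#' `grooming_rate x (hours(i) + hours(j)) x multipliers`, bout durations
#' lognormal with the configured mean (juvenile actors' durations are
#' divided by `juvenile_outreach`, so outreach redistributes rather than
#' inflates grooming time), and aggression counts are Poisson with mean
#' `aggression_rate x dyad hours x multipliers`. Start times are uniform
#' over the pooled focal time and events are returned sorted by
#' (actor, recipient, start time), grooming first.
#'
#' @param roster a roster.
#' @param effort named focal-hours vector.
#' @param rates a [rate_matrix()].
#' @param effects an [effect_profile()].
#' @param seed integer seed.
#' @return event data frame (see [as_events()]).
#' @export
generate_events <- function(roster, effort, rates = rate_matrix(),
                            effects = effect_profile(), seed = NULL) {
  roster <- as_roster(roster)
  effort <- as_effort(effort, roster)
  stopifnot(inherits(rates, "rate_matrix"),
            inherits(effects, "effect_profile"))
  if (!is.null(seed)) set.seed(seed)
  ids <- study_subjects(roster)$id
  cls <- age_sex_class(roster)
  pairs <- expand.grid(actor = ids, recipient = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$actor != pairs$recipient, , drop = FALSE]
  dyad_h <- effort[pairs$actor] + effort[pairs$recipient]
  a_cls <- unname(cls[pairs$actor])
  r_cls <- unname(cls[pairs$recipient])
  session_s <- sum(effort) * 3600
  # grooming
  g_mean <- rates$grooming_rate * dyad_h *
    groom_rate_multiplier(a_cls, r_cls, effects)
  g_counts <- stats::rpois(nrow(pairs), g_mean)
  g_idx <- rep(seq_len(nrow(pairs)), g_counts)
  groom <- NULL
  if (length(g_idx)) {
    dur_mean <- rates$bout_mean_s /
      ifelse(grepl("^juvenile", a_cls[g_idx]), effects$juvenile_outreach, 1)
    meanlog <- log(dur_mean) - rates$bout_sdlog^2 / 2
    groom <- data.frame(actor = pairs$actor[g_idx],
                        recipient = pairs$recipient[g_idx],
                        behaviour = "grooming",
                        start_time_s = stats::runif(length(g_idx), 0,
                                                    session_s),
                        duration_s = stats::rlnorm(length(g_idx), meanlog,
                                                   rates$bout_sdlog),
                        stringsAsFactors = FALSE)
  }
  # aggression
  a_mean <- rates$aggression_rate * dyad_h *
    aggr_rate_multiplier(a_cls, r_cls, effects)
  a_counts <- stats::rpois(nrow(pairs), a_mean)
  a_idx <- rep(seq_len(nrow(pairs)), a_counts)
  aggr <- NULL
  if (length(a_idx)) {
    aggr <- data.frame(actor = pairs$actor[a_idx],
                       recipient = pairs$recipient[a_idx],
                       behaviour = "aggression",
                       start_time_s = stats::runif(length(a_idx), 0,
                                                   session_s),
                       duration_s = NA_real_, stringsAsFactors = FALSE)
  }
  ev <- rbind(groom, aggr)
  if (is.null(ev))
    return(as_events(data.frame(actor = character(), recipient = character(),
                                behaviour = character(),
                                start_time_s = numeric(),
                                duration_s = numeric())))
  ev <- ev[order(ev$behaviour != "grooming", ev$actor, ev$recipient,
                 ev$start_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  as_events(ev, roster)
}

#' Generate a complete study dataset
#'
#' Composes [generate_roster()], [generate_effort()] and
#' [generate_events()]; byte-identical output for identical
#' (config, rates, effects, seed).
#'
#' @param config a [troop_config()].
#' @param rates a [rate_matrix()].
#' @param effects an [effect_profile()].
#' @param seed integer seed.
#' @return list with elements `roster`, `effort`, `events`.
#' @export
generate_study_dataset <- function(config = troop_config(),
                                   rates = rate_matrix(),
                                   effects = effect_profile(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roster <- generate_roster(config)
  effort <- generate_effort(roster, config)
  events <- generate_events(roster, effort, rates, effects)
  list(roster = roster, effort = effort, events = events)
}
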