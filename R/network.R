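#' @keywords internal
"_PACKAGE"

AGE_CLASSES <- c("juvenile", "subadult", "adult")
SEXES <- c("male", "female")
BEHAVIOURS <- c("grooming", "aggression")

#' Validate and normalise a troop roster
#'
#' A roster is a data frame with one row per individual and columns `id`
#' (unique character), `sex` (`"male"`/`"female"`), `age_class`
#' (`"juvenile"`/`"subadult"`/`"adult"`) and `is_study_subject` (logical).
#' Individuals that are not study subjects (e.g. unhabituated animals) are
#' retained in the roster but never enter a network.
#'
#' @param x data frame with columns `id`, `sex`, `age_class`,
#'   `is_study_subject` (the latter defaults to `TRUE` if absent).
#' @return the validated roster with class `troop_roster` prepended.
#' @export
as_roster <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age_class")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) stop("roster must be non-empty")
  x$id <- as.character(x$id)
  dup <- x$id[duplicated(x$id)]
  if (length(dup))
    stop("duplicate roster id(s): ", paste(unique(dup), collapse = ", "),
         " (row ", paste(which(duplicated(x$id)), collapse = ", "), ")")
  bad <- which(!x$sex %in% SEXES)
  if (length(bad))
    stop("invalid sex at roster row ", bad[1], ": '", x$sex[bad[1]], "'")
  bad <- which(!x$age_class %in% AGE_CLASSES)
  if (length(bad))
    stop("invalid age_class at roster row ", bad[1], ": '", x$age_class[bad[1]], "'")
  if (is.null(x$is_study_subject)) x$is_study_subject <- TRUE
  x$is_study_subject <- as.logical(x$is_study_subject)
  if (anyNA(x$is_study_subject)) stop("is_study_subject must be TRUE/FALSE")
  class(x) <- c("troop_roster", "data.frame")
  x
}

#' Age-sex class labels
#'
#' Combines age class and sex into the labels used throughout the analyses,
#' e.g. `"adult_female"`.
#'
#' @param roster a roster (see [as_roster()]).
#' @return character vector of class labels, named by individual id.
#' @export
age_sex_class <- function(roster) {
  roster <- as_roster(roster)
  stats::setNames(paste(roster$age_class, roster$sex, sep = "_"), roster$id)
}

#' Study subjects of a roster
#' @param roster a roster.
#' @return the subset of rows with `is_study_subject == TRUE`.
#' @export
study_subjects <- function(roster) {
  roster <- as_roster(roster)
  roster[roster$is_study_subject, , drop = FALSE]
}

#' Validate an interaction event table
#'
#' Events record one dyadic behaviour each: `actor`, `recipient`,
#' `behaviour` (`"grooming"` or `"aggression"`), `start_time_s` (seconds
#' since session start; optional for aggression) and `duration_s` (grooming
#' only; `NA` for aggression, which carries an implicit count of 1).
#'
#' @param x data frame of events.
#' @param roster optional roster; when given, actor/recipient ids must be
#'   known study subjects.
#' @return validated event data frame.
#' @export
as_events <- function(x, roster = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("actor", "recipient", "behaviour"))
    if (is.null(x[[col]])) stop("events are missing column '", col, "'")
  if (is.null(x$start_time_s)) x$start_time_s <- NA_real_
  if (is.null(x$duration_s)) x$duration_s <- NA_real_
  x$actor <- as.character(x$actor)
  x$recipient <- as.character(x$recipient)
  x$start_time_s <- as.numeric(x$start_time_s)
  x$duration_s <- as.numeric(x$duration_s)
  bad <- which(!x$behaviour %in% BEHAVIOURS)
  if (length(bad))
    stop("invalid behaviour at event row ", bad[1], ": '", x$behaviour[bad[1]], "'")
  bad <- which(x$actor == x$recipient)
  if (length(bad))
    stop("self-interaction at event row ", bad[1], " (id '", x$actor[bad[1]], "')")
  groom <- x$behaviour == "grooming"
  bad <- which(groom & (is.na(x$duration_s) | x$duration_s < 0))
  if (length(bad))
    stop("grooming event at row ", bad[1], " lacks a non-negative duration_s")
  if (!is.null(roster)) {
    known <- study_subjects(roster)$id
    unknown <- setdiff(unique(c(x$actor, x$recipient)), known)
    if (length(unknown))
      stop("event id(s) not found among study subjects: ",
           paste(unknown, collapse = ", "))
  }
  x[, c("actor", "recipient", "behaviour", "start_time_s", "duration_s")]
}

#' Validate an observation-effort table
#'
#' @param x data frame with columns `id` and `hours`, or a named numeric
#'   vector of focal hours.
#' @param roster optional roster; when given, every study subject must have
#'   a positive number of focal hours.
#' @return named numeric vector of focal hours.
#' @export
as_effort <- function(x, roster = NULL) {
  if (is.data.frame(x)) {
    if (is.null(x$id) || is.null(x$hours))
      stop("effort table needs columns 'id' and 'hours'")
    h <- stats::setNames(as.numeric(x$hours), as.character(x$id))
  } else {
    h <- x
    if (is.null(names(h))) stop("effort vector must be named by individual id")
    storage.mode(h) <- "double"
  }
  if (anyDuplicated(names(h)))
    stop("duplicate id(s) in effort table: ",
         paste(unique(names(h)[duplicated(names(h))]), collapse = ", "))
  if (any(is.na(h) | h <= 0))
    stop("focal hours must be positive; offending id(s): ",
         paste(names(h)[is.na(h) | h <= 0], collapse = ", "))
  if (!is.null(roster)) {
    miss <- setdiff(study_subjects(roster)$id, names(h))
    if (length(miss))
      stop("no focal hours recorded for study subject(s): ",
           paste(miss, collapse = ", "))
  }
  h
}

#' Merge interrupted grooming bouts
#'
#' Consecutive grooming records of the same directed dyad separated by a gap
#' of at most `gap_s` seconds are merged into a single bout whose duration is
#' the sum of the component durations (gap time is not groomed time). A
#' change of partner or of grooming direction always starts a new bout, as
#' does a gap longer than the threshold.
#'
#' @param events grooming events, sorted by (actor, recipient, start_time_s).
#' @param gap_s maximum interruption, in seconds, bridged within one bout
#'   (default 30 s).
#' @return merged event data frame in the same layout.
#' @export
merge_grooming_bouts <- function(events, gap_s = 30) {
  events <- as_events(events)
  if (any(events$behaviour != "grooming"))
    stop("merge_grooming_bouts() accepts grooming events only")
  if (nrow(events) < 2L) return(events)
  if (anyNA(events$start_time_s))
    stop("grooming events need start_time_s for bout merging")
  key_now <- paste(events$actor, events$recipient)
  o <- order(key_now, events$start_time_s)
  if (any(o != seq_len(nrow(events))))
    stop("events must be sorted by (actor, recipient, start_time_s)")
  same_dyad <- c(FALSE, key_now[-1] == key_now[-nrow(events)])
  gap <- c(Inf, events$start_time_s[-1] -
             (events$start_time_s[-nrow(events)] + events$duration_s[-nrow(events)]))
  new_bout <- !(same_dyad & gap <= gap_s)
  bout <- cumsum(new_bout)
  out <- events[new_bout, , drop = FALSE]
  out$duration_s <- as.numeric(tapply(events$duration_s, bout, sum))
  rownames(out) <- NULL
  out
}

# ---- network container ------------------------------------------------------

new_social_network <- function(adj, roster, behaviour, directed = TRUE) {
  structure(
    list(adj = adj, roster = roster, behaviour = behaviour,
         directed = directed),
    class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  n <- nrow(x$adj)
  ties <- sum(x$adj > 0)
  if (!x$directed) ties <- ties / 2
  cat(sprintf("<social_network> %s, %s, %d nodes, %d ties\n",
              x$behaviour, if (x$directed) "directed" else "symmetrised",
              n, as.integer(ties)))
  invisible(x)
}

#' Node ids of a network
#' @param net a `social_network`.
#' @return character vector of node ids.
#' @export
network_ids <- function(net) rownames(net$adj)

#' Number of nodes
#' @param net a `social_network`.
#' @export
network_size <- function(net) nrow(net$adj)

rate_denominator <- function(ids, effort, normalization) {
  n <- length(ids)
  h <- effort[ids]
  H <- switch(normalization,
    dyad_hours  = outer(h, h, "+"),
    actor_hours = matrix(h, n, n),
    total_hours = matrix(sum(effort), n, n),
    stop("unknown normalization '", normalization, "'"))
  dimnames(H) <- list(ids, ids)
  if (any(H <= 0)) stop("non-positive rate denominator")
  H
}

build_network <- function(events, effort, roster, behaviour, normalization) {
  roster <- as_roster(roster)
  subjects <- study_subjects(roster)
  events <- as_events(events, roster)
  effort <- as_effort(effort, roster)
  if (any(events$behaviour != behaviour))
    stop("all events must have behaviour '", behaviour, "'")
  ids <- subjects$id
  n <- length(ids)
  amount <- if (behaviour == "grooming") events$duration_s else
    rep(1, nrow(events))
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(events)) {
    totals <- tapply(amount, paste(events$actor, events$recipient), sum)
    keys <- do.call(rbind, strsplit(names(totals), " ", fixed = TRUE))
    adj[cbind(match(keys[, 1], ids), match(keys[, 2], ids))] <- as.numeric(totals)
  }
  H <- rate_denominator(ids, effort, normalization)
  adj <- adj / H
  new_social_network(adj, subjects, behaviour, directed = TRUE)
}

#' Build the grooming network
#'
#' Edge weights are grooming seconds per hour: total seconds `i` groomed `j`
#' divided by the focal-hour denominator `H` chosen by `normalization`
#' (default `"dyad_hours"`, `H = hours(i) + hours(j)`, the joint exposure of
#' the dyad under focal sampling; `"actor_hours"` uses `hours(i)` and
#' `"total_hours"` the summed focal hours of all subjects). Dyads with no
#' observed grooming carry weight 0 (no edge); isolated study subjects are
#' retained as zero-degree nodes.
#'
#' @param events merged grooming bouts (see [merge_grooming_bouts()]).
#' @param effort focal-hours table or named vector (see [as_effort()]).
#' @param roster the troop roster.
#' @param normalization one of `"dyad_hours"`, `"actor_hours"`,
#'   `"total_hours"`.
#' @return a directed, weighted `social_network`.
#' @export
build_grooming_network <- function(events, effort, roster,
                                   normalization = c("dyad_hours",
                                                     "actor_hours",
                                                     "total_hours")) {
  build_network(events, effort, roster, "grooming", match.arg(normalization))
}

#' Build the aggression network
#'
#' Edge weights are agonistic events per hour: the count of aggressive acts
#' `i -> j` divided by the same focal-hour denominator as
#' [build_grooming_network()]. Durations are ignored (agonistic acts are
#' short and carry an implicit count of 1).
#'
#' @inheritParams build_grooming_network
#' @param events aggression events.
#' @return a directed, weighted `social_network`.
#' @export
build_aggression_network <- function(events, effort, roster,
                                     normalization = c("dyad_hours",
                                                       "actor_hours",
                                                       "total_hours")) {
  build_network(events, effort, roster, "aggression", match.arg(normalization))
}

#' Symmetrise a directed network
#'
#' Adds up the weights of the two directions of every dyad,
#' `w_sym(i, j) = w(i -> j) + w(j -> i)`. An already symmetrised network is
#' returned unchanged (idempotent). Used for total degree and all clustering
#' computations.
#'
#' @param net a `social_network`.
#' @return the undirected-equivalent network.
#' @export
symmetrise <- function(net) {
  stopifnot(inherits(net, "social_network"))
  if (!net$directed) return(net)
  net$adj <- net$adj + t(net$adj)
  net$directed <- FALSE
  net
}

#' Induced subnetwork after node removal
#'
#' Deletes nodes and all incident edges; surviving weights are unchanged
#' (hourly rates are dyad-level and independent of group size).
#'
#' @param net a `social_network`.
#' @param remove_ids ids to delete.
#' @return the reduced `social_network`.
#' @export
remove_nodes <- function(net, remove_ids) {
  stopifnot(inherits(net, "social_network"))
  unknown <- setdiff(remove_ids, network_ids(net))
  if (length(unknown))
    stop("cannot remove unknown id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(network_ids(net), remove_ids)
  net$adj <- net$adj[keep, keep, drop = FALSE]
  net$roster <- net$roster[match(keep, net$roster$id), , drop = FALSE]
  net
}

#' Construct a network directly from an edge list
#'
#' Mainly for tests and small worked examples; weights are taken as given
#' (no rate normalisation).
#'
#' @param edges data frame with columns `source`, `target`, `weight`.
#' @param ids node ids (defaults to those appearing in `edges`).
#' @param roster optional roster supplying age-sex attributes.
#' @param behaviour label for the network.
#' @param directed logical.
#' @return a `social_network`.
#' @export
edgelist_network <- function(edges, ids = NULL, roster = NULL,
                             behaviour = "grooming", directed = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(edges$source, edges$target)))
  ids <- as.character(ids)
  if (!is.null(roster)) {
    roster <- study_subjects(roster)
    ids <- roster$id
  } else {
    roster <- as_roster(data.frame(id = ids, sex = "female",
                                   age_class = "adult",
                                   is_study_subject = TRUE))
  }
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(edges)) {
    if (any(edges$weight <= 0)) stop("edge weights must be positive")
    adj[cbind(match(as.character(edges$source), ids),
              match(as.character(edges$target), ids))] <- edges$weight
    if (!directed) adj <- pmax(adj, t(adj))
  }
  new_social_network(adj, roster, behaviour, directed)
}
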