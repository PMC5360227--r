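# Plain-text I/O. All tables are comma-separated with a header row:
#   roster.csv : id,sex,age_class,is_study_subject
#   effort.csv : id,hours
#   events.csv : actor,recipient,behaviour,start_time_s,duration_s
#   network    : source,target,weight edge list (weights are hourly rates)

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read a roster file
#' @param path CSV with columns id, sex, age_class, is_study_subject.
#' @return a validated roster.
#' @export
read_roster <- function(path) {
  as_roster(read_table_checked(path, c("id", "sex", "age_class")))
}

#' Read an observation-effort file
#' @param path CSV with columns id, hours.
#' @param roster optional roster for completeness checks.
#' @return named numeric vector of focal hours.
#' @export
read_effort <- function(path, roster = NULL) {
  as_effort(read_table_checked(path, c("id", "hours")), roster)
}

#' Read an interaction-event file
#' @param path CSV with columns actor, recipient, behaviour, start_time_s,
#'   duration_s (duration empty for aggression).
#' @param roster optional roster; event ids must then be study subjects.
#' @return validated event data frame.
#' @export
read_events <- function(path, roster = NULL) {
  as_events(read_table_checked(path, c("actor", "recipient", "behaviour")),
            roster)
}

#' Write a roster / effort / event table
#' @param x object to serialise.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(x, path) {
  utils::write.csv(as.data.frame(as_roster(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
write_effort <- function(x, path) {
  h <- as_effort(x)
  utils::write.csv(data.frame(id = names(h), hours = unname(h)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
write_events <- function(x, path) {
  utils::write.csv(as_events(x), path, row.names = FALSE)
  invisible(path)
}

#' Export a network as a weighted edge list
#'
#' Writes one row per (ordered, for directed networks) dyad with a positive
#' weight: `source,target,weight`. [read_network()] reproduces the network
#' exactly given the same roster.
#'
#' @param net a `social_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "social_network"))
  idx <- which(net$adj > 0, arr.ind = TRUE)
  if (!net$directed) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  el <- data.frame(source = rownames(net$adj)[idx[, 1]],
                   target = colnames(net$adj)[idx[, 2]],
                   weight = net$adj[idx])
  el <- el[order(el$source, el$target), , drop = FALSE]
  utils::write.csv(el, path, row.names = FALSE)
  invisible(path)
}

#' Read a network from a weighted edge list
#' @param path edge-list CSV written by [write_network()].
#' @param roster roster defining the node set (isolates included).
#' @param behaviour network label.
#' @param directed logical; must match how the file was written.
#' @return a `social_network`.
#' @export
read_network <- function(path, roster, behaviour = "grooming",
                         directed = TRUE) {
  el <- read_table_checked(path, c("source", "target", "weight"))
  edgelist_network(el, roster = roster, behaviour = behaviour,
                   directed = directed)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a network as GraphML
#'
#' Minimal GraphML writer with node attributes `sex` and `age_class` and the
#' edge attribute `weight`, readable by igraph, Gephi and friends.
#'
#' @param net a `social_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "social_network"))
  ids <- network_ids(net)
  ro <- net$roster
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  w("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  w("  <key id=\"sex\" for=\"node\" attr.name=\"sex\" attr.type=\"string\"/>")
  w("  <key id=\"age_class\" for=\"node\" attr.name=\"age_class\" attr.type=\"string\"/>")
  w("  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>")
  w("  <graph id=\"%s\" edgedefault=\"%s\">", xml_escape(net$behaviour),
    if (net$directed) "directed" else "undirected")
  for (i in seq_along(ids)) {
    w("    <node id=\"%s\"><data key=\"sex\">%s</data><data key=\"age_class\">%s</data></node>",
      xml_escape(ids[i]), xml_escape(ro$sex[i]), xml_escape(ro$age_class[i]))
  }
  idx <- which(net$adj > 0, arr.ind = TRUE)
  if (!net$directed) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    w("    <edge source=\"%s\" target=\"%s\"><data key=\"weight\">%.15g</data></edge>",
      xml_escape(ids[idx[k, 1]]), xml_escape(ids[idx[k, 2]]),
      net$adj[idx[k, , drop = FALSE]])
  }
  w("  </graph>")
  w("</graphml>")
  invisible(path)
}
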