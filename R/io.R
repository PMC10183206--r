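#' Read an RFID visit log
#'
#' Reads a CSV of time-stamped tag detections at a feeder antenna and returns
#' a validated, time-sorted visit log. Timestamps may be numeric seconds
#' since epoch or ISO-8601 date-times; both are stored internally as numeric
#' seconds (timezone-naive, interpreted as local feeder time). Byte-identical
#' duplicate rows are collapsed and the number removed is reported.
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Named character vector mapping the canonical names
#'   `timestamp`, `tag_id`, `antenna_id` to the file's column names. Defaults
#'   to identity; `antenna_id` is optional and filled with `"A1"` if absent.
#' @return A tibble with columns `timestamp` (numeric seconds), `tag_id`
#'   and `antenna_id`, sorted by timestamp.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,tag_id,antenna_id",
#'              "100,A,F1", "50,B,F1", "100,A,F1"), f)
#' read_visit_log(f)
#' @export
read_visit_log <- function(path,
                           columns = c(timestamp = "timestamp",
                                       tag_id = "tag_id",
                                       antenna_id = "antenna_id")) {
  if (!file.exists(path)) abort(glue::glue("visit log not found: {path}"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn("empty visit log")
    return(tibble::tibble(timestamp = numeric(), tag_id = character(),
                          antenna_id = character()))
  }
  need <- c("timestamp", "tag_id")
  for (nm in need) {
    col <- columns[[nm]] %||% nm
    if (!col %in% names(raw)) abort(glue::glue("column `{col}` ({nm}) missing from {path}"))
  }
  ant_col <- columns[["antenna_id"]] %||% "antenna_id"
  out <- tibble::tibble(
    timestamp = raw[[columns[["timestamp"]] %||% "timestamp"]],
    tag_id = raw[[columns[["tag_id"]] %||% "tag_id"]],
    antenna_id = if (ant_col %in% names(raw)) raw[[ant_col]] else "A1"
  )
  ts <- parse_time(out$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    abort(glue::glue(
      "unparseable timestamp '{out$timestamp[bad]}' at data line {bad} of {path}"))
  }
  out$timestamp <- ts
  if (any(!nzchar(out$tag_id) | is.na(out$tag_id))) {
    abort("empty tag_id in visit log")
  }
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n0) {
    inform(glue::glue("collapsed {n0 - nrow(out)} duplicate detection row(s)"))
  }
  dplyr::arrange(out, .data$timestamp, .data$tag_id)
}

#' Read an individual metadata table
#'
#' @param path CSV with columns `individual_id`, `tag_id` (optional; defaults
#'   to `individual_id`), `sex` (1 = male, 0 = female), `cohort` (birth
#'   year), `death_year` (last year alive; `NA` = still alive / open), and
#'   optionally `first_tagged`.
#' @return A validated tibble, one row per individual.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) abort(glue::glue("individual table not found: {path}"))
  x <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  for (nm in c("individual_id", "sex", "cohort")) {
    if (!nm %in% names(x)) abort(glue::glue("column `{nm}` missing from {path}"))
  }
  x$individual_id <- as.character(x$individual_id)
  if (!"tag_id" %in% names(x)) x$tag_id <- x$individual_id
  if (!"death_year" %in% names(x)) x$death_year <- NA_real_
  validate_individuals(tibble::as_tibble(x))
}

validate_individuals <- function(x) {
  if (anyDuplicated(x$individual_id)) abort("individual_id values must be unique")
  if (!all(x$sex %in% c(0, 1))) abort("sex must be coded 0 (female) / 1 (male)")
  bad <- !is.na(x$death_year) & x$death_year < x$cohort
  if (any(bad)) {
    abort(glue::glue("death_year before cohort for {x$individual_id[which(bad)[1]]}"))
  }
  x
}

#' Read a multi-generational pedigree
#'
#' Validates referential integrity (every named parent is itself a row or is
#' flagged as a founder) and acyclicity (no individual is its own ancestor).
#'
#' @param path CSV with columns `individual_id`, `sire_id`, `dam_id`,
#'   `cohort`. Missing parents are encoded as empty fields or `NA`.
#' @return A tibble with a logical `founder` column (both parents unknown).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(glue::glue("pedigree not found: {path}"))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  for (nm in c("individual_id", "sire_id", "dam_id", "cohort")) {
    if (!nm %in% names(x)) abort(glue::glue("column `{nm}` missing from {path}"))
  }
  x$cohort <- as.numeric(x$cohort)
  x$sire_id[x$sire_id %in% c("", "NA")] <- NA_character_
  x$dam_id[x$dam_id %in% c("", "NA")] <- NA_character_
  validate_pedigree(tibble::as_tibble(x))
}

validate_pedigree <- function(ped) {
  ids <- ped$individual_id
  if (anyDuplicated(ids)) abort("pedigree individual_id values must be unique")
  parents <- stats::na.omit(c(ped$sire_id, ped$dam_id))
  missing <- setdiff(unique(parents), ids)
  if (length(missing) > 0) {
    abort(glue::glue(
      "parent id(s) not present in pedigree and not flagged founders: ",
      "{paste(utils::head(missing, 5), collapse = ', ')}"))
  }
  # acyclicity via depth-first ancestor walk
  sire <- setNames(ped$sire_id, ids)
  dam <- setNames(ped$dam_id, ids)
  state <- setNames(integer(length(ids)), ids) # 0 unseen, 1 active, 2 done
  visit <- function(id, path) {
    if (state[[id]] == 2L) return(invisible())
    if (state[[id]] == 1L) {
      abort(glue::glue("pedigree cycle detected: {paste(c(path, id), collapse = ' -> ')}"))
    }
    state[[id]] <<- 1L
    for (p in c(sire[[id]], dam[[id]])) {
      if (!is.na(p)) visit(p, c(path, id))
    }
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id, character())
  ped$founder <- is.na(ped$sire_id) & is.na(ped$dam_id)
  ped
}

#' Read a dyadic antagonistic-interaction log
#'
#' @param path CSV with columns `timestamp`, `winner_id`, `loser_id`.
#' @return A tibble sorted chronologically; rows with `winner == loser`
#'   raise an error.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort(glue::glue("interaction log not found: {path}"))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  for (nm in c("timestamp", "winner_id", "loser_id")) {
    if (!nm %in% names(x)) abort(glue::glue("column `{nm}` missing from {path}"))
  }
  x$timestamp <- parse_time(x$timestamp)
  if (any(x$winner_id == x$loser_id)) abort("interaction with winner == loser")
  dplyr::arrange(tibble::as_tibble(x), .data$timestamp)
}

#' Write / read a social network
#'
#' Networks round-trip losslessly (vertex set, edge set, weights and vertex
#' attributes) through either a flat edge-list CSV (with a companion vertex
#' block) or GraphML.
#'
#' @param network An `igraph` object with a `weight` edge attribute.
#' @param path Output file path.
#' @param format `"edge_csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("edge_csv", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(network))
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    verts <- igraph::as_data_frame(network, what = "vertices")
    if (ncol(verts) == 0) verts <- data.frame(name = character())
    edges <- igraph::as_data_frame(network, what = "edges")
    if (nrow(edges) == 0) {
      edges <- data.frame(from = character(), to = character(),
                          weight = numeric())
    }
    txt <- c(glue::glue("# flocknet edge_csv v1; vertices={nrow(verts)}"),
             sub("\n$", "", readr::format_csv(verts)),
             "# edges",
             sub("\n$", "", readr::format_csv(edges)))
    writeLines(unlist(strsplit(txt, "\n")), path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edge_csv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(glue::glue("network file not found: {path}"))
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# flocknet edge_csv", hdr)) abort("not a flocknet edge_csv file")
  split_at <- which(lines == "# edges")
  if (split_at < 3) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  vert_txt <- lines[2:(split_at - 1)]
  edge_txt <- lines[(split_at + 1):length(lines)]
  verts <- readr::read_csv(I(paste(vert_txt, collapse = "\n")),
                           col_types = readr::cols(), progress = FALSE)
  has_edges <- length(edge_txt) > 1
  edges <- if (has_edges) {
    readr::read_csv(I(paste(edge_txt, collapse = "\n")),
                    col_types = readr::cols(), progress = FALSE)
  } else {
    tibble::tibble(from = character(), to = character(), weight = numeric())
  }
  if (nrow(verts) == 0) return(igraph::make_empty_graph(directed = FALSE))
  verts$name <- as.character(verts$name)
  if (nrow(edges) > 0) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Write a fitted-model summary to JSON
#'
#' @param result A `flocknet_model` or `flocknet_repeatability` object, or
#'   any list of tibbles/values.
#' @param path Output path.
#' @export
write_model_result <- function(result, path) {
  if (inherits(result, c("flocknet_model", "flocknet_repeatability"))) {
    result <- list(terms = tidy(result), summary = glance(result))
  }
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
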