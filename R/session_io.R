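SCHEMA_VERSION <- 1L

session_csv_columns <- function() {
  c("schema_version", "dog", "phase", "seed",
    "trial_index", "trial_start_ms", "is_blank", "target_port",
    paste0("channel_port", 1:3), "response", "alert_port", "rewarded",
    "latency_ms", paste0("entries_port", 1:3), paste0("sniff_ms_port", 1:3),
    "pokes")
}

#' Write a session CSV
#'
#' Serializes a completed session to the line-up data-output schema: one
#' row per completed trial carrying the odors presented in each port, the
#' trial start time, the latency to first nose entry, per-port entry
#' counts and sniffing durations, the classified response, and a full poke
#' record. Pokes are serialized as semicolon-separated
#' `port:start_ms:duration_ms` triplets (1-based ports). Ports are 1-based
#' throughout the file; a `schema_version` column is included for forward
#' compatibility. Output is RFC-4180 CSV.
#'
#' @param session a `lineup_session`, or a list of `trial_result` (then
#'   `metadata` must be supplied).
#' @param path output file, or an existing directory, in which case the
#'   file is named `<dog>_<ISO8601 timestamp>.csv`.
#' @param metadata list with `dog_name`, `seed`, `phase`,
#'   `trial_start_ms`, `session_time`; taken from the session if omitted.
#' @return the path written, invisibly.
#' @export
write_session_csv <- function(session, path, metadata = NULL) {
  if (inherits(session, "session_record")) {
    # re-serialize a parsed record (write-read-write is byte-stable)
    rows <- session$trials
    rows$target_port <- rows$target_port + 1L
    rows$alert_port <- rows$alert_port + 1L
    rows$pokes <- vapply(session$pokes, serialize_pokes, character(1))
    rows <- rows[session_csv_columns()]
    if (dir.exists(path))
      path <- file.path(path, paste0(session$metadata$dog_name, "_record.csv"))
    utils::write.csv(rows, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  if (inherits(session, "lineup_session")) {
    results <- session$results
    plan <- session$plan
    if (is.null(metadata)) metadata <- session$metadata
  } else {
    results <- session
    plan <- metadata$plan
  }
  if (is.null(metadata))
    stop("metadata required when writing bare results", call. = FALSE)
  if (dir.exists(path)) {
    stamp <- format(metadata$session_time %||% Sys.time(),
                    "%Y-%m-%dT%H%M%S")
    path <- file.path(path, paste0(metadata$dog_name, "_", stamp, ".csv"))
  }
  n <- length(results)
  rows <- if (n == 0L) {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(session_csv_columns())),
                                    session_csv_columns()))
    empty
  } else {
    do.call(rbind, lapply(seq_len(n), function(i) {
      r <- results[[i]]
      sp <- plan[i, ]
      data.frame(
        schema_version = SCHEMA_VERSION,
        dog = metadata$dog_name,
        phase = metadata$phase,
        seed = metadata$seed,
        trial_index = sp$trial_index,
        trial_start_ms = (metadata$trial_start_ms %||% rep(0L, n))[i],
        is_blank = sp$is_blank,
        target_port = if (is.na(sp$target_port)) NA_integer_ else
          sp$target_port + 1L,
        channel_port1 = sp$channel_port1,
        channel_port2 = sp$channel_port2,
        channel_port3 = sp$channel_port3,
        response = r$response,
        alert_port = if (is.na(r$alert_port)) NA_integer_ else
          r$alert_port + 1L,
        rewarded = r$rewarded,
        latency_ms = r$latency_ms,
        entries_port1 = r$entries_by_port[1],
        entries_port2 = r$entries_by_port[2],
        entries_port3 = r$entries_by_port[3],
        sniff_ms_port1 = r$sniff_ms_by_port[1],
        sniff_ms_port2 = r$sniff_ms_by_port[2],
        sniff_ms_port3 = r$sniff_ms_by_port[3],
        pokes = serialize_pokes(r$pokes),
        stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

serialize_pokes <- function(pokes) {
  if (is.null(pokes) || nrow(pokes) == 0L) return("")
  paste(sprintf("%d:%d:%d", pokes$port + 1L, pokes$start_ms,
                pokes$duration_ms), collapse = ";")
}

parse_pokes <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(port = integer(0), start_ms = integer(0),
                      duration_ms = integer(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed poke triplet: ", s, call. = FALSE)
  m <- matrix(as.integer(unlist(parts)), ncol = 3, byrow = TRUE)
  data.frame(port = m[, 1] - 1L, start_ms = m[, 2], duration_ms = m[, 3])
}

#' Read a session CSV
#'
#' Parses a file written by [write_session_csv()] back into typed trial
#' records. Unknown columns are preserved as opaque extras; missing
#' mandatory columns raise a schema error naming the column.
#'
#' @param path the CSV file.
#' @return a `session_record`: list with `trials` (data frame, 0-based
#'   ports, parsed fields), `pokes` (list of per-trial poke data frames),
#'   and `metadata` (dog, phase, seed, schema_version).
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) > 1L && any(nf != nf[1]))
    stop("truncated or malformed row at line ",
         which(nf != nf[1])[1], call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pokes = "character"))
  mandatory <- session_csv_columns()
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("session file missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pokes <- lapply(df$pokes, parse_pokes)
  trials <- df
  trials$target_port <- as.integer(trials$target_port) - 1L
  trials$alert_port <- as.integer(trials$alert_port) - 1L
  trials$is_blank <- as.logical(trials$is_blank)
  trials$rewarded <- as.logical(trials$rewarded)
  metadata <- list(
    dog_name = if (nrow(df)) df$dog[1] else NA_character_,
    phase = if (nrow(df)) df$phase[1] else NA_character_,
    seed = if (nrow(df)) df$seed[1] else NA_integer_,
    schema_version = if (nrow(df)) df$schema_version[1] else SCHEMA_VERSION)
  structure(list(trials = trials, pokes = pokes, metadata = metadata),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session record: %d trials (dog '%s', phase %s, seed %s)\n",
              nrow(x$trials), x$metadata$dog_name, x$metadata$phase,
              x$metadata$seed))
  if (nrow(x$trials)) print(table(x$trials$response))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a session (and agent) configuration from YAML
#'
#' Reads a structured config file with optional top-level `session:` and
#' `agent:` blocks (bare top-level keys are treated as session keys).
#' Defaults are applied for anything omitted — a file containing only a
#' seed yields the full default phase-3 configuration — and the result is
#' validated against the session invariants.
#'
#' @param path YAML file.
#' @return list with `$session` (a [session_config()]) and `$agent` (an
#'   [agent_params()], defaults if the file has no agent block).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sess_raw <- raw$session %||% raw[setdiff(names(raw), "agent")]
  agent_raw <- raw$agent %||% list()
  known <- names(formals(session_config))
  unknown <- setdiff(names(sess_raw), known)
  if (length(unknown))
    stop("unknown session config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  session <- do.call(session_config, sess_raw)
  unknown_a <- setdiff(names(agent_raw), names(formals(agent_params)))
  if (length(unknown_a))
    stop("unknown agent config key(s): ", paste(unknown_a, collapse = ", "),
         call. = FALSE)
  agent <- do.call(agent_params, agent_raw)
  list(session = session, agent = agent)
}
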