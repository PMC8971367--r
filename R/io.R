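SESSION_SCHEMA_VERSION <- "1.0"

session_block_key <- function(b) paste0("implicitAssociation.block", b)

KNOWN_SESSION_FIELDS <- c("schema_version", "participant_id", "app_type",
                          "input_method", "order_index", "task_seed", "sides",
                          "compatible_blocks", "complete",
                          vapply(1:7, session_block_key, ""))

#' Write a session result to JSON
#'
#' Sessions are serialized to a single JSON object with a schema version
#' tag, the participant/variant/order metadata, the side assignment and
#' compatible-block set, and one array of trial records per block under the
#' keys `implicitAssociation.block1` ... `implicitAssociation.block7`.
#' Field order is deterministic, so writing, reading and re-writing a
#' session yields byte-identical files. Unknown top-level fields read by
#' [read_session()] are preserved and re-emitted after the known ones.
#'
#' @param session an `iat_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "iat_session"))
  obj <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    participant_id = session$participant_id,
    app_type = session$app_type,
    input_method = session$input_method,
    order_index = session$order_index,
    task_seed = session$task_seed,
    sides = session$sides,
    compatible_blocks = I(session$compatible_blocks),
    complete = session$complete
  )
  for (b in 1:7) {
    key <- session_block_key(b)
    blk <- session$blocks[[paste0("block", b)]]
    if (!is.null(blk)) obj[[key]] <- blk
  }
  extras <- session$extra_fields
  if (!is.null(extras)) for (nm in names(extras)) obj[[nm]] <- extras[[nm]]
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "rows", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a session result from JSON
#'
#' Validates the schema version and the presence of all seven block keys,
#' then reconstructs the `iat_session`. Files without a version tag are
#' rejected with guidance; a version mismatch names both versions; a
#' missing block key is named in the error.
#'
#' @param path path to a session JSON file written by [write_session()].
#' @return An `iat_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("session file '%s' not found", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version))
    stop_validation(paste0(
      "'", path, "' has no schema_version tag; this does not look like a ",
      "session file written by this package (expected version ",
      SESSION_SCHEMA_VERSION, ")"))
  if (!identical(as.character(raw$schema_version), SESSION_SCHEMA_VERSION))
    stop_validation(sprintf(
      "session schema version mismatch: file has '%s', this package reads '%s'",
      raw$schema_version, SESSION_SCHEMA_VERSION))
  blocks <- list()
  for (b in 1:7) {
    key <- session_block_key(b)
    if (is.null(raw[[key]]))
      stop_validation(sprintf("session file is missing block key '%s'", key))
    blk <- as.data.frame(raw[[key]], stringsAsFactors = FALSE)
    need <- c("stimulus", "kind", "cat", "trial_code", "pairing",
              "latency_ms", "initially_correct")
    missing <- setdiff(need, names(blk))
    if (length(missing))
      stop_validation(sprintf("malformed trial records in '%s': missing field(s) %s",
                              key, paste(missing, collapse = ", ")))
    blk$cat <- as.integer(blk$cat)
    blk$latency_ms <- as.numeric(blk$latency_ms)
    blk$initially_correct <- as.logical(blk$initially_correct)
    blocks[[paste0("block", b)]] <- blk
  }
  extras <- raw[setdiff(names(raw), KNOWN_SESSION_FIELDS)]
  ses <- structure(
    list(
      participant_id = as.character(raw$participant_id),
      app_type = raw$app_type,
      input_method = raw$input_method,
      order_index = as.integer(raw$order_index),
      task_seed = if (is.null(raw$task_seed)) NULL else as.integer(raw$task_seed),
      sides = lapply(raw$sides, as.integer),
      compatible_blocks = as.integer(raw$compatible_blocks),
      complete = isTRUE(raw$complete),
      blocks = blocks
    ),
    class = "iat_session"
  )
  if (length(extras)) ses$extra_fields <- extras
  ses
}

#' Export sessions to a long-format trial CSV
#'
#' Writes one row per trial (see [trial_table()] for the columns). The
#' export is lossless for scoring: [sessions_from_trials()] on the re-read
#' table reconstructs sessions whose D scores equal those of the originals.
#'
#' @param sessions an `iat_session` or list of them.
#' @param path output CSV path; `NULL` returns the table without writing.
#' @return The trial table, invisibly when written.
#' @export
export_trials_csv <- function(sessions, path = NULL) {
  tt <- trial_table(sessions)
  if (is.null(path)) return(tt)
  write.csv(tt, path, row.names = FALSE)
  invisible(tt)
}

#' Read a long-format trial CSV
#'
#' @param path path to a CSV written by [export_trials_csv()].
#' @return The trial table data frame.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("trial CSV '%s' not found", path))
  tt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "app_type", "input_method", "order_index", "block",
            "trial_index", "latency_ms", "initially_correct")
  missing <- setdiff(need, names(tt))
  if (length(missing))
    stop_validation(paste0("trial CSV is missing column(s): ",
                           paste(missing, collapse = ", ")))
  tt
}

#' Rebuild sessions from a long-format trial table
#'
#' Groups trial rows by participant and order position and reconstructs
#' minimal `iat_session` objects sufficient for scoring and analysis. The
#' compatible-block set is recovered from the `compatible` flags.
#'
#' @param trials a trial table as returned by [trial_table()] or
#'   [read_trials_csv()].
#' @return A list of `iat_session` objects.
#' @export
sessions_from_trials <- function(trials) {
  trials <- as.data.frame(trials)
  key <- paste(trials$participant, trials$order_index, sep = "\r")
  lapply(split(seq_len(nrow(trials)), key), function(idx) {
    part <- trials[idx, , drop = FALSE]
    part <- part[order(part$block, part$trial_index), , drop = FALSE]
    blocks <- lapply(split(part, part$block), function(bd) {
      data.frame(
        stimulus = as.character(bd$stimulus),
        kind = as.character(bd$stimulus_kind %||% bd$kind),
        cat = if ("cat" %in% names(bd)) as.integer(bd$cat) else NA_integer_,
        trial_code = as.character(bd$trial_code %||% NA_character_),
        pairing = as.character(bd$pairing %||% NA_character_),
        latency_ms = as.numeric(bd$latency_ms),
        initially_correct = as.logical(bd$initially_correct),
        stringsAsFactors = FALSE
      )
    })
    names(blocks) <- paste0("block", sort(unique(part$block)))
    compat <- sort(unique(part$block[part$compatible %in% TRUE]))
    structure(
      list(
        participant_id = as.character(part$participant[1L]),
        app_type = part$app_type[1L],
        input_method = part$input_method[1L],
        order_index = as.integer(part$order_index[1L]),
        task_seed = NULL,
        sides = NULL,
        compatible_blocks = as.integer(compat),
        complete = TRUE,
        blocks = blocks
      ),
      class = "iat_session"
    )
  })
}
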