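# Plain-text serialization: word-event tables as TSV, matrices (signals,
# embeddings, prediction distributions) as TSV, ground-truth ledgers and
# run reports as JSON.

#' Write / read a word-event table as TSV
#'
#' Columns: `token`, `onset_s`, `offset_s`, `type_id` (and
#' `repetition_count` if present).
#'
#' @param events an `nlx_events`
#' @param path file path
#' @return `read_events_tsv` returns an `nlx_events`
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("token", "onset_s", "offset_s", "type_id") %in% names(ev)))
  class(ev) <- c("nlx_events", "data.frame")
  ev
}

#' Write / read a recording as TSV (electrodes x samples) plus a JSON sidecar
#'
#' The sidecar (`<path>.json`) stores `fs`, `electrode_ids` and `stage`.
#'
#' @param rec an `nlx_recording`
#' @param path TSV file path
#' @return `read_recording_tsv` returns an `nlx_recording`
#' @export
write_recording_tsv <- function(rec, path) {
  utils::write.table(rec$signal, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, electrode_ids = rec$electrode_ids,
                            stage = rec$stage),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  sig <- as.matrix(utils::read.delim(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_recording(unname(sig), meta$fs, meta$electrode_ids, meta$stage)
}

#' Write / read an embedding matrix as TSV
#'
#' The kind tag is stored in a JSON sidecar (`<path>.json`).
#'
#' @param emb an `nlx_embedding`
#' @param path TSV file path
#' @return `read_embedding_tsv` returns an `nlx_embedding`
#' @export
write_embedding_tsv <- function(emb, path) {
  utils::write.table(unclass(emb), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(kind = embedding_kind(emb),
                            note = attr(emb, "note") %||% ""),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_embedding(unname(m), meta$kind, meta$note)
}

#' Write a ground-truth ledger (or any report list) as JSON
#'
#' Matrices are stored as nested arrays; `NULL` entries are dropped.
#'
#' @param x list to serialize
#' @param path file path
#' @export
write_ledger_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
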