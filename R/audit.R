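# Append-only audit trail and sample review states.
#
# Every change during interpretation is an event: who (user + role), what
# (annotate / review / approve), on which feature or sample, when. The
# current annotations and review states are a pure fold over the event
# log, so replaying the log always reconstructs the state exactly.

.AUDIT_ROLES <- c("data_analyst", "lab_specialist")
.AUDIT_ACTIONS <- c("annotate", "review", "approve")
.SAMPLE_STATES <- c("new", "in_review", "reviewed", "approved")

#' Create an audit event
#'
#' @param user User name (plain string; authentication is out of scope).
#' @param role `"data_analyst"` or `"lab_specialist"`.
#' @param action `"annotate"` (free-text note on a feature or sample),
#'   `"review"` (advance a sample's review state), or `"approve"`
#'   (final sign-off; lab specialists only).
#' @param sample_id,feature_id Subject of the event (at least one for
#'   `annotate`; `sample_id` for `review`/`approve`).
#' @param text Free-text note.
#' @param timestamp Event time (POSIXct; defaults to now).
#' @return An `audit_event` list.
#' @export
audit_event <- function(user, role, action, sample_id = NA_character_,
                        feature_id = NA_character_, text = "",
                        timestamp = Sys.time()) {
  role <- match.arg(role, .AUDIT_ROLES)
  action <- match.arg(action, .AUDIT_ACTIONS)
  structure(list(timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%OS3%z"),
                 user = user, role = role, action = action,
                 sample_id = sample_id, feature_id = feature_id,
                 text = text),
            class = "audit_event")
}

#' Create an empty audit log
#' @return An `audit_log` (list of events).
#' @export
audit_log <- function() structure(list(), class = "audit_log")

.next_state <- function(state, action) {
  if (action == "review") {
    if (state == "new") return("in_review")
    if (state == "in_review") return("reviewed")
    stop("cannot review a sample in state '", state, "'", call. = FALSE)
  }
  if (action == "approve") {
    if (state == "reviewed") return("approved")
    stop("cannot approve a sample in state '", state,
         "' (must be 'reviewed')", call. = FALSE)
  }
  state
}

#' Append an event to the audit log
#'
#' Validates the role matrix (`approve` requires a lab specialist) and the
#' sample review state machine (`new -> in_review -> reviewed ->
#' approved`, advanced by `review`/`approve` events) before appending.
#' The log itself is never modified in place: a new, longer log is
#' returned.
#'
#' @param log An [audit_log()].
#' @param event An [audit_event()].
#' @return The extended `audit_log`.
#' @export
record_event <- function(log, event) {
  stopifnot(inherits(log, "audit_log"), inherits(event, "audit_event"))
  if (event$action == "approve" && event$role != "lab_specialist")
    stop("only a lab_specialist may approve a sample", call. = FALSE)
  if (event$action %in% c("review", "approve")) {
    if (is.na(event$sample_id))
      stop("review/approve events need a sample_id", call. = FALSE)
    state <- replay_log(log)$sample_status
    cur <- if (event$sample_id %in% names(state)) state[[event$sample_id]]
      else "new"
    .next_state(cur, event$action)  # errors on invalid transition
  } else if (is.na(event$sample_id) && is.na(event$feature_id)) {
    stop("annotate events need a sample_id or feature_id", call. = FALSE)
  }
  log[[length(log) + 1L]] <- event
  class(log) <- "audit_log"
  log
}

#' Reconstruct current state from the audit log
#'
#' A pure left fold over the events: per-sample review states and the
#' accumulated feature/sample annotations, in event order.
#'
#' @param log An [audit_log()].
#' @return List: `sample_status` (named character vector), `annotations`
#'   (data.frame `timestamp`, `user`, `role`, `sample_id`, `feature_id`,
#'   `text`).
#' @export
replay_log <- function(log) {
  status <- character(0)
  notes <- list()
  for (e in log) {
    if (e$action %in% c("review", "approve")) {
      cur <- if (e$sample_id %in% names(status)) status[[e$sample_id]]
        else "new"
      status[[e$sample_id]] <- .next_state(cur, e$action)
    } else {
      notes[[length(notes) + 1L]] <- data.frame(
        timestamp = e$timestamp, user = e$user, role = e$role,
        sample_id = e$sample_id, feature_id = e$feature_id, text = e$text,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, notes)
  if (is.null(ann))
    ann <- data.frame(timestamp = character(0), user = character(0),
                      role = character(0), sample_id = character(0),
                      feature_id = character(0), text = character(0))
  list(sample_status = status, annotations = ann)
}

#' Persist the audit log as append-only JSON lines
#'
#' `append_audit_log` appends the events not yet on disk (the file only
#' ever grows); `read_audit_log` restores the full log.
#'
#' @param log An [audit_log()].
#' @param path JSONL file path.
#' @return The path / the restored `audit_log`.
#' @export
append_audit_log <- function(log, path) {
  n_disk <- if (file.exists(path)) length(readLines(path)) else 0L
  if (n_disk > length(log))
    stop("audit file has more events than the log; refusing to truncate")
  if (n_disk < length(log)) {
    con <- file(path, open = "a")
    on.exit(close(con))
    for (e in log[(n_disk + 1L):length(log)])
      writeLines(jsonlite::toJSON(unclass(e), auto_unbox = TRUE,
                                  na = "null"), con)
  }
  invisible(path)
}

#' @rdname append_audit_log
#' @export
read_audit_log <- function(path) {
  log <- audit_log()
  if (!file.exists(path)) return(log)
  for (line in readLines(path)) {
    raw <- jsonlite::fromJSON(line)
    e <- structure(list(timestamp = raw$timestamp, user = raw$user,
                        role = raw$role, action = raw$action,
                        sample_id = raw$sample_id %||% NA_character_,
                        feature_id = raw$feature_id %||% NA_character_,
                        text = raw$text %||% ""),
                   class = "audit_event")
    log[[length(log) + 1L]] <- e
  }
  class(log) <- "audit_log"
  log
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
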