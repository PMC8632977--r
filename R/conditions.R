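# Structured error conditions used throughout the engine. Every user-facing
# refusal carries a condition class so callers (and the service layer) can
# dispatch on the kind of failure rather than on message text.

abort_validation <- function(msg, ...) {
  abort(msg, class = "varlocus_validation_error", ...)
}

abort_conflict <- function(msg, ...) {
  abort(msg, class = "varlocus_conflict_error", ...)
}

abort_authorization <- function(msg, ...) {
  abort(msg, class = "varlocus_authorization_error", ...)
}

abort_range <- function(msg, ...) {
  abort(msg, class = "varlocus_range_error", ...)
}

abort_parse <- function(msg, position = NA_integer_, ...) {
  abort(msg, class = "varlocus_parse_error", position = position, ...)
}

abort_capability <- function(msg, ...) {
  abort(msg, class = "varlocus_capability_error", ...)
}

abort_read_only <- function(announcement) {
  abort(
    paste0(
      "The database is in read-only mode; mutating operations are refused.",
      if (!is.na(announcement) && nzchar(announcement)) {
        paste0("\nAnnouncement: ", announcement)
      }
    ),
    class = "varlocus_read_only_error",
    announcement = announcement
  )
}

abort_guidance <- function(msg, ...) {
  abort(msg, class = "varlocus_guidance_error", ...)
}
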