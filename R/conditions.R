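# Structured condition helpers. Every user-facing error carries a subclass so
# callers (and tests) can dispatch on the failure kind rather than the message.

semdisc_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "semdisc_error")))
}

abort_invalid_entity <- function(msg) semdisc_error(msg, "semdisc_invalid_entity")
abort_malformed_uri <- function(msg, uri = NULL) {
  semdisc_error(msg, "semdisc_malformed_uri", uri = uri)
}
abort_unresolved_label <- function(uri) {
  semdisc_error(paste0("no human-readable label available for <", uri, ">"),
                "semdisc_unresolved_label", uri = uri)
}
abort_parse <- function(msg, file = NULL) {
  semdisc_error(msg, "semdisc_parse_error", file = file)
}
abort_not_found <- function(msg) semdisc_error(msg, "semdisc_not_found")
abort_invalid_input <- function(msg) semdisc_error(msg, "semdisc_invalid_input")
abort_lookup <- function(msg, uri = NULL) {
  semdisc_error(msg, "semdisc_lookup_error", uri = uri)
}

semdisc_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "semdisc_warning")))
}
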