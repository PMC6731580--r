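#' Engine configuration
#'
#' Shared configuration for the command-line entry point and for scripted
#' use: corpus location, dictionary and prefix-registry paths, ranking
#' weights, and the remote service endpoints (SPARQL query, label lookup,
#' sequence dbfetch, multiple-alignment) — each with an enabled flag that
#' defaults to off, so a default configuration never touches the network.
#'
#' @param path Optional YAML file; values in it override the defaults.
#' @return A list of class `semdisc_config`.
#' @export
semdisc_config <- function(path = NULL) {
  cfg <- list(
    corpus_dir = ".",
    dictionary_path = system.file("extdata", "dictionary.tsv", package = "semdisc"),
    prefix_registry_path = system.file("extdata", "prefixes.tsv", package = "semdisc"),
    weights = as.list(default_weights()),
    remotes = list(
      query = list(enabled = FALSE, url = "", timeout = 30, retries = 2),
      label_lookup = list(enabled = FALSE, url = "https://www.ebi.ac.uk/ols4/api/terms",
                          timeout = 30),
      dbfetch = list(enabled = FALSE, url = "https://www.ebi.ac.uk/Tools/dbfetch",
                     timeout = 60),
      msa = list(enabled = FALSE, url = "https://www.ebi.ac.uk/Tools/services/rest/clustalo",
                 timeout = 120)),
    log_level = "info")
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  w <- unlist(cfg$weights)
  cfg$weights <- as.list(validate_weights(w))
  structure(cfg, class = "semdisc_config")
}
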