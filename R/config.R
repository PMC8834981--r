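#' Load profile weights and reclassification bands from a config file
#'
#' Reads a structured config (YAML if the yaml package is available and the
#' file ends in .yml/.yaml, otherwise JSON) whose schema mirrors the model's
#' weighting table:
#'
#' ```yaml
#' variables:
#'   benches:
#'     units: m
#'     closure: left
#'     bands: [{lower: 0, upper: 100, level: 5}, ...]
#' profiles:
#'   healthy: {benches: 0.45, all_services: 0.45, slope: 0.10}
#' ```
#'
#' Omitted variables/profiles fall back to the built-ins; everything given
#' is validated on load.
#'
#' @param path config file path.
#' @return list with `$tables` (reclass tables) and `$profiles`
#'   (named list of [profile_weights()]).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package needed to read YAML configs; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  tables <- builtin_reclass_tables()
  for (v in names(cfg$variables)) {
    spec_v <- cfg$variables[[v]]
    bands <- as.data.frame(do.call(rbind, lapply(
      if (is.data.frame(spec_v$bands)) split(spec_v$bands, seq_len(nrow(spec_v$bands)))
      else spec_v$bands,
      function(b) data.frame(lower = as.numeric(b$lower),
                             upper = as.numeric(b$upper),
                             level = as.integer(b$level)))))
    tables[[v]] <- reclass_table(
      v, bands,
      units = if (is.null(spec_v$units)) "m" else spec_v$units,
      closure = if (is.null(spec_v$closure)) "left" else spec_v$closure)
  }
  profs <- builtin_profiles()
  for (p in names(cfg$profiles))
    profs[[p]] <- profile_weights(p, unlist(cfg$profiles[[p]]))
  list(tables = tables, profiles = profs)
}
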