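#' Read a run configuration (YAML or JSON)
#'
#' Configurations group parameters by module block; unknown top-level keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML or JSON file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  gp_validate(file.exists(path), sprintf("no such file: %s", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  allowed <- c("meniscus", "qc", "profile", "confluency", "cellcycle",
               "synth", "seed", "out_dir", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    gp_stop(sprintf("unknown config keys: %s",
                    paste(unknown, collapse = ", ")),
            "gelplate_validation")
  structure(cfg, class = "run_config")
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved_config.yaml"))
}

gp_log <- function(level = "info", ...) {
  message(sprintf("[gelplate %s] %s", level, paste0(...)))
}
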