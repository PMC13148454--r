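# Shared JSON/YAML config plumbing. Format is inferred from the file
# extension; JSON is the default for unrecognized extensions.

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- config_format(path)
  res <- tryCatch(
    if (fmt == "yaml") {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    },
    error = function(e) {
      stop("could not parse ", path, " as ", toupper(fmt), ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  res
}

write_config_file <- function(x, path) {
  fmt <- config_format(path)
  if (fmt == "yaml") {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# stable-ordered JSON for CLI output: names come out in insertion order and
# numbers are not rounded
to_stable_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}
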