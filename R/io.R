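# Hypnogram CSV interchange, checkpoints, pipeline configuration.

#' Read / write hypnogram CSV
#'
#' Format: columns `epoch_index` (0-based, consecutive), `stage` (token
#' from [STAGE_TOKENS]; note the merged light-sleep class is spelled
#' `N1N2` — raw `N1`/`N2` tokens are rejected), and optionally
#' `participant_id` and `night_label`. Write then read is the identity.
#'
#' @param path CSV file path.
#' @return [hypnogram], with `participant_id`/`night_label` attributes
#'   when present in the file.
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "stage")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV requires columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$epoch_index)) {
    stop("duplicate epoch_index values in ", path)
  }
  df <- df[order(df$epoch_index), ]
  bad <- setdiff(unique(df$stage), STAGE_TOKENS)
  if (length(bad) > 0) {
    stop("unknown stage token(s): ", paste(bad, collapse = ", "),
         "; accepted tokens are: ", paste(STAGE_TOKENS, collapse = ", "))
  }
  hyp <- hypnogram(df$stage)
  if ("participant_id" %in% names(df)) {
    attr(hyp, "participant_id") <- df$participant_id[1]
  }
  if ("night_label" %in% names(df)) {
    attr(hyp, "night_label") <- df$night_label[1]
  }
  hyp
}

#' @rdname read_hypnogram_csv
#' @param hyp [hypnogram] to write.
#' @param participant_id,night_label Optional metadata columns.
#' @export
write_hypnogram_csv <- function(hyp, path, participant_id = NULL,
                                night_label = NULL) {
  df <- data.frame(epoch_index = seq_along(hyp) - 1L,
                   stage = as.character(hyp))
  if (!is.null(participant_id)) df$participant_id <- participant_id
  if (!is.null(night_label)) df$night_label <- night_label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CHECKPOINT_FORMAT <- "cardiosleep-checkpoint-1"

#' Save / load a model checkpoint
#'
#' Single-file, version-tagged serialization of configuration and
#' weights.
#'
#' @param model [build_model()] result.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  saveRDS(list(format = CHECKPOINT_FORMAT,
               package_version = as.character(utils::packageVersion("cardiosleep")),
               cfg = unclass(model$cfg),
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: the restored `sleep_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, CHECKPOINT_FORMAT)) {
    stop("not a recognized checkpoint file: ", path)
  }
  model <- build_model(do.call(model_config,
                               ck$cfg[setdiff(names(formals(model_config)),
                                              "...") |>
                                        intersect(names(ck$cfg))]),
                       seed = 0L)
  model$params <- ck$params
  model
}

## ---- pipeline configuration ---------------------------------------------

PIPELINE_CONFIG_KEYS <- c("seed", "extraction", "model", "training", "paths")

#' Read / write the pipeline configuration (YAML)
#'
#' A text configuration with sections `seed`, `extraction` (arguments of
#' [extraction_config()]), `model` ([model_config()]), `training`
#' ([train_config()]) and `paths`. Unknown top-level or section keys are
#' rejected with the offending location. Round-trips losslessly.
#'
#' @param path YAML file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw, path)
}

validate_pipeline_config <- function(raw, where = "config") {
  unknown <- setdiff(names(raw), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) at %s top level: %s", where,
                 paste(unknown, collapse = ", ")))
  }
  sections <- list(extraction = names(formals(extraction_config)),
                   model = names(formals(model_config)),
                   training = names(formals(train_config)))
  for (sec in names(sections)) {
    if (is.null(raw[[sec]])) next
    bad <- setdiff(names(raw[[sec]]), sections[[sec]])
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) at %s$%s: %s", where, sec,
                   paste(bad, collapse = ", ")))
    }
  }
  structure(raw, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param cfg `pipeline_config` (or plain named list with the same keys).
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(unclass(cfg))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Polynomial rolling hash of a serialized object: provenance
# fingerprint for logs and artifact sidecars.
config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

# Provenance sidecar written next to pipeline artifacts.
write_provenance <- function(path, seed, extra = list()) {
  info <- c(list(tool = "cardiosleep",
                 version = as.character(utils::packageVersion("cardiosleep")),
                 seed = seed),
            extra)
  info$config_hash <- config_hash(info)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
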