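# Single-file checkpoints: a versioned RDS with a config header and the
# parameter tree. Batch-norm running-statistic environments are converted
# to tagged lists on save and restored to environments on load.

freeze_states <- function(p) {
  if (is.environment(p)) {
    return(list(.bn_state = TRUE, mean = p$mean, var = p$var))
  }
  if (is.list(p)) return(lapply(p, freeze_states))
  p
}

thaw_states <- function(p) {
  if (is.list(p)) {
    if (isTRUE(p$.bn_state)) {
      st <- new.env(parent = emptyenv())
      st$mean <- p$mean
      st$var <- p$var
      return(st)
    }
    return(lapply(p, thaw_states))
  }
  p
}

#' Save a model checkpoint
#'
#' @param path Output file.
#' @param kind `"encoder"` or `"segmodel"`.
#' @param config The configuration the parameters were built under.
#' @param params Parameter tree.
#' @param extra Optional named list stored alongside (e.g. the projection
#'   head used during pretraining).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, kind, config, params, extra = list()) {
  obj <- list(format = "stainseg-checkpoint", version = 1L, kind = kind,
              config = config, params = freeze_states(params),
              extra = freeze_states(extra))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return List with `kind`, `config`, `params`, `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "stainseg-checkpoint")) {
    stop(path, " is not a stainseg checkpoint")
  }
  if (obj$version > 1L) stop("checkpoint version ", obj$version, " is newer than supported")
  list(kind = obj$kind, config = obj$config,
       params = thaw_states(obj$params), extra = thaw_states(obj$extra))
}

# Field-by-field compatibility check between a checkpoint's encoder config
# and the requested one; names every mismatching field.
check_config_compatible <- function(ck_cfg, cfg) {
  fields <- c("preset", "input_size", "stage_channels", "stage_depths",
              "attention_heads")
  bad <- fields[!vapply(fields, function(f) {
    identical(unclass(ck_cfg[[f]]), unclass(cfg[[f]]))
  }, logical(1))]
  if (length(bad)) {
    stop("checkpoint encoder config is incompatible; mismatched fields: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
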