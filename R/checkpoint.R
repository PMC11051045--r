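# Model checkpointing: weights, batch-norm running statistics and the
# architecture spec in one RDS file.

#' Save a trained model
#'
#' @param model An `hs_model`.
#' @param path Output file (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  params <- lapply(mget(ls(model$params), envir = model$params),
                   function(p) p$value)
  state <- lapply(mget(ls(model$state), envir = model$state),
                  function(s) list(mean = s$mean, var = s$var))
  saveRDS(list(spec = model$spec, seed = model$seed,
               params = params, state = state), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Checkpoint file.
#' @return An `hs_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) hs_file_error(sprintf("checkpoint not found: '%s'", path))
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = ck$seed)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$state)) {
    model$state[[nm]]$mean <- ck$state[[nm]]$mean
    model$state[[nm]]$var <- ck$state[[nm]]$var
  }
  model
}
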