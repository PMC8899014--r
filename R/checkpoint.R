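# Model persistence: serialized parameter lists plus a JSON sidecar
# describing the run (seeds, configuration, validation trace), so results
# can be audited without loading the checkpoint.

#' Save / load a trained model
#'
#' The model state is serialized as RDS; a `.json` sidecar records the
#' training configuration, best epoch and validation trace.
#'
#' @param fit A [train_model()] result.
#' @param path Checkpoint path (the sidecar gets `.json` appended).
#' @export
save_model <- function(fit, path) {
  saveRDS(fit, path)
  meta <- list(best_epoch = fit$best_epoch, val_trace = fit$val_trace,
               test_auc = fit$test_roc$auc,
               n_pos = fit$test_roc$n_pos, n_neg = fit$test_roc$n_neg,
               epochs = fit$config$epochs, lr = fit$config$lr,
               seed = fit$config$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the [train_model()] result.
#' @export
load_model <- function(path) readRDS(path)
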