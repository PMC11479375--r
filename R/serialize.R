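# Model weights travel as JSON: every numeric array is stored as
# {dim, data} with full double precision, alongside the architecture
# config and the frozen scaler, so a saved model is self-describing.

tree_pack <- function(x) {
  if (is.numeric(x))
    return(list(.array = TRUE, dim = dim(x) %||% length(x),
                data = as.vector(x)))
  if (is.null(x)) return(NULL)
  lapply(x, tree_pack)
}

tree_unpack <- function(x) {
  if (is.null(x)) return(NULL)
  if (isTRUE(x$.array)) {
    v <- as.numeric(unlist(x$data))
    d <- as.integer(unlist(x$dim))
    if (length(d) > 1) dim(v) <- d
    return(v)
  }
  lapply(x, tree_unpack)
}

#' Save / load a trained model
#'
#' Serializes architecture config, weights, batch-norm running statistics,
#' the frozen scaler and (spatial models) the target standardization to a
#' JSON file with full float precision.
#'
#' @param model a `temporal_model` or `spatial_model`.
#' @param path output JSON path.
#' @return `path` (save) / the reconstructed model (load).
#' @export
save_model <- function(model, path) {
  if (inherits(model, "temporal_model")) {
    obj <- list(type = "temporal", config = unclass(model$config),
                params = tree_pack(params_get(model$layers)),
                buffers = tree_pack(lapply(model$layers, function(l)
                  l$buffers)),
                scaler = if (!is.null(model$scaler))
                  lapply(unclass(model$scaler), as.list))
  } else if (inherits(model, "spatial_model")) {
    obj <- list(type = "spatial", config = unclass(model$config),
                params = tree_pack(spatial_params_get(model)),
                target_mean = model$target_mean, target_sd = model$target_sd,
                duration_scale = model$duration_scale,
                calibration = model$calibration %||% c(0, 1),
                scaler = if (!is.null(model$scaler))
                  lapply(unclass(model$scaler), as.list))
  } else stop_mear("unknown model type", "mear_config_error")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(0)  # throwaway init, overwritten below; keeps global RNG intact
  scaler <- NULL
  if (!is.null(obj$scaler))
    scaler <- structure(list(median = unlist(obj$scaler$median),
                             iqr = unlist(obj$scaler$iqr)),
                        class = "scaler_params")
  obj$config <- lapply(obj$config, unlist)
  if (identical(obj$type, "temporal")) {
    cfg <- do.call(temporal_config, obj$config)
    model <- build_temporal_model(cfg)
    model$layers <- params_set(model$layers, tree_unpack(obj$params))
    bufs <- tree_unpack(obj$buffers)
    for (i in seq_along(model$layers))
      if (!is.null(model$layers[[i]]$buffers))
        model$layers[[i]]$buffers <- bufs[[i]]
    model$scaler <- scaler
    model
  } else if (identical(obj$type, "spatial")) {
    cfg <- do.call(spatial_config, obj$config)
    model <- build_spatial_model(cfg)
    model <- spatial_params_set(model, tree_unpack(obj$params))
    model$target_mean <- obj$target_mean
    model$target_sd <- obj$target_sd
    model$duration_scale <- obj$duration_scale %||% 1
    model$calibration <- unlist(obj$calibration %||% c(0, 1))
    model$scaler <- scaler
    model
  } else stop_mear("unknown model type in file", "mear_format_error")
}
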