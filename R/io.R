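# Plain-text interchange: boundary curves (CSV), time-lapse bundles (JSON),
# parameter tables (TSV), tip clouds (CSV).

#' Read / write a boundary curve as CSV (x,y per row)
#' @param path file path.
#' @param ... passed to [boundary_curve()].
#' @return A `boundary_curve`.
#' @export
read_boundary_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  boundary_curve(as.matrix(df[, 1:2]), ...)
}

#' @rdname read_boundary_csv
#' @param curve a `boundary_curve`.
#' @export
write_boundary_csv <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$points[, 1], y = curve$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a time-lapse bundle as JSON
#'
#' The JSON dialect bundles frames with timestamps:
#' `{"pixel_size": 1, "frames": [{"t": 0, "x": [...], "y": [...]}, ...]}`.
#'
#' @param path file path.
#' @return A `time_lapse` (without ground-truth fields).
#' @export
read_timelapse_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  frames <- lapply(seq_len(nrow(obj$frames)), function(i)
    boundary_curve(cbind(obj$frames$x[[i]], obj$frames$y[[i]])))
  structure(list(frames = frames, timestamps = obj$frames$t,
                 pixel_size = obj$pixel_size %||% 1, truth = NULL),
            class = "time_lapse")
}

#' @rdname read_timelapse_json
#' @param tl a `time_lapse`.
#' @export
write_timelapse_json <- function(tl, path) {
  obj <- list(pixel_size = tl$pixel_size,
              frames = data.frame(t = tl$timestamps))
  obj$frames$x <- lapply(tl$frames, function(f) f$points[, 1])
  obj$frames$y <- lapply(tl$frames, function(f) f$points[, 2])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write parameter tables as TSV (one row per sampled set)
#' @param path file path.
#' @return data.frame of parameter draws.
#' @export
read_params_tsv <- function(path) utils::read.delim(path, check.names = FALSE)

#' @rdname read_params_tsv
#' @param params data.frame (e.g. from [sample_parameters()]).
#' @export
write_params_tsv <- function(params, path) {
  utils::write.table(params, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tip clouds as CSV (sample_id, genotype, x, y, z)
#' @param path file path.
#' @return list of `tip_cloud`s (one per sample_id).
#' @export
read_tipcloud_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$sample_id), function(d)
    tip_cloud(as.matrix(d[, intersect(c("x", "y", "z"), names(d))]),
              sample_id = d$sample_id[1], genotype = as.character(d$genotype[1])))
}

#' @rdname read_tipcloud_csv
#' @param clouds a `tip_cloud` or list of them.
#' @export
write_tipcloud_csv <- function(clouds, path) {
  if (inherits(clouds, "tip_cloud")) clouds <- list(clouds)
  rows <- lapply(clouds, function(cl) {
    d <- as.data.frame(cl$tips)
    names(d) <- c("x", "y", "z")[seq_len(ncol(d))]
    cbind(sample_id = cl$sample_id, genotype = cl$genotype, d)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a model specification to JSON
#' @param model a [model_spec()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(variant = model$variant,
                            params = unclass(model$params),
                            readout_exponents = model$readout_exponents),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  model_spec(obj$variant, do.call(parameter_set, obj$params),
             readout_exponents = obj$readout_exponents)
}
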