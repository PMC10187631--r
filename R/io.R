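#' Write an endocardial map as documented JSON
#'
#' Points, triangles (1-based), per-point bipolar voltage and ARI, apex
#' and axis annotations, and the ground-truth table when present.
#'
#' @param map an `endocardial_map`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_map_json <- function(map, path) {
  obj <- list(points = unname(as.matrix(map$points)),
              triangles = unname(as.matrix(map$triangles)),
              bipolar_voltage = map$bipolar_voltage,
              ari = map$ari, apex_index = map$apex_index,
              base_axis = map$base_axis)
  if (!is.null(map$truth)) obj$truth <- map$truth
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an endocardial map written by [write_map_json()]
#'
#' @param path `.json` path.
#' @return an `endocardial_map` (without electrograms).
#' @export
read_map_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(points = as.matrix(obj$points),
                 triangles = as.matrix(obj$triangles),
                 bipolar_voltage = obj$bipolar_voltage, ari = obj$ari,
                 apex_index = obj$apex_index, base_axis = obj$base_axis,
                 egms = NULL, truth = obj$truth),
            class = "endocardial_map")
}

#' Write a sampled trace (electrogram or optical) as two-column CSV
#'
#' Column 1: time (ms); column 2: value.
#'
#' @param trace an [electrogram()] or [optical_trace()].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  t_ms <- if (inherits(trace, "electrogram")) egm_time(trace)
  else (seq_along(trace$samples) - 1) * 1000 / trace$fs
  write.csv(data.frame(time_ms = t_ms, value = trace$samples), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a two-column trace CSV as an electrogram
#'
#' @param path `.csv` path written by [write_trace_csv()].
#' @return an [electrogram()] (sampling rate inferred from the time
#'   column).
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  dt <- median(diff(df[[1]]))
  electrogram(df[[2]], fs = 1000 / dt, t0 = df[[1]][1])
}
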