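## Mapping representative generators of Vietoris-Rips persistent holes back
## to sensors, and class-level sensor frequency histograms.

#' Vietoris-Rips persistence of a recording's sensor cloud
#'
#' Views the channels as points in R^N, computes the standardized Euclidean
#' distance matrix, builds the Vietoris-Rips filtration and reduces it with
#' representative cycles. Vertex ids in the returned generators are sensor
#' ids (montage positions).
#'
#' @param rec A \code{\link{recording}} with >= 2 channels.
#' @param r_max Filtration cap; default the largest pairwise distance, so
#'   the filtration completes.
#' @param max_dim Largest homology dimension (default 2).
#' @return A \code{\link{barcode}} with generators.
#' @export
analyze_recording <- function(rec, r_max = NULL, max_dim = 2L) {
  dm <- standardized_euclidean(rec)
  fc <- vietoris_rips(dm, r_max = r_max %||% max(dm), max_dim = max_dim)
  reduce_matrix(fc, max_dim = max_dim)
}

#' Sensor frequency histogram of hole generators
#'
#' For every persistent interval of positive length, each distinct sensor
#' appearing in its representative cycle increments that sensor's counter,
#' separately per class label and homology dimension. Representative cycles
#' are not unique; counts refer to the deterministic representatives chosen
#' by the reduction's fixed simplex order.
#'
#' @param barcodes List of \code{\link{barcode}}s with generators (e.g. from
#'   \code{\link{analyze_recording}}).
#' @param labels Class label per barcode.
#' @param dims Homology dimensions to include (default: all present).
#' @param min_length Count only intervals longer than this (default 0, i.e.
#'   every positive-length interval); useful for suppressing near-zero bars
#'   from noisy point clouds.
#' @return A data frame of class \code{sensor_histogram} with columns
#'   \code{label}, \code{dim}, \code{sensor_id}, \code{count}.
#' @export
aggregate_histogram <- function(barcodes, labels, dims = NULL, min_length = 0) {
  if (length(barcodes) != length(labels))
    ts_error("analysis_error", "one label per barcode required")
  rows <- list()
  for (b in seq_along(barcodes)) {
    bc <- barcodes[[b]]
    if (!inherits(bc, "barcode")) ts_error("analysis_error", "barcodes must be barcode objects")
    if (is.null(bc$generators))
      ts_error("analysis_error", sprintf("barcode %d has no generators", b))
    iv <- bc$intervals
    m <- bc$max_filter + 1
    death <- ifelse(is.infinite(iv$death), m, iv$death)
    for (i in seq_len(nrow(iv))) {
      if (!is.null(dims) && !(iv$dim[i] %in% dims)) next
      if (death[i] - iv$birth[i] <= max(min_length, 0)) next
      sensors <- sort(unique(unlist(bc$generators[[i]])))
      if (!length(sensors)) ts_error("analysis_error", sprintf("empty generator in barcode %d", b))
      rows[[length(rows) + 1L]] <- data.frame(
        label = as.character(labels[b]), dim = iv$dim[i], sensor_id = sensors)
    }
  }
  if (!length(rows)) {
    out <- data.frame(label = character(0), dim = integer(0),
                      sensor_id = integer(0), count = integer(0))
  } else {
    all <- do.call(rbind, rows)
    out <- stats::aggregate(list(count = rep(1L, nrow(all))),
                            by = all[c("label", "dim", "sensor_id")], FUN = sum)
    out <- out[order(out$label, out$dim, out$sensor_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("sensor_histogram", "data.frame")
  out
}
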