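## Filtered simplicial complexes: the sublevel-set ("piecewise") filtration
## of a sampled signal, and the Vietoris-Rips filtration of the sensor point
## cloud under a standardized Euclidean metric.

#' Filtered simplicial complex
#'
#' A flat container of simplices with filter values; the common substrate of
#' both filtrations in this package.
#'
#' @param verts List of integer vectors; each vector is the sorted, distinct
#'   vertex ids of one simplex (length k+1 for a k-simplex).
#' @param filt Numeric vector of filter values, one per simplex.
#' @param validate Check face closure and filter monotonicity (default
#'   \code{TRUE}; constructors that build complexes correct by construction
#'   skip it).
#' @return An object of class \code{filtered_complex}, a list with elements
#'   \code{verts}, \code{dim} and \code{filt}; \code{filter_values(fc)}
#'   returns the set F of distinct filter values.
#' @export
filtered_complex <- function(verts, filt, validate = TRUE) {
  if (length(verts) != length(filt))
    ts_error("data_error", "verts and filt must have the same length")
  verts <- lapply(verts, function(v) sort(unique(as.integer(v))))
  fc <- structure(
    list(verts = verts,
         dim = vapply(verts, length, integer(1)) - 1L,
         filt = as.numeric(filt)),
    class = "filtered_complex"
  )
  if (validate) validate_complex(fc)
  fc
}

#' @rdname filtered_complex
#' @param fc A \code{filtered_complex}.
#' @export
filter_values <- function(fc) sort(unique(fc$filt))

#' @export
print.filtered_complex <- function(x, ...) {
  tab <- table(x$dim)
  cat(sprintf("<filtered_complex> %d simplices (%s); %d distinct filter values\n",
              length(x$verts),
              paste(sprintf("dim %s: %d", names(tab), tab), collapse = ", "),
              length(unique(x$filt))))
  invisible(x)
}

simplex_keys <- function(verts) {
  vapply(verts, paste, character(1), collapse = "-")
}

#' Validate a filtered complex
#'
#' Checks that every face of every simplex is present (face closure) and
#' enters the filtration no later than its coface (filter monotonicity).
#' Raises a data error on violation; returns \code{fc} invisibly otherwise.
#'
#' @param fc A \code{\link{filtered_complex}}.
#' @export
validate_complex <- function(fc) {
  if (!all(is.finite(fc$filt)))
    ts_error("data_error", "filter values must be finite")
  keys <- simplex_keys(fc$verts)
  if (anyDuplicated(keys))
    ts_error("data_error", "duplicate simplices in complex")
  filt_of <- stats::setNames(fc$filt, keys)
  for (j in seq_along(fc$verts)) {
    v <- fc$verts[[j]]
    if (length(v) < 2L) next
    for (drop in seq_along(v)) {
      fk <- paste(v[-drop], collapse = "-")
      fv <- filt_of[fk]
      if (is.na(fv))
        ts_error("data_error", sprintf("complex not closed under faces: missing face %s", fk))
      if (fv > fc$filt[j] + 1e-12)
        ts_error("data_error",
                 sprintf("filter monotonicity violated: face %s enters after its coface", fk))
    }
  }
  invisible(fc)
}

#' Sublevel-set (piecewise) filtration of a sampled signal
#'
#' Treats the samples as the breakpoints of a piecewise-linear function and
#' builds its sublevel-set filtration: one vertex per sample entering at its
#' amplitude, one edge per consecutive sample pair entering at the larger of
#' its two endpoint amplitudes (lower-star rule). A length-N signal yields
#' exactly N vertices and N-1 edges.
#'
#' For the three-point signal with amplitudes (0, 2, 1) this gives vertices
#' at filter values 0, 2, 1 and both edges at 2, so F = \{0, 1, 2\}.
#'
#' @param sig A \code{\link{channel_signal}}, or a bare numeric vector of
#'   amplitudes.
#' @return A \code{\link{filtered_complex}} with vertex ids 1..N in time
#'   order.
#' @export
#' @examples
#' fc <- piecewise_filtration(c(0, 2, 1))
#' filter_values(fc)
piecewise_filtration <- function(sig) {
  y <- if (inherits(sig, "channel_signal")) sig$samples else as.numeric(sig)
  n <- length(y)
  if (n < 1L) ts_error("data_error", "signal must have at least one sample")
  if (!all(is.finite(y))) ts_error("data_error", "signal amplitudes must be finite")
  verts <- c(as.list(seq_len(n)),
             if (n > 1L) lapply(seq_len(n - 1L), function(k) c(k, k + 1L)))
  filt <- c(y, if (n > 1L) pmax(y[-n], y[-1L]))
  structure(list(verts = lapply(verts, as.integer),
                 dim = rep(c(0L, 1L), c(n, max(n - 1L, 0L))),
                 filt = filt),
            class = "filtered_complex")
}

#' Standardized Euclidean distances between channels
#'
#' Views the channels of a recording as points in R^N (N = samples per
#' channel) and computes all pairwise standardized Euclidean distances:
#' each coordinate k is divided by s_k, the sample standard deviation of
#' that coordinate across the recording's own channels, before the ordinary
#' Euclidean distance is taken. Coordinates where all channels agree
#' (s_k = 0) make the metric undefined and raise a degenerate-position
#' error naming the first such position.
#'
#' @param rec A \code{\link{recording}} with at least 2 channels.
#' @return A symmetric n x n numeric matrix with zero diagonal; rows and
#'   columns are named by sensor id.
#' @export
standardized_euclidean <- function(rec) {
  if (!inherits(rec, "recording") || n_channels(rec) < 2L)
    ts_error("data_error", "need a recording with at least 2 channels")
  mat <- vapply(rec$channels, function(ch) ch$samples, numeric(n_samples(rec)))
  mat <- matrix(mat, nrow = n_samples(rec))  # samples x channels
  s_k <- apply(mat, 1L, stats::sd)
  bad <- which(s_k == 0)
  if (length(bad))
    ts_error("degenerate_position_error",
             sprintf("all channels identical at sample position(s) %s: standardized distance undefined",
                     paste(utils::head(bad, 5L), collapse = ", ")),
             positions = bad)
  z <- mat / s_k
  dm <- as.matrix(stats::dist(t(z), method = "euclidean"))
  ids <- vapply(rec$channels, function(ch) ch$sensor_id, integer(1))
  dimnames(dm) <- list(ids, ids)
  dm
}

#' Vietoris-Rips filtration of a finite metric space
#'
#' Builds the filtered clique complex of a distance matrix: a simplex is
#' included whenever all pairwise distances among its vertices are at most
#' \code{r_max}, with filter value equal to its diameter (0 for vertices).
#' Simplices are generated up to dimension \code{max_dim + 1} so that
#' homology through dimension \code{max_dim} has its deaths witnessed.
#'
#' @param dm Symmetric numeric distance matrix with zero diagonal.
#' @param r_max Filtration scale cap; default the largest entry of
#'   \code{dm}, so the filtration runs to completion.
#' @param max_dim Largest homology dimension of interest (default 2).
#' @return A \code{\link{filtered_complex}}; vertex ids are 1..n (row order
#'   of \code{dm}).
#' @export
vietoris_rips <- function(dm, r_max = max(dm), max_dim = 2L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n != ncol(dm) || any(abs(dm - t(dm)) > 1e-9) || any(diag(dm) != 0) || any(dm < 0))
    ts_error("data_error", "dm must be a symmetric non-negative matrix with zero diagonal")
  if (r_max < 0 || max_dim < 0) ts_error("config_error", "r_max and max_dim must be non-negative")

  verts <- as.list(seq_len(n))
  filt <- rep(0, n)
  ## grow simplices dimension by dimension: extend each k-simplex by a
  ## higher-indexed vertex adjacent (within r_max) to all of its vertices
  prev <- lapply(seq_len(n), function(i) list(v = i, d = 0))
  for (k in seq_len(max_dim + 1L)) {
    cur <- list()
    for (sx in prev) {
      last <- sx$v[length(sx$v)]
      if (last >= n) next
      for (w in (last + 1L):n) {
        dmax <- max(dm[sx$v, w])
        if (dmax <= r_max) {
          cur[[length(cur) + 1L]] <- list(v = c(sx$v, w), d = max(sx$d, dmax))
        }
      }
    }
    if (!length(cur)) break
    verts <- c(verts, lapply(cur, `[[`, "v"))
    filt <- c(filt, vapply(cur, `[[`, numeric(1), "d"))
    prev <- cur
  }
  structure(list(verts = lapply(verts, as.integer),
                 dim = vapply(verts, length, integer(1)) - 1L,
                 filt = filt),
            class = "filtered_complex")
}

#' Export a filtered complex as plain text
#'
#' One simplex per line in the documented format
#' \code{dim v1 ... vk filter_value}, for verification with external tools.
#'
#' @param fc A \code{\link{filtered_complex}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_complex <- function(fc, path) {
  lines <- vapply(seq_along(fc$verts), function(j)
    paste(fc$dim[j], paste(fc$verts[[j]], collapse = " "),
          format(fc$filt[j], digits = 15)), character(1))
  writeLines(lines, path)
  invisible(path)
}
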