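## Persistent entropy of a barcode and the Sample Entropy comparator.

#' Persistent entropy of a barcode
#'
#' Shannon entropy of the normalized bar lengths of a barcode. Infinite
#' intervals [x, Inf) are first replaced by [x, m) with
#' m = max(F) + 1, where max(F) is the largest filter value of the source
#' complex. With lengths l_i = y_i - x_i, L = sum(l_i) and p_i = l_i / L,
#'
#'   H = -sum(p_i * log(p_i))   (natural log, nats)
#'
#' Zero-length bars contribute 0 (the 0 * log 0 limit) and are excluded from
#' the maximum length.
#'
#' @param bc A \code{\link{barcode}}.
#' @param dims Homology dimensions to include (default 0).
#' @return An object of class \code{entropy_result}: list with \code{H}
#'   (nats), \code{H_norm} (NA if undefined, see
#'   \code{\link{normalized_persistent_entropy}}), \code{lengths},
#'   \code{total} (L) and \code{l_max}.
#' @export
#' @examples
#' bc <- persistence_0d(piecewise_filtration(c(0, 2, 1)))
#' persistent_entropy(bc)$H   # 0.5623 nats
persistent_entropy <- function(bc, dims = 0L) {
  if (!inherits(bc, "barcode")) ts_error("data_error", "bc must be a barcode")
  iv <- bc$intervals[bc$intervals$dim %in% dims, , drop = FALSE]
  if (nrow(iv) == 0L)
    ts_error("entropy_error", "barcode has no intervals in the requested dimensions")
  m <- bc$max_filter + 1
  death <- ifelse(is.infinite(iv$death), m, iv$death)
  len <- death - iv$birth
  pos <- len[len > 0]
  if (length(pos) == 0L)
    ts_error("entropy_error", "all bars have zero length: persistent entropy undefined")
  L <- sum(pos)
  p <- pos / L
  H <- -sum(p * log(p))
  l_max <- max(pos)
  H_norm <- if (l_max > 1) H / log(l_max) else NA_real_
  structure(list(H = H, H_norm = H_norm, lengths = len, total = L, l_max = l_max),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> H = %.4f nats, normalized H = %s (%d bars, l_max = %g)\n",
              x$H, if (is.na(x$H_norm)) "undefined" else sprintf("%.4f", x$H_norm),
              length(x$lengths), x$l_max))
  invisible(x)
}

#' Normalized persistent entropy
#'
#' H / log(l_max), where l_max is the longest (finite, after infinite-bar
#' replacement) bar in the barcode. The ratio is invariant to the logarithm
#' base. Requires l_max > 1, otherwise the normalization is undefined and a
#' normalization-domain error is raised (never silently clipped). Note that
#' H itself is invariant to rescaling all bar lengths, but the normalized
#' value is not, because l_max rescales while H does not.
#'
#' @inheritParams persistent_entropy
#' @return The normalized persistent entropy, a single number.
#' @export
normalized_persistent_entropy <- function(bc, dims = 0L) {
  res <- persistent_entropy(bc, dims)
  if (is.na(res$H_norm))
    ts_error("normalization_error",
             sprintf("l_max = %g <= 1: normalized persistent entropy undefined", res$l_max))
  res$H_norm
}

#' Sample Entropy of a signal
#'
#' SampEn(m, r): the negative log of the conditional probability that two
#' subsequences matching for m points (Chebyshev distance <= r,
#' self-matches excluded) continue to match for m + 1 points. Conventions:
#' template count B over length-m windows, A over length-(m+1) windows,
#' SampEn = -log(A/B). Returns +Inf with a warning when no matches exist.
#'
#' @param sig A \code{\link{channel_signal}} or numeric vector.
#' @param m Embedding (template) length, default 2.
#' @param r Match tolerance; default 0.2 times the sample standard
#'   deviation of the signal.
#' @return A single non-negative number (or +Inf).
#' @export
sample_entropy <- function(sig, m = 2L, r = NULL) {
  x <- if (inherits(sig, "channel_signal")) sig$samples else as.numeric(sig)
  n <- length(x)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (n <= m + 1L) ts_error("config_error", "signal too short for the chosen m")
  if (is.na(r) || r < 0) ts_error("config_error", "tolerance r must be non-negative")

  ## count template pairs within tolerance, vectorized over the second
  ## template index; both counts run over the same n - m template starts
  ## (those admitting an (m+1)-length extension), the standard convention
  count_pairs <- function(mm, n_t) {
    total <- 0
    for (i in seq_len(n_t - 1L)) {
      js <- (i + 1L):n_t
      ok <- rep(TRUE, length(js))
      for (k in 0:(mm - 1L)) {
        ok <- ok & (abs(x[i + k] - x[js + k]) <= r)
        if (!any(ok)) break
      }
      total <- total + sum(ok)
    }
    total
  }
  B <- count_pairs(m, n - m)
  A <- count_pairs(m + 1L, n - m)
  if (A == 0 || B == 0) {
    ts_warning("entropy_warning", "no matching templates: Sample Entropy undefined, returning Inf")
    return(Inf)
  }
  -log(A / B)
}
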