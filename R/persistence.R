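## Persistence barcodes from filtered complexes: a union-find computation
## for dimension 0 and a full boundary-matrix reduction over GF(2) with
## representative cycles for arbitrary dimension.

#' Persistence barcode
#'
#' @param dim Integer vector of homology dimensions.
#' @param birth,death Numeric vectors of interval endpoints; \code{Inf}
#'   deaths mark features that survive the whole filtration.
#' @param max_filter Largest filter value of the source complex (max F).
#' @param generators Optional list (one element per interval) of
#'   representative cycles; each cycle is a list of integer vertex vectors,
#'   one per simplex in the cycle.
#' @return An object of class \code{barcode}: a list with a data frame
#'   \code{intervals} (columns \code{dim}, \code{birth}, \code{death}),
#'   \code{max_filter} and \code{generators}.
#' @export
barcode <- function(dim, birth, death, max_filter, generators = NULL) {
  if (any(death < birth, na.rm = TRUE))
    ts_error("data_error", "interval death before birth")
  structure(list(
    intervals = data.frame(dim = as.integer(dim), birth = as.numeric(birth),
                           death = as.numeric(death)),
    max_filter = as.numeric(max_filter),
    generators = generators
  ), class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("<barcode> %d intervals (max filter %g)\n", nrow(iv), x$max_filter))
  for (d in sort(unique(iv$dim))) {
    sub <- iv[iv$dim == d, , drop = FALSE]
    cat(sprintf("  H%d: %d intervals, %d infinite\n", d, nrow(sub),
                sum(is.infinite(sub$death))))
  }
  invisible(x)
}

#' @rdname barcode
#' @param bc A \code{barcode}.
#' @param path Output path for \code{write_barcode}; columns are dim, birth,
#'   death and a space-separated generator vertex list.
#' @export
write_barcode <- function(bc, path) {
  iv <- bc$intervals
  gen <- if (is.null(bc$generators)) rep("", nrow(iv)) else
    vapply(bc$generators, function(g)
      paste(sort(unique(unlist(g))), collapse = " "), character(1))
  utils::write.csv(cbind(iv, generator = gen), path, row.names = FALSE)
  invisible(path)
}

## Face-compatible total order: (filter value, dimension, lexicographic
## vertex tuple). Any face-respecting order yields the same barcode; the
## lexicographic tie rule only fixes which representatives are reported.
order_simplices <- function(fc) {
  lex <- vapply(fc$verts, function(v)
    paste(sprintf("%09d", v), collapse = ""), character(1))
  order(fc$filt, fc$dim, lex)
}

#' Zero-dimensional persistence by union-find
#'
#' Computes the H0 barcode of a filtered complex with the elder rule: each
#' vertex is born at its filter value; when an edge joins two components the
#' younger one (later birth; ties broken toward the smaller birth vertex id)
#' dies at the edge's filter value. One interval per vertex, including
#' zero-length intervals; each connected component contributes exactly one
#' infinite interval. Simplices of dimension > 1 are ignored.
#'
#' @param fc A \code{\link{filtered_complex}}.
#' @return A \code{\link{barcode}} of dimension-0 intervals; each interval's
#'   generator is its birth vertex.
#' @export
#' @examples
#' persistence_0d(piecewise_filtration(c(0, 2, 1)))$intervals
persistence_0d <- function(fc) {
  if (!inherits(fc, "filtered_complex")) ts_error("data_error", "fc must be a filtered_complex")
  keep <- fc$dim <= 1L
  verts <- fc$verts[keep]; dims <- fc$dim[keep]; filt <- fc$filt[keep]
  vids <- unlist(verts[dims == 0L], use.names = FALSE)
  nv <- length(vids)
  if (nv == 0L) ts_error("data_error", "complex has no vertices")
  id_of <- integer(max(vids)); id_of[vids] <- seq_len(nv)

  lex <- vapply(verts, function(v) paste(sprintf("%09d", v), collapse = ""), character(1))
  ord <- order(filt, dims, lex)

  parent <- seq_len(nv)
  birth <- rep(NA_real_, nv)      # birth value of the component rooted here
  birth_v <- integer(nv)          # original vertex id realizing that birth
  alive <- logical(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  b_dim <- integer(0); b_birth <- numeric(0); b_death <- numeric(0)
  b_gen <- list()
  for (j in ord) {
    if (dims[j] == 0L) {
      i <- id_of[verts[[j]][1L]]
      birth[i] <- filt[j]; birth_v[i] <- verts[[j]][1L]; alive[i] <- TRUE
    } else {
      e <- verts[[j]]
      ra <- find(id_of[e[1L]]); rb <- find(id_of[e[2L]])
      if (ra == rb) next
      ## elder rule: the later-born root dies; ties -> larger birth vertex dies
      if (birth[ra] < birth[rb] ||
          (birth[ra] == birth[rb] && birth_v[ra] < birth_v[rb])) {
        elder <- ra; young <- rb
      } else {
        elder <- rb; young <- ra
      }
      b_dim <- c(b_dim, 0L); b_birth <- c(b_birth, birth[young])
      b_death <- c(b_death, filt[j])
      b_gen[[length(b_gen) + 1L]] <- list(birth_v[young])
      parent[young] <- elder
    }
  }
  for (i in seq_len(nv)) {
    if (alive[i] && find(i) == i) {
      b_dim <- c(b_dim, 0L); b_birth <- c(b_birth, birth[i]); b_death <- c(b_death, Inf)
      b_gen[[length(b_gen) + 1L]] <- list(birth_v[i])
    }
  }
  barcode(b_dim, b_birth, b_death, max_filter = max(fc$filt), generators = b_gen)
}

## GF(2) symmetric difference of two sorted integer vectors.
xor_cols <- function(a, b) {
  both <- c(a, b)
  both <- sort(both)
  dup <- both[duplicated(both)]
  setdiff(both, dup)
}

#' Persistence by boundary-matrix reduction over GF(2)
#'
#' Standard column reduction of the boundary matrix under the
#' (filter value, dimension, lexicographic) total order, returning intervals
#' for homology dimensions 0..\code{max_dim} together with representative
#' cycles: for a finite interval, the reduced boundary column at the death
#' event; for an infinite interval, the surviving cycle accumulated in the
#' reduction's basis-change column. Representatives are not unique as
#' cycles; the fixed simplex order makes the reported ones deterministic.
#'
#' @param fc A \code{\link{filtered_complex}} (validated first).
#' @param max_dim Largest homology dimension to report (default: largest
#'   simplex dimension present).
#' @return A \code{\link{barcode}} with generators.
#' @export
reduce_matrix <- function(fc, max_dim = NULL) {
  if (!inherits(fc, "filtered_complex")) ts_error("data_error", "fc must be a filtered_complex")
  validate_complex(fc)
  if (is.null(max_dim)) max_dim <- max(fc$dim)

  ord <- order_simplices(fc)
  verts <- fc$verts[ord]; dims <- fc$dim[ord]; filt <- fc$filt[ord]
  m <- length(verts)
  keys <- simplex_keys(verts)
  col_of_key <- stats::setNames(seq_len(m), keys)

  Rcols <- vector("list", m)   # reduced columns (row index sets)
  Vcols <- vector("list", m)   # basis-change columns (column index sets)
  low_owner <- integer(m)      # low row -> owning column (0 = none)
  paired_with <- integer(m)    # creator row -> destroyer column

  for (j in seq_len(m)) {
    v <- verts[[j]]
    if (length(v) == 1L) {
      R <- integer(0)
    } else {
      face_keys <- vapply(seq_along(v), function(drop)
        paste(v[-drop], collapse = "-"), character(1))
      R <- sort(unname(col_of_key[face_keys]))
    }
    V <- j
    while (length(R) > 0L) {
      lo <- R[length(R)]
      k <- low_owner[lo]
      if (k == 0L) break
      R <- xor_cols(R, Rcols[[k]])
      V <- xor_cols(V, Vcols[[k]])
    }
    Vcols[[j]] <- V
    if (length(R) > 0L) {
      Rcols[[j]] <- R
      lo <- R[length(R)]
      low_owner[lo] <- j
      paired_with[lo] <- j
    }
  }

  b_dim <- integer(0); b_birth <- numeric(0); b_death <- numeric(0)
  b_gen <- list()
  for (i in seq_len(m)) {
    creates <- is.null(Rcols[[i]])  # reduced to zero => creates a class
    if (!creates) next
    d <- dims[i]
    if (d > max_dim) next
    j <- paired_with[i]
    if (j > 0L) {
      b_dim <- c(b_dim, d); b_birth <- c(b_birth, filt[i]); b_death <- c(b_death, filt[j])
      b_gen[[length(b_gen) + 1L]] <- verts[Rcols[[j]]]
    } else {
      b_dim <- c(b_dim, d); b_birth <- c(b_birth, filt[i]); b_death <- c(b_death, Inf)
      b_gen[[length(b_gen) + 1L]] <- verts[Vcols[[i]]]
    }
  }
  barcode(b_dim, b_birth, b_death, max_filter = max(fc$filt), generators = b_gen)
}

#' Betti numbers at a filtration time
#'
#' Counts, for each homology dimension, the intervals alive at \code{t}:
#' those with birth <= t < death.
#'
#' @param bc A \code{\link{barcode}}.
#' @param t Filtration time.
#' @param max_dim Report dimensions 0..\code{max_dim} (default: largest
#'   dimension in the barcode, or 0 for an empty one).
#' @return Named integer vector \code{c(b0 = ..., b1 = ..., ...)}.
#' @export
betti_at <- function(bc, t, max_dim = NULL) {
  if (!inherits(bc, "barcode")) ts_error("data_error", "bc must be a barcode")
  iv <- bc$intervals
  if (is.null(max_dim)) max_dim <- if (nrow(iv)) max(iv$dim) else 0L
  counts <- vapply(0:max_dim, function(d)
    sum(iv$dim == d & iv$birth <= t & t < iv$death), integer(1))
  stats::setNames(counts, paste0("b", 0:max_dim))
}
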