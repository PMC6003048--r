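test_that("piecewise filtration reproduces the three-point worked example", {
  fc <- piecewise_filtration(c(0, 2, 1))
  expect_identical(fc$dim, c(0L, 0L, 0L, 1L, 1L))
  ## vertex filter values f(v0)=0, f(v1)=2, f(v2)=1
  expect_identical(fc$filt[1:3], c(0, 2, 1))
  ## both edges enter at 2
  expect_identical(fc$filt[4:5], c(2, 2))
  expect_identical(filter_values(fc), c(0, 1, 2))
  expect_silent(validate_complex(fc))
})

test_that("piecewise filtration size, constants and edge rule", {
  const <- piecewise_filtration(rep(3.5, 7))
  expect_identical(length(const$verts), 13L)  # 2N - 1
  expect_identical(unique(const$filt), 3.5)

  set.seed(5)
  for (rep_i in 1:20) {
    y <- random_signal(sample(2:40, 1))
    fc <- piecewise_filtration(y)
    n <- length(y)
    expect_identical(length(fc$verts), 2L * n - 1L)
    ## brute-force max over endpoint pairs
    for (k in seq_len(n - 1L))
      expect_identical(fc$filt[n + k], max(y[k], y[k + 1L]))
    expect_silent(validate_complex(fc))
  }

  incr <- piecewise_filtration(c(1, 2, 5, 9))
  expect_identical(incr$filt[5:7], c(2, 5, 9))  # edge k enters with y[k+1]

  expect_error(piecewise_filtration(c(1, Inf)), class = "toposeize_data_error")
})

test_that("standardized Euclidean distance matches hand evaluation and is symmetric", {
  ## 3 channels, N = 2: A=(0,0), B=(1,1), C=(2,2); s_k = 1 at both positions
  rec <- make_recording(cbind(c(0, 0), c(1, 1), c(2, 2)))
  dm <- standardized_euclidean(rec)
  expect_equal(dm["1", "2"], sqrt(2))
  expect_equal(dm["1", "3"], 2 * sqrt(2))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c("1" = 0, "2" = 0, "3" = 0))

  ## identical channels at every position -> degenerate
  expect_error(standardized_euclidean(make_recording(cbind(1:3, 1:3))),
               class = "toposeize_degenerate_position_error")

  ## permuting channels permutes rows/columns identically
  set.seed(3)
  mat <- matrix(rnorm(5 * 4), nrow = 5)
  dm1 <- standardized_euclidean(make_recording(mat))
  dm2 <- standardized_euclidean(make_recording(mat[, c(3, 1, 4, 2)]))
  expect_equal(unname(dm2), unname(dm1[c(3, 1, 4, 2), c(3, 1, 4, 2)]))

  ## consistency limit: channels pre-divided by s_k have unit per-position
  ## sd, so standardizing again is a no-op and the result is the plain
  ## Euclidean distance of the pre-divided coordinates
  s_k <- apply(mat, 1, sd)
  dm3 <- standardized_euclidean(make_recording(mat / s_k))
  expect_equal(unname(dm3), unname(as.matrix(dist(t(mat / s_k)))))
})

test_that("Vietoris-Rips obeys the diameter rule and simplex counts", {
  dm <- matrix(c(0, 3, 3, 0), 2)
  fc <- vietoris_rips(dm, r_max = 3, max_dim = 1)
  expect_identical(fc$dim, c(0L, 0L, 1L))
  expect_identical(fc$filt, c(0, 0, 3))

  ## equilateral triangle: the 2-simplex enters at the side length
  s <- 2.5
  dm <- matrix(s, 3, 3); diag(dm) <- 0
  fc <- vietoris_rips(dm, max_dim = 1)
  tri <- which(fc$dim == 2L)
  expect_length(tri, 1L)
  expect_identical(fc$filt[tri], s)

  ## complete complex counts: C(n,1) + C(n,2) + C(n,3) at max_dim = 1
  set.seed(8)
  pts <- matrix(runif(6 * 2), ncol = 2)
  dm <- as.matrix(dist(pts))
  fc <- vietoris_rips(dm, r_max = max(dm), max_dim = 1)
  expect_identical(length(fc$verts),
                   as.integer(choose(6, 1) + choose(6, 2) + choose(6, 3)))
  expect_silent(validate_complex(fc))

  expect_error(vietoris_rips(matrix(c(0, 1, 2, 0), 2)),
               class = "toposeize_data_error")
})

test_that("Vietoris-Rips is monotone in r_max", {
  set.seed(13)
  pts <- matrix(runif(7 * 3), ncol = 3)
  dm <- as.matrix(dist(pts))
  rs <- sort(sample(dm[upper.tri(dm)], 3))
  keys <- function(fc) paste(vapply(fc$verts, paste, character(1), collapse = "-"),
                             fc$filt)
  for (i in 1:2) {
    small <- keys(vietoris_rips(dm, r_max = rs[i], max_dim = 2))
    big <- keys(vietoris_rips(dm, r_max = rs[i + 1], max_dim = 2))
    expect_true(all(small %in% big))
  }
})

test_that("complex export writes the documented line format", {
  fc <- piecewise_filtration(c(0, 2, 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_complex(fc, path)
  lines <- readLines(path)
  expect_length(lines, 5L)
  expect_identical(lines[1L], "0 1 0")
  expect_identical(lines[4L], "1 1 2 2")
})

test_that("validator rejects broken complexes", {
  expect_error(filtered_complex(list(1, c(1, 2)), c(0, 1)),
               class = "toposeize_data_error")   # missing vertex 2
  expect_error(filtered_complex(list(1, 2, c(1, 2)), c(0, 5, 1)),
               class = "toposeize_data_error")   # face after coface
  expect_error(filtered_complex(list(1, 1), c(0, 0)),
               class = "toposeize_data_error")   # duplicate simplex
})
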