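# Lay n abundance rows out as a (1, 1, n) field and mix them noiselessly.
make_stack <- function(X, refs, voxel_size = c(1, 1, 1)) {
  ab <- array(0, dim = c(1, 1, nrow(X), ncol(X)))
  ab[1, 1, , ] <- X
  stack_from_abundances(ab, refs, voxel_size)
}

stack_from_spectra_rows <- function(S, refs) {
  arr <- array(0, dim = c(1, 1, nrow(S), ncol(S)))
  arr[1, 1, , ] <- S
  lambda_stack(arr, attr(refs, "bin_centers"), c(1, 1, 1))
}

test_that("single-source and zero voxels unmix exactly", {
  refs <- default_spectra()
  X <- rbind(c(0, 0, 0, 5, 0, 0),    # 5 x Cy3 fingerprint
             rep(0, 6))
  um <- linear_unmix(make_stack(X, refs), refs)
  expect_equal(as.numeric(um$abundances[1, 1, 1, ]), c(0, 0, 0, 5, 0, 0),
               tolerance = 1e-8)
  expect_equal(as.numeric(um$abundances[1, 1, 2, ]), rep(0, 6))
  expect_equal(as.numeric(um$residual), c(0, 0), tolerance = 1e-8)
})

test_that("noiseless random mixtures are recovered to 1e-6 relative error", {
  refs <- default_spectra()
  set.seed(11)
  n <- 1000
  X <- matrix(rexp(n * 6, rate = 1 / 50), n, 6)
  st <- make_stack(X, refs)
  for (nonneg in c(TRUE, FALSE)) {
    um <- linear_unmix(st, refs, nonnegative = nonneg)
    got <- um$abundances[1, 1, , ]
    rel <- abs(got - X) / pmax(X, 1e-9)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("nonnegative solutions match an independent dense NNLS solver", {
  refs <- default_spectra()
  B <- t(unclass(refs))
  set.seed(21)
  n <- 400
  X <- matrix(rexp(n * 6, 1 / 30) * rbinom(n * 6, 1, 0.4), n, 6)
  S <- pmax(X %*% t(B) + matrix(rnorm(n * 32, sd = 0.5), n, 32), 0)
  um <- linear_unmix(stack_from_spectra_rows(S, refs), refs,
                     nonnegative = TRUE)
  got <- um$abundances[1, 1, , ]
  for (i in seq(1, n, by = 4)) {
    oracle <- pracma::lsqnonneg(B, S[i, ])$x
    expect_equal(unname(got[i, ]), oracle, tolerance = 1e-6)
  }
})

test_that("unmixing is homogeneous and permutation-equivariant", {
  refs <- default_spectra()
  set.seed(31)
  X <- matrix(rexp(50 * 6, 1 / 20), 50, 6)
  st <- make_stack(X, refs)
  st3 <- lambda_stack(st$data * 3, st$bin_centers, st$voxel_size)
  um <- linear_unmix(st, refs)
  um3 <- linear_unmix(st3, refs)
  expect_equal(um3$abundances, um$abundances * 3, tolerance = 1e-7)

  perm <- c(4, 1, 6, 2, 5, 3)
  refs_p <- reference_spectra(unclass(refs)[perm, ],
                              rownames(refs)[perm],
                              attr(refs, "bin_centers"))
  um_p <- linear_unmix(st, refs_p)
  expect_equal(um_p$abundances[, , , ], um$abundances[, , , perm],
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("residuals obey the reconstruction bounds", {
  refs <- default_spectra()
  set.seed(41)
  n <- 200
  S <- matrix(abs(rnorm(n * 32, sd = 5)), n, 32)   # unstructured spectra
  st <- stack_from_spectra_rows(S, refs)
  um_n <- linear_unmix(st, refs, nonnegative = TRUE)
  um_u <- linear_unmix(st, refs, nonnegative = FALSE)
  zero_resid <- sqrt(rowSums(S^2) / 32)            # residual of x = 0
  expect_true(all(um_n$residual <= zero_resid + 1e-9))
  expect_true(all(um_u$residual <= um_n$residual + 1e-9))
  expect_true(all(um_n$abundances >= 0))
})

test_that("a flat background column absorbs uniform offsets", {
  refs <- default_spectra()
  X <- matrix(c(0, 0, 0, 40, 0, 0), 1, 6)
  ab <- array(0, dim = c(1, 1, 1, 6)); ab[1, 1, 1, ] <- X
  st <- stack_from_abundances(ab, refs, offset = 6)
  um <- linear_unmix(st, refs, background = TRUE)
  expect_equal(dimnames(um$abundances)[[4]][7], "background")
  expect_equal(as.numeric(um$abundances[1, 1, 1, 1:6]),
               c(0, 0, 0, 40, 0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(um$abundances[1, 1, 1, 7]), 6 * 32,
               tolerance = 1e-6)
  expect_lt(max(um$residual), 1e-8)
})

test_that("grid mismatch and rank deficiency are rejected", {
  refs <- default_spectra()
  st <- make_stack(matrix(1, 1, 6), refs)
  refs_wrong <- toy_spectra(k = 3, nbins = 12)
  expect_error(linear_unmix(st, refs_wrong), "mismatch")

  bad <- unclass(refs)
  bad[3, ] <- 2 * bad[4, ]
  expect_error(reference_spectra(bad, rownames(refs),
                                 attr(refs, "bin_centers")),
               "Alexa532/Cy3|collinear")
})
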