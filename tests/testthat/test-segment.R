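test_that("planted blobs are segmented with their voxel counts", {
  arr <- array(0, dim = c(3, 10, 10))
  arr[1, 1:2, 1:2] <- 5          # 4 voxels
  arr[2, 5:7, 5] <- 7            # 3 voxels
  arr[3, 9, 9:10] <- 9           # 2 voxels
  seg <- segment_channel(arr, threshold = 4, min_size = 1)
  expect_equal(nrow(seg$objects), 3)
  expect_setequal(seg$objects$n_voxels, c(4, 3, 2))
  expect_true(all(arr[unlist(seg$voxels)] >= 4))

  # a threshold above the global maximum finds nothing
  seg0 <- segment_channel(arr, threshold = 100)
  expect_equal(nrow(seg0$objects), 0)
})

test_that("corner contact merges at 26-connectivity but not at 6", {
  arr <- array(0, dim = c(2, 4, 4))
  arr[1, 1, 1] <- 1
  arr[2, 2, 2] <- 1              # diagonal (corner) neighbour in z, y, x
  s26 <- segment_channel(arr, threshold = 1, min_size = 1, connectivity = 26)
  s6 <- segment_channel(arr, threshold = 1, min_size = 1, connectivity = 6)
  expect_equal(nrow(s26$objects), 1)
  expect_equal(nrow(s6$objects), 2)
})

test_that("object measurements follow voxel geometry", {
  arr <- array(0, dim = c(4, 6, 6))
  arr[2:3, 2:3, 2:3] <- 10       # 2x2x2 cube
  seg <- segment_channel(arr, threshold = 5, min_size = 1,
                         voxel_size = c(8.2, 0.2, 0.2))
  m <- measure_objects(seg)
  expect_equal(m$n_voxels, 8)
  expect_equal(m$size_um3, 8 * 8.2 * 0.2 * 0.2)   # 2.624 um^3
  expect_equal(m$footprint_px, 4)

  arr1 <- array(0, dim = c(2, 3, 3))
  arr1[1, 2, 2] <- 1
  seg1 <- segment_channel(arr1, threshold = 1, min_size = 1)
  expect_equal(seg1$objects$n_voxels, 1)
  expect_equal(seg1$objects$footprint_px, 1)
})

test_that("labeling agrees with a flood-fill oracle on exhaustive tiny arrays", {
  # all 256 binary 2x2x2 arrays (exhaustive) at both connectivities
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    arr <- array(bits, dim = c(2, 2, 2))
    for (conn in c(6, 26)) {
      seg <- segment_channel(array(as.numeric(arr), dim = dim(arr)),
                             threshold = 1, min_size = 1,
                             connectivity = conn)
      oracle <- flood_fill_oracle(arr == 1, conn)
      expect_identical(canon_components(seg$voxels), oracle)
    }
  }
})

test_that("labeling agrees with the oracle on random 3^3 and 32^3 volumes", {
  set.seed(17)
  for (rep in 1:60) {
    arr <- array(rbinom(27, 1, 0.5), dim = c(3, 3, 3))
    for (conn in c(6, 18, 26)) {
      seg <- segment_channel(array(as.numeric(arr), dim = dim(arr)),
                             threshold = 1, min_size = 1,
                             connectivity = conn)
      expect_identical(canon_components(seg$voxels),
                       flood_fill_oracle(arr == 1, conn))
    }
  }
  for (rep in 1:3) {
    arr <- array(rbinom(32^3, 1, 0.15), dim = c(32, 32, 32))
    for (conn in c(6, 26)) {
      seg <- segment_channel(array(as.numeric(arr), dim = dim(arr)),
                             threshold = 1, min_size = 1,
                             connectivity = conn)
      expect_identical(canon_components(seg$voxels),
                       flood_fill_oracle(arr == 1, conn))
    }
  }
})

test_that("raising the threshold never grows the foreground, and voxels are conserved", {
  set.seed(23)
  arr <- array(rexp(4 * 20 * 20, 1 / 5), dim = c(4, 20, 20))
  prev <- Inf
  for (th in c(2, 5, 10, 20)) {
    seg <- segment_channel(arr, threshold = th, min_size = 3)
    fg_total <- sum(arr >= th)
    counted <- sum(seg$objects$n_voxels)
    expect_lte(fg_total, prev)
    prev <- fg_total
    # counted + small-object + sub-threshold voxels account for every voxel
    all_comps <- segment_channel(arr, threshold = th, min_size = 1)
    discarded <- sum(all_comps$objects$n_voxels) - counted
    expect_equal(counted + discarded + sum(arr < th), length(arr))
  }
})

test_that("object ids are ordered by minimum voxel position", {
  arr <- array(0, dim = c(2, 5, 5))
  arr[2, 5, 5] <- 1
  arr[1, 1, 3] <- 1
  arr[1, 3, 1] <- 1
  seg <- segment_channel(arr, threshold = 1, min_size = 1)
  mins <- t(vapply(seg$voxels, function(v) {
    co <- cxplaque:::vox_coords(v, dim(arr))
    co[1, ]
  }, integer(3)))
  expect_true(!is.unsorted(order(mins[, 1], mins[, 2], mins[, 3])))
  expect_equal(seg$objects$id, 1:3)
})

test_that("degenerate inputs are rejected", {
  expect_error(segment_channel(matrix(1, 3, 3)), "3D")
  expect_error(segment_channel(array(1, dim = c(2, 2, 2)), threshold = -1),
               "threshold")
  expect_error(segment_channel(array(c(1, NA), dim = c(2, 1, 1))), "finite")
})

test_that("otsu thresholding separates a bimodal volume", {
  set.seed(5)
  arr <- array(abs(rnorm(2000, 2, 0.5)), dim = c(5, 20, 20))
  fg <- sample(length(arr), 60)
  arr[fg] <- rnorm(60, 40, 2)
  seg <- segment_channel(arr, threshold = "otsu", min_size = 1)
  expect_true(seg$threshold > 5 && seg$threshold < 38)
  expect_setequal(unlist(seg$voxels), fg)
})
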