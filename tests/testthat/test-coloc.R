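d <- c(2L, 12L, 12L)
vx <- function(z, y, x) cxplaque:::vox_index(z, y, x, d)

test_that("overlapping objects from two channels form one multi-connexin plaque", {
  ch <- list(
    Cx26 = objects_from_voxels(list(vx(1, 2:4, 2)), d, "Cx26"),
    Cx45 = objects_from_voxels(list(vx(1, 4:5, 2)), d, "Cx45"))
  pl <- merge_channels(ch)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$class, "Cx26/Cx45")
  expect_true(pl$Cx26 && pl$Cx45 && !pl$Cx30 && !pl$Cx43)
  expect_equal(pl$n_voxels, 4)          # union of 3 + 2 sharing one voxel
})

test_that("four mutually overlapping channels give the quadruple class", {
  core <- vx(1, 5, 5)
  ch <- lapply(setNames(cxplaque:::CX_CHANNELS, cxplaque:::CX_CHANNELS),
               function(cx) objects_from_voxels(
                 list(c(core, vx(1, 5, 6))), d, cx))
  pl <- merge_channels(ch)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$class, "Cx26/Cx30/Cx43/Cx45")
  expect_equal(pl$n_objects, 4)
})

test_that("disjoint distant objects stay singleton plaques", {
  ch <- list(
    Cx26 = objects_from_voxels(list(vx(1, 1:2, 1)), d, "Cx26"),
    Cx30 = objects_from_voxels(list(vx(1, 8:9, 8)), d, "Cx30"),
    Cx43 = objects_from_voxels(list(vx(2, 3:4, 10)), d, "Cx43"))
  pl <- merge_channels(ch)
  expect_equal(nrow(pl), 3)
  expect_setequal(pl$class, c("Cx26", "Cx30", "Cx43"))
  expect_true(all(pl$n_objects == 1))
})

test_that("the minimum-overlap rule is honoured", {
  a <- vx(1, 2:5, 3)                     # 4 voxels
  b <- c(vx(1, 5, 3), vx(1, 6:7, 3))     # shares exactly 1 voxel with a
  ch <- list(Cx26 = objects_from_voxels(list(a), d, "Cx26"),
             Cx30 = objects_from_voxels(list(b), d, "Cx30"))
  expect_equal(merge_channels(ch, min_overlap = 1)$class, "Cx26/Cx30")
  expect_equal(sort(merge_channels(ch, min_overlap = 2)$class),
               c("Cx26", "Cx30"))
})

test_that("the centroid-distance rule merges nearby objects", {
  a <- vx(1, 2, 2)
  b <- vx(1, 3, 2)                       # centroids 1 um apart at unit voxels
  ch <- list(Cx26 = objects_from_voxels(list(a), d, "Cx26"),
             Cx45 = objects_from_voxels(list(b), d, "Cx45"))
  expect_equal(merge_channels(ch, rule = "centroid_distance",
                              max_distance = 1.5)$class, "Cx26/Cx45")
  expect_equal(sort(merge_channels(ch, rule = "centroid_distance",
                                   max_distance = 0.5)$class),
               c("Cx26", "Cx45"))
})

test_that("merging is a partition and is symmetric in channel order", {
  set.seed(13)
  dd <- c(3L, 24L, 24L)
  chans <- list()
  n_obj <- 0L
  for (cx in cxplaque:::CX_CHANNELS) {
    sets <- lapply(1:6, function(i) {
      z <- sample(3, 1); y <- sample(22, 1); x <- sample(22, 1)
      cxplaque:::vox_index(z, y + 0:1, x, dd)
    })
    chans[[cx]] <- objects_from_voxels(sets, dd, cx)
    n_obj <- n_obj + length(chans[[cx]]$voxels)
  }
  pl <- merge_channels(chans)
  # every per-channel object lands in exactly one plaque
  expect_equal(sum(pl$n_objects), n_obj)
  # class counts over the 15 classes sum to the number of plaques
  counts <- table(factor(pl$class, levels = combination_classes()))
  expect_equal(sum(counts), nrow(pl))

  pl_rev <- merge_channels(rev(chans))
  expect_equal(sort(pl_rev$class), sort(pl$class))
  expect_equal(sort(pl_rev$n_voxels), sort(pl$n_voxels))
})

test_that("overlap merging agrees with a brute-force pairwise oracle", {
  set.seed(29)
  dd <- c(2L, 16L, 16L)
  for (rep in 1:20) {
    chans <- list()
    voxsets <- list()
    owner <- character(0)
    for (cx in cxplaque:::CX_CHANNELS) {
      sets <- lapply(1:3, function(i) {
        y <- sample(15, 1); x <- sample(15, 1); z <- sample(2, 1)
        unique(cxplaque:::vox_index(z, c(y, y + 1), c(x, x), dd))
      })
      chans[[cx]] <- objects_from_voxels(sets, dd, cx)
      voxsets <- c(voxsets, chans[[cx]]$voxels)
      owner <- c(owner, rep(cx, length(chans[[cx]]$voxels)))
    }
    # oracle: union-find over explicit pairwise overlap tests
    n <- length(voxsets)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (owner[i] != owner[j] &&
          length(intersect(voxsets[[i]], voxsets[[j]])) >= 1) {
        parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    oracle_classes <- sort(vapply(split(seq_len(n), roots), function(ix) {
      class_label(unique(owner[ix]))
    }, character(1)))
    pl <- merge_channels(chans)
    expect_equal(sort(pl$class), unname(oracle_classes))
  }
})

test_that("compartment assignment follows the vessel-distance rule", {
  dd <- c(1L, 20L, 20L)
  vessel <- array(FALSE, dim = dd)
  vessel[1, , 10] <- TRUE
  near_set <- cxplaque:::vox_index(1L, 5:6, 9L, dd)     # 1 px from vessel
  far_set <- cxplaque:::vox_index(1L, 5:6, 2L, dd)      # 8 px away
  ch <- list(Cx26 = objects_from_voxels(list(near_set, far_set), dd, "Cx26"))
  pl <- merge_channels(ch)
  pl <- assign_compartment(pl, vessel, max_distance = 2, fraction = 0.5,
                           voxel_size = c(1, 1, 1))
  cent_x <- pl$centroid_x
  expect_equal(pl$compartment[order(cent_x)], c("parenchymal", "vascular"))
})

test_that("an empty vessel mask warns and assigns everything parenchymal", {
  dd <- c(1L, 8L, 8L)
  ch <- list(Cx30 = objects_from_voxels(
    list(cxplaque:::vox_index(1L, 2:3, 2L, dd)), dd, "Cx30"))
  pl <- merge_channels(ch)
  expect_warning(
    pl <- assign_compartment(pl, array(FALSE, dim = dd)),
    "empty vessel mask")
  expect_equal(pl$compartment, "parenchymal")
})

test_that("planted compartments are recovered on noiseless scenes", {
  sc <- small_scene(seed = 19,
                    noise = list(background = 0, poisson_gain = 0,
                                 read_sd = 0, autofluorescence = 0),
                    intensity_cv = 0)
  truth <- build_scene(sc)
  refs <- default_spectra()
  um <- linear_unmix(render_lambda_stack(truth, refs), refs)
  markers <- attr(refs, "markers")
  chans <- list()
  for (cx in cxplaque:::CX_CHANNELS) {
    m <- um$abundances[, , , match(cx, markers), drop = FALSE]
    dim(m) <- truth$field_shape
    chans[[cx]] <- segment_channel(m, threshold = 50, min_size = 1,
                                   voxel_size = truth$voxel_size)
  }
  pl <- merge_channels(chans)
  pl <- assign_compartment(pl, truth$vessel_mask,
                           max_distance = sc$compartment$max_distance,
                           fraction = sc$compartment$fraction)
  expect_equal(nrow(pl), nrow(truth$plaques))
  # match detected plaques to planted ones by centroid and compare labels
  for (i in seq_len(nrow(pl))) {
    dist2 <- (truth$plaques$centroid_y - pl$centroid_y[i])^2 +
      (truth$plaques$centroid_x - pl$centroid_x[i])^2 +
      (truth$plaques$centroid_z - pl$centroid_z[i])^2
    j <- which.min(dist2)
    expect_equal(pl$compartment[i], truth$plaques$compartment[j])
    expect_equal(pl$class[i], truth$plaques$class[j])
  }
})
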