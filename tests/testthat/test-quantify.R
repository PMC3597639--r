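fake_field <- function(n_par, n_vasc, size = 5) {
  k <- n_par + n_vasc
  data.frame(class = rep("Cx30", k),
             compartment = rep(c("parenchymal", "vascular"),
                               c(n_par, n_vasc)),
             n_voxels = rep(size, k))
}

test_that("field aggregation averages counts over all fields", {
  plan <- sampling_plan()
  info <- expand.grid(field = 1:8,
                      region = c("central", "midperipheral", "peripheral"),
                      stringsAsFactors = FALSE)
  tables <- replicate(24, fake_field(10, 0), simplify = FALSE)
  agg <- aggregate_fields(tables, info, plan)
  row <- agg[agg$class == "Cx30" & agg$compartment == "parenchymal", ]
  expect_equal(row$mean_count_per_field, 10)
  expect_equal(row$mean_size_voxels, 5)
  # all other class cells are present with zero counts
  expect_equal(nrow(agg), 30)
  expect_equal(sum(agg$mean_count_per_field), 10)

  tables2 <- lapply(1:24, function(i) fake_field(i, 0))
  agg2 <- aggregate_fields(tables2, info, plan)
  expect_equal(agg2$mean_count_per_field[agg2$class == "Cx30" &
                                           agg2$compartment == "parenchymal"],
               mean(1:24))
})

test_that("missing fields are reported by (region, index)", {
  plan <- sampling_plan()
  info <- expand.grid(field = 1:8,
                      region = c("central", "midperipheral", "peripheral"),
                      stringsAsFactors = FALSE)[-c(3, 20), ]
  tables <- replicate(22, fake_field(1, 0), simplify = FALSE)
  expect_error(aggregate_fields(tables, info, plan),
               "missing fields of view.*central, 3")
})

test_that("density-to-total conversion is exact and linear", {
  expect_equal(density_to_total(10, 50), 500)
  expect_equal(density_to_total(0, 123), 0)
  expect_equal(density_to_total(3 * 7, 2), 3 * density_to_total(7, 2))
  expect_error(density_to_total(-1, 5))
})

test_that("vessel surface area matches the closed form for a cylinder", {
  tube <- data.frame(z0 = 25, y0 = 0, x0 = 25,
                     z1 = 25, y1 = 1000, x1 = 25, radius = 5)
  expect_equal(vessel_surface_area(tube), 2 * pi * 5 * 1000 / 1e6,
               tolerance = 1e-12)   # 0.0314159 mm^2

  # mask-based estimate at fine isotropic voxels within 5% of closed form
  d <- c(50L, 80L, 50L)
  vs <- c(1, 1, 1)
  mask <- cxplaque:::tube_mask(d, vs, data.frame(
    z0 = 25, y0 = 0, x0 = 25, z1 = 25, y1 = 80, x1 = 25, radius = 5))
  est <- vessel_surface_area(mask, vs)
  expect_equal(est, 2 * pi * 5 * 80 / 1e6, tolerance = 0.05)

  expect_warning(e0 <- vessel_surface_area(tube[0, ]), "empty")
  expect_equal(e0, 0)
  expect_warning(em <- vessel_surface_area(array(FALSE, dim = c(2, 2, 2)),
                                           c(1, 1, 1)), "empty")
  expect_equal(em, 0)
})

test_that("percent change truncates toward zero and keeps the raw value", {
  expect_equal(percent_change(100, 300)$percent, 200)
  expect_equal(percent_change(5, 5)$percent, 0)
  expect_equal(percent_change(100, 47.33)$percent, -52)   # -52.67 -> -52
  expect_equal(percent_change(100, 522.96)$percent, 422)  # +422.96 -> +422
  expect_error(percent_change(0, 10), "baseline")
  expect_error(percent_change(-2, 10), "baseline")

  # reciprocal relation of the raw (untruncated) values
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    pab <- percent_change(a, b)$percent_raw
    pba <- percent_change(b, a)$percent_raw
    expect_equal((1 + pab / 100) * (1 + pba / 100), 1, tolerance = 1e-12)
  }
})

test_that("the printed totals table reproduces its printed percentages", {
  tab <- percent_change_table(table2_totals())
  expect_equal(nrow(tab), 30)
  expect_equal(sort(unique(tab$compartment)), c("parenchymal", "vascular"))

  integer_rows <- tab$printed_percent == trunc(tab$printed_percent)
  # two known printing anomalies: the homotypic Cx30 parenchymal row
  # (raw +635.69, printed 636 -- rounding, not truncation) and the
  # Cx30/Cx43 vascular row (printed 71, but its own totals imply +43)
  anomaly <- (tab$class == "Cx30" & tab$compartment == "parenchymal") |
    (tab$class == "Cx30/Cx43" & tab$compartment == "vascular")
  consistent <- integer_rows & !anomaly
  expect_equal(tab$percent[consistent], tab$printed_percent[consistent])
  expect_equal(sum(consistent), 25)

  # the anomalies still satisfy the arithmetic on their printed totals
  expect_equal(tab$percent_raw[tab$class == "Cx30" &
                                 tab$compartment == "parenchymal"],
               635.6865, tolerance = 1e-6)
  expect_equal(tab$percent_raw[tab$class == "Cx30/Cx43" &
                                 tab$compartment == "vascular"],
               43.38128, tolerance = 1e-6)
  # fractional-print rows match to the printed decimal
  frac <- !integer_rows
  expect_equal(sum(frac), 3)
  expect_lt(max(abs(tab$percent_raw[frac] - tab$printed_percent[frac])), 0.06)
})

test_that("number-times-size and group summaries behave", {
  expect_equal(number_times_size(100, 5), 500)
  expect_equal(number_times_size(0, 7), 0)
  g <- group_mean_sem(c(2, 4, 6, 8))
  expect_equal(g$mean, 5)
  expect_equal(g$sem, sd(c(2, 4, 6, 8)) / 2)
  expect_equal(g$n, 4)
})
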