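#' Field-of-view sampling plan
#'
#' The study design this package models: per retina, eight fields of view in
#' each of three retinal regions (central, midperipheral, peripheral; 24
#' fields total), four retinas per age group, ages 3, 9 and 22 months.
#'
#' @param regions region names.
#' @param fields_per_region fields of view sampled per region.
#' @param retinas_per_group retinas (animals) per age group.
#' @param age_groups ages in months.
#' @return object of class \code{sampling_plan}.
#' @export
sampling_plan <- function(regions = c("central", "midperipheral", "peripheral"),
                          fields_per_region = 8L,
                          retinas_per_group = 4L,
                          age_groups = c(3L, 9L, 22L)) {
  stopifnot(length(regions) >= 1, fields_per_region >= 1,
            retinas_per_group >= 1, length(age_groups) >= 1)
  structure(list(regions = regions,
                 fields_per_region = as.integer(fields_per_region),
                 retinas_per_group = as.integer(retinas_per_group),
                 age_groups = age_groups),
            class = "sampling_plan")
}

#' Aggregate per-field plaque tables into per-retina summaries
#'
#' Per (compartment, class): the unweighted mean plaque count per field over
#' all fields of the retina, and the mean plaque size (voxels) over that
#' retina's plaques. Every (region, field index) cell of the sampling plan
#' must be present.
#'
#' @param field_tables list of per-field plaque tables (as returned by
#'   \code{\link{assign_compartment}}: columns \code{class},
#'   \code{compartment}, \code{n_voxels}), each element named or accompanied
#'   by \code{field_info}.
#' @param field_info data.frame with one row per element of
#'   \code{field_tables}: columns \code{region}, \code{field}.
#' @param plan a \code{\link{sampling_plan}}.
#' @return data.frame: \code{compartment}, \code{class},
#'   \code{mean_count_per_field}, \code{mean_size_voxels},
#'   \code{n_fields}; every (compartment, 15-class) combination is present
#'   (zero counts included), so downstream sums conserve totals.
#' @export
aggregate_fields <- function(field_tables, field_info, plan = sampling_plan()) {
  stopifnot(is.list(field_tables), nrow(field_info) == length(field_tables),
            all(c("region", "field") %in% names(field_info)))
  want <- expand.grid(region = plan$regions,
                      field = seq_len(plan$fields_per_region),
                      stringsAsFactors = FALSE)
  have <- paste(field_info$region, field_info$field)
  missing <- want[!paste(want$region, want$field) %in% have, , drop = FALSE]
  if (nrow(missing)) {
    stop("missing fields of view: ",
         paste(sprintf("(%s, %d)", missing$region, missing$field),
               collapse = ", "))
  }
  n_fields <- nrow(field_info)

  grid <- expand.grid(compartment = COMPARTMENTS,
                      class = combination_classes(),
                      stringsAsFactors = FALSE)
  all_pl <- do.call(rbind, lapply(field_tables, function(tb) {
    tb[, c("class", "compartment", "n_voxels"), drop = FALSE]
  }))
  counts <- sizes <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- all_pl$class == grid$class[i] &
      all_pl$compartment == grid$compartment[i]
    counts[i] <- sum(sel) / n_fields
    sizes[i] <- if (any(sel)) mean(all_pl$n_voxels[sel]) else NA_real_
  }
  data.frame(grid, mean_count_per_field = counts,
             mean_size_voxels = sizes, n_fields = n_fields)
}

#' Convert a density to a per-retina total
#'
#' Parenchymal densities (plaques per mm^2 of retina) scale by total retinal
#' area; vascular densities (per mm^2 of vessel surface) by total vessel
#' surface area. Exactly linear in both arguments.
#'
#' @param density count per mm^2 (nonnegative).
#' @param area mm^2 (nonnegative).
#' @return total count per retina, \code{density * area}.
#' @export
density_to_total <- function(density, area) {
  stopifnot(all(density >= 0), all(area >= 0))
  density * area
}

#' Vessel surface area
#'
#' From a tube specification, the analytic lateral area (sum of
#' 2*pi*r*L over segments); from a binary mask, a coarea-formula surface
#' estimate of the mask boundary (gradient magnitude of the smoothed
#' indicator integrated over the volume).
#'
#' @param x a vessel tube data.frame (\code{z0,y0,x0,z1,y1,x1,radius}, um) or
#'   a logical 3D mask.
#' @param voxel_size um per voxel (z, y, x); required for masks.
#' @return surface area in mm^2.
#' @export
vessel_surface_area <- function(x, voxel_size = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) {
      warning("empty vessel geometry: surface area 0")
      return(0)
    }
    L <- sqrt((x$z1 - x$z0)^2 + (x$y1 - x$y0)^2 + (x$x1 - x$x0)^2)
    return(sum(2 * pi * x$radius * L) / 1e6)
  }
  stopifnot(is.array(x), length(dim(x)) == 3, !is.null(voxel_size))
  if (!any(x)) {
    warning("empty vessel mask: surface area 0")
    return(0)
  }
  mask_surface_area(x, voxel_size) / 1e6
}

#' Percent change between two per-retina totals
#'
#' \code{100 * (v_end - v_start) / v_start}, reported both as the raw value
#' and truncated toward zero to a signed integer, the rounding convention
#' that matches the printed percent-change table this reproduces (see the
#' methods vignette for the two printed values that follow a different
#' rounding).
#'
#' @param v_start baseline total (> 0).
#' @param v_end endpoint total.
#' @return list with \code{percent} (signed integer, truncated toward zero)
#'   and \code{percent_raw} (untruncated).
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) {
    stop("undefined baseline: v_start must be > 0")
  }
  raw <- 100 * (v_end - v_start) / v_start
  list(percent = trunc(raw), percent_raw = raw)
}

#' Number-times-size product index
#'
#' Elementwise product of plaque count and mean plaque size, the combined
#' abundance index plotted per connexin, age and compartment.
#'
#' @param count plaque counts (or totals).
#' @param mean_size mean plaque sizes (voxels).
#' @return elementwise product.
#' @export
number_times_size <- function(count, mean_size) {
  stopifnot(length(count) == length(mean_size))
  count * mean_size
}

#' Group-level summary across retinas
#'
#' Means +/- SEM over retinas per age group for a per-retina summary metric;
#' SEM uses n = number of retinas.
#'
#' @param retina_values numeric vector, one value per retina.
#' @return list \code{mean}, \code{sem}, \code{n}.
#' @export
group_mean_sem <- function(retina_values) {
  n <- length(retina_values)
  list(mean = mean(retina_values),
       sem = if (n > 1) sd(retina_values) / sqrt(n) else NA_real_,
       n = n)
}

#' Printed per-retina totals of the modeled quantification table
#'
#' The published 3-to-22-month total-per-retina pairs for all 15 combination
#' classes in both compartments, shipped as package data so the percent-
#' change arithmetic can be re-run against the printed values, together with
#' the printed signed percent for each row.
#'
#' @return data.frame: \code{class}, \code{compartment}, \code{total_3mo},
#'   \code{total_22mo}, \code{printed_percent} (signed, as printed).
#' @export
table2_totals <- function() {
  path <- system.file("extdata", "printed_totals_3_22mo.csv",
                      package = "cxplaque")
  if (path == "") path <- "inst/extdata/printed_totals_3_22mo.csv"
  read.csv(path, stringsAsFactors = FALSE)
}

#' Percent-change table in the printed layout
#'
#' Applies \code{\link{percent_change}} to per-class 3-month and 22-month
#' totals per compartment, emitting both truncated and raw percents.
#'
#' @param totals data.frame with columns \code{class}, \code{compartment},
#'   \code{total_3mo}, \code{total_22mo}.
#' @return the input with \code{percent} and \code{percent_raw} columns.
#' @export
percent_change_table <- function(totals) {
  pc <- percent_change(totals$total_3mo, totals$total_22mo)
  totals$percent <- pc$percent
  totals$percent_raw <- pc$percent_raw
  totals
}
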