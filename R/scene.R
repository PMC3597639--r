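#' Configuration of a synthetic wholemount field of view
#'
#' Describes one nerve-fibre-layer field: voxel grid, vessel tubes, stellate
#' GFAP astrocytes, planted gap-junction plaques per combination class and
#' compartment, fluorophore intensities and noise. Defaults model the
#' acquisition geometry of the study this package emulates: 512 x 512 pixel
#' frames, a thin z-range of 8.2 um optical slices, six fluorophores over a
#' 32-bin 411-754 nm lambda stack. The xy pixel pitch is an assumption
#' (0.28 um, a typical 63x/1.4 oil configuration) since only the slice
#' thickness is fixed by the acquisition description.
#'
#' @param field_shape integer (z, y, x) voxel counts.
#' @param voxel_size um per voxel in (z, y, x).
#' @param vessel_spec data.frame of tube segments with columns
#'   \code{z0,y0,x0,z1,y1,x1,radius} (um), or NULL for an avascular field.
#' @param astrocyte_spec list: \code{count}, \code{soma_radius} (um),
#'   \code{process_count}, \code{process_length} (um).
#' @param plaque_means named list \code{parenchymal}, \code{vascular}; each a
#'   named numeric vector of expected plaque counts per combination class
#'   (names from \code{\link{combination_classes}}; absent classes mean 0).
#' @param plaque_size list \code{meanlog}, \code{sdlog} (log-normal voxel
#'   count), \code{min_voxels}, \code{max_voxels}.
#' @param plaque_intensity named numeric, mean abundance (photon-scale a.u.)
#'   contributed by each labeled connexin; \code{intensity_cv} its
#'   coefficient of variation across plaques.
#' @param intensity_cv see \code{plaque_intensity}.
#' @param marker_intensity named numeric for \code{"GS-lectin"} and
#'   \code{"GFAP"} structural channels.
#' @param noise list: \code{background} (flat offset per spectral bin),
#'   \code{poisson_gain} (0 disables shot noise), \code{read_sd} (Gaussian
#'   read noise sd), \code{autofluorescence} (flat tissue glow per bin).
#' @param compartment list: \code{max_distance} (um from vessel surface
#'   within which a plaque is vascular), \code{fraction} (minimum fraction of
#'   plaque voxels within that distance), \code{parenchymal_margin} (extra
#'   clearance, um, required when planting parenchymal plaques so planted
#'   labels are unambiguous).
#' @param n_bins,spectral_range lambda-stack bin grid.
#' @param allow_overlap permit planted plaques to overlap each other.
#' @param seed integer seed owning all randomness of this field.
#' @return object of class \code{scene_config} (a validated list).
#' @export
scene_config <- function(field_shape = c(3L, 512L, 512L),
                         voxel_size = c(8.2, 0.28, 0.28),
                         vessel_spec = NULL,
                         astrocyte_spec = list(count = 6, soma_radius = 4,
                                               process_count = 6,
                                               process_length = 25),
                         plaque_means = default_plaque_means(),
                         plaque_size = list(meanlog = log(5), sdlog = 0.5,
                                            min_voxels = 2, max_voxels = 30),
                         plaque_intensity = c(Cx26 = 120, Cx30 = 120,
                                              Cx43 = 120, Cx45 = 120),
                         intensity_cv = 0.25,
                         marker_intensity = c("GS-lectin" = 90, GFAP = 70),
                         noise = list(background = 4, poisson_gain = 1,
                                      read_sd = 2, autofluorescence = 2),
                         compartment = list(max_distance = 2, fraction = 0.5,
                                            parenchymal_margin = 3),
                         n_bins = 32L, spectral_range = c(411, 754),
                         allow_overlap = FALSE,
                         seed = 1L) {
  field_shape <- as.integer(field_shape)
  stopifnot(length(field_shape) == 3, all(field_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            plaque_size$min_voxels >= 1,
            plaque_size$max_voxels >= plaque_size$min_voxels,
            all(plaque_intensity > noise$background),
            noise$background >= 0, noise$read_sd >= 0,
            noise$poisson_gain >= 0, noise$autofluorescence >= 0,
            compartment$max_distance >= 0,
            compartment$fraction > 0, compartment$fraction <= 1)
  if (is.null(vessel_spec)) {
    vessel_spec <- default_vessel_spec(field_shape, voxel_size)
  }
  if (nrow(vessel_spec) > 0) {
    stopifnot(all(c("z0", "y0", "x0", "z1", "y1", "x1", "radius") %in%
                    names(vessel_spec)),
              all(vessel_spec$radius > 0))
  }
  for (comp in COMPARTMENTS) {
    pm <- plaque_means[[comp]]
    if (length(pm) > 0) {
      stopifnot(!is.null(names(pm)), all(pm >= 0))
      bad <- setdiff(names(pm), combination_classes())
      if (length(bad)) stop("unknown combination class: ",
                            paste(bad, collapse = ", "))
    }
  }
  stopifnot(astrocyte_spec$count >= 0, astrocyte_spec$soma_radius > 0,
            astrocyte_spec$process_length > 0)
  structure(list(field_shape = field_shape, voxel_size = as.numeric(voxel_size),
                 vessel_spec = vessel_spec, astrocyte_spec = astrocyte_spec,
                 plaque_means = plaque_means, plaque_size = plaque_size,
                 plaque_intensity = plaque_intensity,
                 intensity_cv = intensity_cv,
                 marker_intensity = marker_intensity, noise = noise,
                 compartment = compartment,
                 bin_centers = lambda_bin_centers(n_bins, spectral_range),
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Two straight vessels crossing the field along y (an artery/vein pair, as
# nerve-fibre-layer fields typically contain superficial vessel branches),
# at one and two thirds of the x extent, mid z.
default_vessel_spec <- function(field_shape, voxel_size) {
  ylen <- field_shape[2] * voxel_size[2]
  xlen <- field_shape[3] * voxel_size[3]
  zmid <- field_shape[1] * voxel_size[1] / 2
  data.frame(z0 = zmid, y0 = 0, x0 = c(xlen / 3, 2 * xlen / 3),
             z1 = zmid, y1 = ylen, x1 = c(xlen / 3, 2 * xlen / 3),
             radius = 4)
}

#' Default expected plaque counts per class and compartment
#'
#' Per-field means whose relative proportions follow the young-adult pattern
#' of the modeled system: homomeric/homotypic classes dominate (Cx26 most
#' abundant, then Cx30, Cx43, Cx45) and multi-connexin classes are roughly
#' two orders of magnitude rarer, mirroring the ratio of homotypic to
#' heterogeneous totals in the modeled quantification.
#'
#' @return named list with \code{parenchymal} and \code{vascular} named
#'   numeric vectors of expected counts per field of view.
#' @export
default_plaque_means <- function() {
  pairs <- combn(CX_CHANNELS, 2, paste, collapse = "/")
  triples <- combn(CX_CHANNELS, 3, paste, collapse = "/")
  quad <- paste(CX_CHANNELS, collapse = "/")
  list(
    parenchymal = c(Cx26 = 11, Cx30 = 7, Cx43 = 5, Cx45 = 3,
                    setNames(rep(0.6, 6), pairs),
                    setNames(rep(0.4, 4), triples),
                    setNames(0.3, quad)),
    vascular = c(Cx26 = 3, Cx30 = 4, Cx43 = 2.5, Cx45 = 1,
                 setNames(rep(0.5, 6), pairs),
                 setNames(rep(0.3, 4), triples),
                 setNames(0.2, quad)))
}

#' Build the ground truth of one synthetic field
#'
#' Places vessels, stellate astrocytes and gap-junction plaques in the field.
#' Per (class, compartment) the plaque count is Poisson with the configured
#' mean; each plaque is a small in-plane ellipsoid with a log-normal voxel
#' count. Vascular plaques are planted with every voxel within the
#' compartment rule's \code{max_distance} of the vessel surface; parenchymal
#' plaques are planted clear of the vessel by an extra margin so that planted
#' compartment labels are unambiguous. Deterministic given the config seed.
#'
#' @param config a \code{\link{scene_config}}.
#' @return object of class \code{scene_truth}: list with \code{plaques}
#'   (data.frame: id, class, compartment, centroid um, n_voxels),
#'   \code{plaque_voxels} (list of linear voxel-index vectors),
#'   \code{plaque_intensity} (plaque x connexin abundance matrix),
#'   \code{vessel_mask}, \code{astrocyte_mask}, \code{areas}
#'   (parenchymal_area_mm2, vessel_surface_area_mm2), plus geometry fields.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, build_scene_impl(config))
}

build_scene_impl <- function(config) {
  d <- config$field_shape
  vs <- config$voxel_size
  vessel <- tube_mask(d, vs, config$vessel_spec)
  astro <- astrocyte_mask(d, vs, config$astrocyte_spec, vessel)

  near <- dilate_mask(vessel, vs, config$compartment$max_distance)
  far <- !dilate_mask(vessel, vs, config$compartment$max_distance +
                        config$compartment$parenchymal_margin)
  shell <- near & !vessel
  allowed <- list(vascular = shell, parenchymal = far)
  allowed_idx <- lapply(allowed, which)

  occupied <- array(FALSE, dim = d)
  plaques <- list()
  voxsets <- list()
  id <- 0L
  for (comp in COMPARTMENTS) {
    means <- config$plaque_means[[comp]]
    means <- means[means > 0]
    for (cls in names(means)) {
      n <- rpois(1L, means[[cls]])
      for (i in seq_len(n)) {
        pv <- place_plaque(config, allowed[[comp]], allowed_idx[[comp]],
                           occupied, d)
        if (is.null(pv)) {
          stop(sprintf(
            "placement failure: could not fit a %s '%s' plaque after bounded retries (field too small or too crowded)",
            comp, cls))
        }
        if (!config$allow_overlap) occupied[pv] <- TRUE
        id <- id + 1L
        voxsets[[id]] <- sort(pv)
        co <- vox_coords(pv, d)
        plaques[[id]] <- data.frame(
          id = id, class = cls, compartment = comp,
          centroid_z = mean((co[, "z"] - 0.5) * vs[1]),
          centroid_y = mean((co[, "y"] - 0.5) * vs[2]),
          centroid_x = mean((co[, "x"] - 0.5) * vs[3]),
          n_voxels = length(pv))
      }
    }
  }
  plaques <- if (length(plaques)) do.call(rbind, plaques) else
    data.frame(id = integer(), class = character(), compartment = character(),
               centroid_z = numeric(), centroid_y = numeric(),
               centroid_x = numeric(), n_voxels = integer())

  # per-plaque planted abundance for each member connexin
  inten <- matrix(0, nrow(plaques), length(CX_CHANNELS),
                  dimnames = list(NULL, CX_CHANNELS))
  cv <- config$intensity_cv
  for (i in seq_len(nrow(plaques))) {
    for (cx in class_members(plaques$class[i])) {
      mu <- config$plaque_intensity[[cx]]
      inten[i, cx] <- if (cv > 0) {
        rlnorm(1, log(mu) - 0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))
      } else mu
    }
  }

  areas <- c(
    parenchymal_area_mm2 = prod(d[2:3] * vs[2:3]) / 1e6,
    vessel_surface_area_mm2 = vessel_lateral_area_um2(
      config$vessel_spec, d, vs) / 1e6)

  structure(list(plaques = plaques, plaque_voxels = voxsets,
                 plaque_intensity = inten, vessel_mask = vessel,
                 astrocyte_mask = astro, areas = areas,
                 field_shape = d, voxel_size = vs, config = config),
            class = "scene_truth")
}

# One plaque: log-normal target voxel count realized as a rotated in-plane
# ellipse on one z-slice (slices are 8.2 um apart, far thicker than a
# punctum). Bounded rejection sampling keeps it inside the allowed region
# and off previously placed plaques.
place_plaque <- function(config, allowed_mask, allowed_idx, occupied, d,
                         max_tries = 200L) {
  if (length(allowed_idx) == 0) return(NULL)
  ps <- config$plaque_size
  for (try in seq_len(max_tries)) {
    nv <- round(rlnorm(1, ps$meanlog, ps$sdlog))
    nv <- min(max(nv, ps$min_voxels), ps$max_voxels)
    center <- allowed_idx[sample.int(length(allowed_idx), 1L)]
    co <- vox_coords(center, d)
    ar <- exp(runif(1, log(0.5), log(2)))      # in-plane aspect ratio
    a <- sqrt(nv * ar / pi)
    b <- sqrt(nv / ar / pi)
    pv <- ellipse_voxels(co[1, "z"], co[1, "y"] + runif(1, -0.5, 0.5),
                         co[1, "x"] + runif(1, -0.5, 0.5),
                         a, b, runif(1, 0, pi), d)
    if (is.null(pv)) next
    if (!all(allowed_mask[pv])) next
    # planted plaques must not touch (26-neighbourhood): two unresolvable
    # adjacent puncta are operationally a single plaque, so ground-truth
    # counts would be ill-defined
    if (!config$allow_overlap && any(occupied[expand_neighborhood(pv, d)])) next
    return(pv)
  }
  NULL
}

astrocyte_mask <- function(d, vs, spec, vessel) {
  mask <- array(FALSE, dim = d)
  if (spec$count == 0) return(mask)
  ext <- d * vs
  zmid <- ext[1] / 2
  for (i in seq_len(spec$count)) {
    soma <- c(zmid, runif(1, 0.1, 0.9) * ext[2], runif(1, 0.1, 0.9) * ext[3])
    # soma: filled disk in the central slice
    iz <- pmin(pmax(ceiling(soma[1] / vs[1]), 1L), d[1])
    rpx <- ceiling(spec$soma_radius / vs[2])
    ys <- pmax(1L, ceiling(soma[2] / vs[2]) - rpx):
      pmin(d[2], ceiling(soma[2] / vs[2]) + rpx)
    xs <- pmax(1L, ceiling(soma[3] / vs[3]) - rpx):
      pmin(d[3], ceiling(soma[3] / vs[3]) + rpx)
    for (y in ys) for (x in xs) {
      if (((y - 0.5) * vs[2] - soma[2])^2 + ((x - 0.5) * vs[3] - soma[3])^2 <=
          spec$soma_radius^2) {
        mask[iz, y, x] <- TRUE
      }
    }
    # radiating processes
    for (p in seq_len(spec$process_count)) {
      ang <- runif(1, 0, 2 * pi)
      len <- spec$process_length * runif(1, 0.6, 1.2)
      tip <- soma + c(0, sin(ang), cos(ang)) * len
      tip[2] <- min(max(tip[2], 0.5 * vs[2]), ext[2] - 0.5 * vs[2])
      tip[3] <- min(max(tip[3], 0.5 * vs[3]), ext[3] - 0.5 * vs[3])
      mask <- paint_segment(mask, vs, soma, tip)
    }
  }
  mask
}

# Analytic lateral surface of the vessel tubes, clipped to the field extent
# along the dominant axis of each segment.
vessel_lateral_area_um2 <- function(segments, d, vs) {
  if (is.null(segments) || nrow(segments) == 0) return(0)
  ext <- d * vs
  total <- 0
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    a <- pmin(pmax(c(s$z0, s$y0, s$x0), 0), ext)
    b <- pmin(pmax(c(s$z1, s$y1, s$x1), 0), ext)
    total <- total + 2 * pi * s$radius * sqrt(sum((b - a)^2))
  }
  total
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
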