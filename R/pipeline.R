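#' Configuration of an end-to-end cohort run
#'
#' Bundles everything one pipeline run needs: the per-field scene template,
#' the sampling plan, per-age class-abundance multipliers (the planted aging
#' effect), the whole-retina normalization areas, and the analysis
#' parameters of every stage. Unknown argument names are rejected.
#'
#' @param scene a \code{\link{scene_config}} template for one field of view
#'   (its plaque means are the youngest-age baseline).
#' @param plan a \code{\link{sampling_plan}}; its \code{age_groups} define
#'   the cohort ages.
#' @param age_multipliers named list: one element per age (as character),
#'   each a named numeric vector of per-class multipliers applied to the
#'   baseline plaque means in both compartments (classes absent from the
#'   vector keep multiplier 1).
#' @param retinal_area_mm2 total retinal area used to convert parenchymal
#'   densities to per-retina totals (default 52 mm2, a young-adult rat
#'   retina).
#' @param vessel_area_mm2 total vessel surface area used for vascular
#'   totals (default 15 mm2).
#' @param segmentation list: \code{threshold} ("otsu" or numeric),
#'   \code{min_size}, \code{connectivity}.
#' @param merge list: \code{rule}, \code{min_overlap}, \code{max_distance}.
#' @param compartment list: \code{max_distance}, \code{fraction}.
#' @param spectra \code{"default"} or path to a reference-spectra CSV
#'   (\code{\link{read_spectra_csv}}); must cover all four connexin markers
#'   plus GS-lectin.
#' @param nonnegative use nonnegative unmixing (default TRUE).
#' @param unmix_background include a flat constant-offset fingerprint when
#'   unmixing, absorbing background and autofluorescence (default TRUE; see
#'   \code{\link{linear_unmix}}).
#' @param out_dir output directory for \code{\link{run_pipeline}}.
#' @param save_images also write per-field TIFF stacks (default FALSE; the
#'   tables are the quantitative output).
#' @param seed top-level seed; all per-field randomness is expanded from it.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(scene = scene_config(field_shape = c(3L, 128L, 128L)),
                       plan = sampling_plan(age_groups = c(3L, 22L)),
                       age_multipliers = default_age_multipliers(plan),
                       retinal_area_mm2 = 52,
                       vessel_area_mm2 = 15,
                       segmentation = list(threshold = "otsu_sparse",
                                           min_size = 2L,
                                           connectivity = 26L),
                       merge = list(rule = "voxel_overlap", min_overlap = 1L,
                                    max_distance = 1),
                       compartment = list(max_distance = 2, fraction = 0.5),
                       spectra = "default",
                       nonnegative = TRUE,
                       unmix_background = TRUE,
                       out_dir = tempfile("cxplaque_run_"),
                       save_images = FALSE,
                       seed = 1L) {
  stopifnot(inherits(scene, "scene_config"), inherits(plan, "sampling_plan"),
            retinal_area_mm2 > 0, vessel_area_mm2 > 0)
  ages <- as.character(plan$age_groups)
  if (!all(ages %in% names(age_multipliers))) {
    stop("age_multipliers must name every age in the sampling plan: ",
         paste(ages, collapse = ", "))
  }
  for (a in ages) {
    bad <- setdiff(names(age_multipliers[[a]]), combination_classes())
    if (length(bad)) stop("unknown class in age_multipliers: ",
                          paste(bad, collapse = ", "))
  }
  refs <- resolve_spectra(spectra, scene)
  need <- c(CX_CHANNELS, "GS-lectin")
  got <- attr(refs, "markers") %||% rownames(refs)
  if (!all(need %in% got)) {
    stop("spectra missing declared channels: ",
         paste(setdiff(need, got), collapse = ", "))
  }
  stopifnot(segmentation$min_size >= 1,
            segmentation$connectivity %in% c(6, 18, 26),
            merge$rule %in% c("voxel_overlap", "centroid_distance"),
            compartment$max_distance >= 0,
            compartment$fraction > 0, compartment$fraction <= 1)
  structure(list(scene = scene, plan = plan,
                 age_multipliers = age_multipliers,
                 retinal_area_mm2 = retinal_area_mm2,
                 vessel_area_mm2 = vessel_area_mm2,
                 segmentation = segmentation, merge = merge,
                 compartment = compartment, spectra = spectra,
                 nonnegative = isTRUE(nonnegative),
                 unmix_background = isTRUE(unmix_background),
                 out_dir = out_dir, save_images = isTRUE(save_images),
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_spectra <- function(spectra, scene) {
  if (identical(spectra, "default")) {
    default_spectra(scene$bin_centers)
  } else if (is.character(spectra)) {
    read_spectra_csv(spectra)
  } else if (inherits(spectra, "reference_spectra")) {
    spectra
  } else stop("spectra must be 'default', a CSV path, or a reference_spectra")
}

#' Default planted aging effect
#'
#' Baseline (youngest age) multipliers of 1 everywhere; at the oldest age a
#' 6-fold increase in the homotypic Cx30 class, flat Cx43, halved Cx26,
#' and a doubled Cx26/Cx45 class -- the qualitative aging pattern of the
#' modeled system at round planted effect sizes.
#'
#' @param plan a \code{\link{sampling_plan}}.
#' @return named list of per-age multiplier vectors.
#' @export
default_age_multipliers <- function(plan = sampling_plan(age_groups = c(3L, 22L))) {
  ages <- as.character(plan$age_groups)
  eff <- setNames(rep(list(c(Cx26 = 1)), length(ages)), ages)
  eff[[length(eff)]] <- c(Cx26 = 0.5, Cx30 = 6, Cx43 = 1, Cx45 = 2,
                          "Cx26/Cx45" = 2)
  eff
}

# Derive a bounded positive sub-seed from the master seed and a stage tag.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s) + 1L
}

scale_scene <- function(scene, multipliers) {
  if (length(multipliers)) {
    for (comp in COMPARTMENTS) {
      pm <- scene$plaque_means[[comp]]
      hit <- intersect(names(pm), names(multipliers))
      pm[hit] <- pm[hit] * multipliers[hit]
      scene$plaque_means[[comp]] <- pm
    }
  }
  scene
}

#' Process one field of view end to end
#'
#' Simulate (or take) a field, render, unmix, segment the four connexin
#' channels, merge into plaques, and assign compartments using the vessel
#' mask segmented from the GS-lectin channel.
#'
#' @param truth a \code{scene_truth} for the field.
#' @param refs \code{reference_spectra} covering the six markers.
#' @param config a \code{\link{run_config}}.
#' @param render_seed seed for the noise draws.
#' @return list: \code{plaques} (classified, compartment-assigned table),
#'   \code{vessel_mask} (measured), \code{vessel_area_mm2} (measured,
#'   coarea estimate), \code{parenchymal_area_mm2}, \code{stack} (only if
#'   \code{config$save_images}).
#' @export
process_field <- function(truth, refs, config, render_seed = truth$config$seed + 1L) {
  stack <- render_lambda_stack(truth, refs, truth$config, seed = render_seed)
  um <- linear_unmix(stack, refs, nonnegative = config$nonnegative,
                     background = isTRUE(config$unmix_background))
  markers <- attr(refs, "markers") %||% rownames(refs)

  seg <- config$segmentation
  chans <- list()
  for (cx in CX_CHANNELS) {
    m <- um$abundances[, , , match(cx, markers), drop = FALSE]
    dim(m) <- dim(um$abundances)[1:3]
    chans[[cx]] <- segment_channel(m, threshold = seg$threshold,
                                   min_size = seg$min_size,
                                   connectivity = seg$connectivity,
                                   channel = cx,
                                   voxel_size = truth$voxel_size)
  }
  lec <- um$abundances[, , , match("GS-lectin", markers), drop = FALSE]
  dim(lec) <- dim(um$abundances)[1:3]
  vessel_meas <- lec >= otsu_threshold(lec)

  plaques <- merge_channels(chans, rule = config$merge$rule,
                            min_overlap = config$merge$min_overlap,
                            max_distance = config$merge$max_distance)
  plaques <- assign_compartment(plaques, vessel_meas,
                                max_distance = config$compartment$max_distance,
                                fraction = config$compartment$fraction,
                                voxel_size = truth$voxel_size)
  va <- suppressWarnings(vessel_surface_area(vessel_meas, truth$voxel_size))
  out <- list(plaques = plaques, vessel_mask = vessel_meas,
              vessel_area_mm2 = va,
              parenchymal_area_mm2 = truth$areas[["parenchymal_area_mm2"]])
  if (config$save_images) out$stack <- stack
  out
}

#' Simulate and quantify a whole cohort
#'
#' For every (age, retina, field) cell of the sampling plan: build a scene
#' with the age's planted class multipliers, run \code{\link{process_field}},
#' then aggregate fields per retina, convert densities to per-retina totals
#' and summarize groups.
#'
#' @param config a \code{\link{run_config}}.
#' @param progress print progress lines to stderr.
#' @return list: \code{retina_totals} (age, retina, compartment, class,
#'   mean_count_per_field, density, total, mean_size_voxels),
#'   \code{group_summary} (per age/compartment/class mean +/- SEM of totals),
#'   \code{percent_change} (oldest vs youngest age, per compartment/class),
#'   \code{stats} (\code{\link{compare_age_groups}} report).
#' @export
simulate_cohort <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  plan <- config$plan
  refs <- resolve_spectra(config$spectra, config$scene)
  ages <- plan$age_groups
  rows <- list()
  for (ai in seq_along(ages)) {
    age <- ages[ai]
    scene_age <- scale_scene(config$scene,
                             config$age_multipliers[[as.character(age)]])
    for (ri in seq_len(plan$retinas_per_group)) {
      tables <- list()
      info <- list()
      va <- pa <- numeric(0)
      fi <- 0L
      for (region in plan$regions) {
        for (f in seq_len(plan$fields_per_region)) {
          fi <- fi + 1L
          fseed <- derive_seed(config$seed, ai, ri, fi)
          sc <- scene_age
          sc$seed <- fseed
          truth <- build_scene(sc)
          res <- process_field(truth, refs, config,
                               render_seed = derive_seed(fseed, 1L))
          tables[[fi]] <- res$plaques
          info[[fi]] <- data.frame(region = region, field = f)
          va <- c(va, res$vessel_area_mm2)
          pa <- c(pa, res$parenchymal_area_mm2)
        }
      }
      if (progress) {
        message(sprintf("age %s retina %d: %d fields done", age, ri, fi))
      }
      agg <- aggregate_fields(tables, do.call(rbind, info), plan)
      area_field <- ifelse(agg$compartment == "parenchymal",
                           mean(pa), mean(va))
      total_area <- ifelse(agg$compartment == "parenchymal",
                           config$retinal_area_mm2, config$vessel_area_mm2)
      density <- agg$mean_count_per_field / area_field
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, retina = ri, compartment = agg$compartment,
        class = agg$class, mean_count_per_field = agg$mean_count_per_field,
        density_mm2 = density,
        total = density_to_total(density, total_area),
        mean_size_voxels = agg$mean_size_voxels)
    }
  }
  retina_totals <- do.call(rbind, rows)

  group_summary <- summarize_groups(retina_totals)
  pc <- cohort_percent_change(group_summary, ages)
  stats <- compare_age_groups(retina_totals)
  list(retina_totals = retina_totals, group_summary = group_summary,
       percent_change = pc, stats = stats)
}

summarize_groups <- function(retina_totals) {
  keys <- unique(retina_totals[, c("age", "compartment", "class")])
  keys <- keys[order(keys$age, keys$compartment, keys$class), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- retina_totals$age == keys$age[i] &
      retina_totals$compartment == keys$compartment[i] &
      retina_totals$class == keys$class[i]
    tot <- group_mean_sem(retina_totals$total[sel])
    cnt <- group_mean_sem(retina_totals$mean_count_per_field[sel])
    sz <- retina_totals$mean_size_voxels[sel]
    msz <- if (all(is.na(sz))) NA_real_ else mean(sz, na.rm = TRUE)
    data.frame(keys[i, , drop = FALSE],
               mean_count_per_field = cnt$mean, total = tot$mean,
               total_sem = tot$sem, mean_size_voxels = msz,
               number_times_size = number_times_size(cnt$mean,
                                                     ifelse(is.na(msz), 0, msz)),
               n_retinas = tot$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cohort_percent_change <- function(group_summary, ages) {
  a0 <- min(ages)
  a1 <- max(ages)
  keys <- unique(group_summary[, c("compartment", "class")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    s0 <- group_summary$total[group_summary$age == a0 &
                                group_summary$compartment == keys$compartment[i] &
                                group_summary$class == keys$class[i]]
    s1 <- group_summary$total[group_summary$age == a1 &
                                group_summary$compartment == keys$compartment[i] &
                                group_summary$class == keys$class[i]]
    if (!length(s0) || !length(s1) || s0 <= 0) next
    pc <- percent_change(s0, s1)
    rows[[length(rows) + 1L]] <- data.frame(
      compartment = keys$compartment[i], class = keys$class[i],
      total_start = s0, total_end = s1,
      percent = pc$percent, percent_raw = pc$percent_raw)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write its output directory
#'
#' Simulates the configured cohort, writes the quantitative tables
#' (per-retina totals, group summaries, percent-change table, age-group
#' statistics), the serialized configuration, and a manifest listing every
#' artifact with its md5 checksum. Deterministic given (config, seed).
#'
#' @param config a \code{\link{run_config}}.
#' @param progress print progress lines.
#' @return (invisibly) list with the \code{\link{simulate_cohort}} results
#'   plus \code{out_dir} and \code{manifest}.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- simulate_cohort(config, progress = progress)

  paths <- c(retina_totals = "retina_totals.csv",
             group_summary = "group_summary.csv",
             percent_change = "percent_change.csv",
             stats = "age_group_stats.csv")
  for (nm in names(paths)) {
    write.csv(res[[nm]], file.path(config$out_dir, paths[[nm]]),
              row.names = FALSE)
  }
  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    bytes = unname(file.size(file.path(config$out_dir, files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  invisible(c(res, list(out_dir = config$out_dir, manifest = manifest)))
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  x$plan <- unclass(x$plan)
  x$spectra <- if (is.character(x$spectra)) x$spectra else "inline"
  x$out_dir <- NULL   # run-local; keeps manifests identical across reruns
  x
}

#' Read a run configuration from JSON
#'
#' Schema-validated: unknown keys at the top level or inside \code{scene}
#' are rejected and spectra/channel declarations are checked before any
#' computation starts.
#'
#' @param path JSON file.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("scene", "plan", "age_multipliers", "retinal_area_mm2",
               "vessel_area_mm2", "segmentation", "merge", "compartment",
               "spectra", "nonnegative", "unmix_background", "out_dir",
               "save_images", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))

  args <- raw
  if (!is.null(raw$scene)) {
    sc <- raw$scene
    sc_allowed <- setdiff(names(formals(scene_config)),
                          c("n_bins", "spectral_range"))
    sc_allowed <- c(sc_allowed, "n_bins", "spectral_range")
    bad <- setdiff(names(sc), c(sc_allowed, "bin_centers", "allow_overlap"))
    if (length(bad)) stop("unknown scene keys: ", paste(bad, collapse = ", "))
    sc$bin_centers <- NULL
    for (nm in c("plaque_intensity", "marker_intensity")) {
      if (!is.null(sc[[nm]])) sc[[nm]] <- unlist(sc[[nm]])
    }
    if (!is.null(sc$plaque_means)) {
      sc$plaque_means <- lapply(sc$plaque_means, unlist)
    }
    if (!is.null(sc$vessel_spec)) {
      sc$vessel_spec <- as.data.frame(sc$vessel_spec)
    }
    args$scene <- do.call(scene_config, sc)
  }
  if (!is.null(raw$plan)) {
    args$plan <- do.call(sampling_plan, raw$plan)
  }
  if (!is.null(raw$age_multipliers)) {
    args$age_multipliers <- lapply(raw$age_multipliers, unlist)
  }
  do.call(run_config, args)
}
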