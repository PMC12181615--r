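# Pipeline configuration and stage drivers. Each run_* function mirrors one
# stage of the processing chain (generate -> train -> segment -> align /
# reconstruct -> compare) and is what the command-line wrapper calls.

#' Pipeline configuration
#'
#' All tunables of the pipeline with defaults matching the processing chain
#' the package automates: bandpass 50/2 px, 0-2 label codes, alignment
#' batches of 10 new sections + 2 carried references, 3D downscale factor 5,
#' 20 um section spacing (8 um x 5/2 retention). Round-trips losslessly
#' through YAML.
#'
#' @param input_dir,output_dir,model_file Paths (may be NULL for in-memory
#'   use).
#' @param method Segmentation method: `"yiq"`, `"hdab"` or `"ml"`.
#' @param sim Synthetic-data settings (a [slide_sim_config()] or its list of
#'   fields).
#' @param bandpass_large,bandpass_small Bandpass sizes in pixels.
#' @param min_area_um2 Particle-analysis size cut.
#' @param connectivity Particle connectivity (4 or 8).
#' @param batch_size,n_refs Alignment batching.
#' @param downscale_factor 3D rendering reduction.
#' @param z_spacing_um Section spacing.
#' @param brain_mask_sigma Surface-mask smoothing (voxels).
#' @param seed Pipeline seed.
#' @return Object of class `cmh_pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            model_file = NULL, method = "yiq",
                            sim = slide_sim_config(),
                            bandpass_large = 50, bandpass_small = 2,
                            min_area_um2 = 10, connectivity = 8L,
                            batch_size = 10L, n_refs = 2L,
                            downscale_factor = 5L, z_spacing_um = 20,
                            brain_mask_sigma = 2, seed = 1L) {
  if (inherits(sim, "slide_sim_config")) sim <- unclass(sim)
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, model_file = model_file,
    method = match.arg(method, c("yiq", "hdab", "ml")),
    sim = sim,
    bandpass_large = bandpass_large, bandpass_small = bandpass_small,
    min_area_um2 = min_area_um2, connectivity = as.integer(connectivity),
    batch_size = as.integer(batch_size), n_refs = as.integer(n_refs),
    downscale_factor = as.integer(downscale_factor),
    z_spacing_um = z_spacing_um, brain_mask_sigma = brain_mask_sigma,
    seed = as.integer(seed)
  )
  class(cfg) <- "cmh_pipeline_config"
  cfg
}

sim_config_of <- function(config) do.call(slide_sim_config, config$sim)

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `cmh_pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config`: invisibly `path`;
#'   `read_pipeline_config`: the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$sim$image_size_px <- as.integer(raw$sim$image_size_px)
  do.call(pipeline_config, raw)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, extra, path) {
  jsonlite::write_json(
    c(list(
      package = "cmhq",
      version = as.character(utils::packageVersion("cmhq")),
      config_hash = config_fingerprint(config),
      seed = config$seed,
      sim_seed = config$sim$rng_seed
    ), extra),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Generate a synthetic dataset on disk
#'
#' Wraps [generate_stack()] + [write_synthetic_dataset()] and records a run
#' manifest (config hash and seeds) sufficient to reproduce every output.
#'
#' @param config A [pipeline_config()] with `output_dir` set.
#' @return Invisibly, the generated `cmh_synthetic_stack`.
#' @export
run_generate <- function(config) {
  if (is.null(config$output_dir)) stop_config("output_dir is not set")
  stack <- generate_stack(sim_config_of(config))
  write_synthetic_dataset(stack, config$output_dir)
  write_manifest(config, list(stage = "generate",
                              n_sections = length(stack$images)),
                 file.path(config$output_dir, "run_manifest.json"))
  invisible(stack)
}

#' Train the pixel classifier on a small dedicated synthetic training set
#'
#' Generates a training stack (same imaging conditions, independent seed),
#' simulates expert annotations from its ground truth, and fits the
#' classifier.
#'
#' @param config A [pipeline_config()].
#' @param n_training_sections Sections in the training stack (default 8).
#' @return The trained `cmh_pixel_classifier` (saved to `model_file` if
#'   set).
#' @export
run_train <- function(config, n_training_sections = 8L) {
  sim <- config$sim
  sim$n_sections <- as.integer(n_training_sections)
  # keep the classic ~20 small / 10 large training mix on the smaller stack
  sim$rng_seed <- derive_seed(config$seed, 101L)
  tcfg <- do.call(slide_sim_config, sim)
  tstack <- generate_stack(tcfg)
  anns <- lapply(seq_along(tstack$images), function(i) {
    annotate_from_truth(tstack$truth[[i]],
                        seed = derive_seed(config$seed, 102L, i))
  })
  model <- train_pixel_classifier(anns, tstack$images,
                                  seed = derive_seed(config$seed, 103L))
  if (!is.null(config$model_file)) {
    save_pixel_classifier(model, config$model_file)
  }
  model
}

# Label map for one section under a given method.
section_labels <- function(image, method, config, model = NULL) {
  tissue <- tissue_mask_luma(image)
  if (method == "ml") {
    if (is.null(model)) {
      stop_config("method 'ml' needs a trained model (run_train or --model)")
    }
    return(predict_labels(model, image))
  }
  bleed <- if (method == "yiq") {
    segment_yiq(image)
  } else {
    segment_hdab(image, list(bandpass_large = config$bandpass_large,
                             bandpass_small = config$bandpass_small))
  }
  masks_to_labels(tissue | bleed, bleed)
}

#' Segment a stack of sections with one method
#'
#' Produces per-section 0/1/2 label maps and particle tables. For the
#' in-memory path pass the `cmh_synthetic_stack`; for the on-disk path set
#' `config$input_dir` / `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @param stack Optional in-memory `cmh_synthetic_stack` (otherwise images
#'   are read from `input_dir`).
#' @param method Segmentation method (default from config).
#' @param model Optional classifier for `method = "ml"` (otherwise loaded
#'   from `config$model_file`).
#' @return List with `labels` (list of matrices), `particles` (list of
#'   particle tables), `summary` (per-section counts/areas) and `timing`.
#' @export
run_segment <- function(config, stack = NULL, method = NULL, model = NULL) {
  method <- method %||% config$method
  if (method == "ml" && is.null(model)) {
    if (!is.null(config$model_file) && file.exists(config$model_file)) {
      model <- load_pixel_classifier(config$model_file)
    } else {
      stop_config("method 'ml' needs a trained model (run_train or --model)")
    }
  }
  images <- if (!is.null(stack)) {
    stack$images
  } else {
    if (is.null(config$input_dir)) stop_config("input_dir is not set")
    files <- sort(list.files(config$input_dir, pattern = "^sec_.*\\.tif$",
                             full.names = TRUE))
    if (length(files) == 0L) stop_data("no input images")
    lapply(files, function(f) tiff::readTIFF(f) * 255)
  }
  ps <- config$sim$pixel_size_um
  timer <- new_timing()
  labels <- time_stage(timer, "segmentation", {
    lapply(images, function(img) section_labels(img, method, config, model))
  })
  particles <- time_stage(timer, "counting", {
    lapply(labels, function(lab) {
      analyze_particles(lab == 2L, ps, config$min_area_um2,
                        config$connectivity)
    })
  })
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(labels)) {
      write_mask_tiff(labels[[i]] == 2L,
                      file.path(config$output_dir,
                                sprintf("%s_mask_%04d.tif", method, i)))
    }
    smry <- particle_summary(particles)
    write.csv(smry, file.path(config$output_dir,
                              sprintf("%s_particles.csv", method)),
              row.names = FALSE)
  }
  list(labels = labels, particles = particles,
       summary = particle_summary(particles), timing = timing_table(timer))
}

#' Align, reconstruct and quantify a segmented stack
#'
#' The full reconstruction chain: canvas standardization, batched rigid
#' alignment with carried references, factor-5 downscale, 3D surface mask,
#' minimum overlay, reverse-pass alignment refinement, volume assembly, and
#' burden quantification (on the full-resolution masked stack and on the
#' downscaled volume).
#'
#' @param config A [pipeline_config()].
#' @param labels List of per-section 0/1/2 label matrices.
#' @return List: `aligned` (full-res aligned masked stack), `volume`
#'   (`cmh_volume`), `quant` (full-resolution [quantify_cmh()] table),
#'   `quant_downscaled`, `drift` (before/after), `timing`.
#' @export
run_align_reconstruct <- function(config, labels) {
  timer <- new_timing()
  stack <- time_stage(timer, "canvas", {
    standardize_canvas(labels, config$sim$pixel_size_um)
  })
  aligned <- time_stage(timer, "alignment", {
    align_batched(stack, config$batch_size, config$n_refs)
  })
  drift_pre <- stack_drift(stack)
  mask_full <- time_stage(timer, "surface_mask", {
    build_brain_mask(aligned, config$brain_mask_sigma)
  })
  masked <- minimum_overlay(aligned, mask_full)
  refined <- time_stage(timer, "reverse_pass", {
    reverse_pass_align(masked, config$batch_size, config$n_refs)
  })
  small <- time_stage(timer, "downscale", {
    downscale_stack(refined, config$downscale_factor)
  })
  volume <- assemble_volume(small, config$z_spacing_um)
  quant <- quantify_cmh(refined, min_area_um2 = config$min_area_um2,
                        connectivity = config$connectivity)
  quant_small <- quantify_cmh(small, min_area_um2 = config$min_area_um2,
                              connectivity = config$connectivity)
  drift <- c(before = drift_pre, after = stack_drift(refined))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(quant),
              file.path(config$output_dir, "quant_full_res.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(quant_small),
              file.path(config$output_dir, "quant_volume.csv"),
              row.names = FALSE)
    write_transforms_csv(refined,
                         file.path(config$output_dir, "transforms.csv"))
    write_volume_tiff(volume, file.path(config$output_dir, "volume.tif"))
    max_projection(volume, file.path(config$output_dir, "volume_mip.png"))
    write_manifest(config, list(
      stage = "align_reconstruct",
      drift_before_px = drift[["before"]],
      drift_after_px = drift[["after"]]
    ), file.path(config$output_dir, "run_manifest.json"))
  }
  list(aligned = refined, volume = volume, quant = quant,
       quant_downscaled = quant_small, drift = drift,
       timing = timing_table(timer))
}

#' Compare method results against the ground-truth reference
#'
#' @param config A [pipeline_config()].
#' @param method_summaries Named list of per-section summaries
#'   ([particle_summary()] outputs), one per method.
#' @param reference Reference per-section summary (ground truth standing in
#'   for expert manual counts, or an external manual-count table with
#'   columns section, count, area_um2).
#' @return A `cmh_comparison`; artifacts (CSV/JSON/PNG) are written when
#'   `output_dir` is set.
#' @export
run_compare <- function(config, method_summaries, reference) {
  ratios <- lapply(method_summaries, ratio_to_reference, reference)
  cmp <- compare_methods(ratios)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (met in names(cmp)) {
      write.csv(cmp[[met]]$summary,
                file.path(config$output_dir,
                          sprintf("comparison_%s.csv", met)),
                row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(cmp, function(m) {
        list(anova_F = m$anova_F, anova_p = m$anova_p,
             summary = m$summary, brown_forsythe_p = m$brown_forsythe_p)
      }),
      file.path(config$output_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    plot_ratio_bars(cmp, file.path(config$output_dir, "ratio_count.png"),
                    "count")
    plot_ratio_bars(cmp, file.path(config$output_dir, "ratio_area.png"),
                    "area")
  }
  cmp
}

#' Ground-truth per-section reference summary for a synthetic stack
#'
#' The generator's object table, aggregated per section in the same form as
#' [particle_summary()] - the stand-in for expert manual counting.
#'
#' @param stack A `cmh_synthetic_stack`.
#' @return Data frame (section, count, area_um2).
#' @export
truth_summary <- function(stack) {
  n <- length(stack$images)
  obj <- stack$objects
  data.frame(
    section = seq_len(n),
    count = vapply(seq_len(n), function(i) sum(obj$section == i), 0L),
    area_um2 = vapply(seq_len(n), function(i) {
      sum(obj$area_um2[obj$section == i])
    }, 0)
  )
}
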