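# Random-forest pixel classification: sparse-annotation training,
# three-class inference (0 = background, 1 = tissue, 2 = bleed), and batch
# segmentation of image directories.

CLASS_LEVELS <- c("background", "tissue", "bleed")

#' Default pixel-feature descriptor
#'
#' Per RGB channel: the raw intensity, Gaussian blurs (sigma 1, 2, 4, 8 px),
#' gradient magnitude, Laplacian, and min / max / variance over a radius-2
#' neighborhood. Feature order is fixed and recorded with trained models.
#'
#' @return List with `filters` (character vector) and `id` (the descriptor
#'   fingerprint stored in models).
#' @export
default_feature_descriptor <- function() {
  filters <- c(
    "identity", "gauss_1", "gauss_2", "gauss_4", "gauss_8",
    "gradient", "laplacian", "win_min_2", "win_max_2", "win_var_2"
  )
  list(filters = filters, id = paste(filters, collapse = "|"))
}

apply_filter <- function(channel, name) {
  if (name == "identity") return(channel)
  if (grepl("^gauss_", name)) {
    return(gaussian_blur(channel, as.numeric(sub("^gauss_", "", name))))
  }
  if (name == "gradient") {
    gr <- (mat_shift(channel, 1L, 1L) - mat_shift(channel, -1L, 1L)) / 2
    gc <- (mat_shift(channel, 1L, 2L) - mat_shift(channel, -1L, 2L)) / 2
    return(sqrt(gr^2 + gc^2))
  }
  if (name == "laplacian") {
    return(mat_shift(channel, 1L, 1L) + mat_shift(channel, -1L, 1L) +
             mat_shift(channel, 1L, 2L) + mat_shift(channel, -1L, 2L) -
             4 * channel)
  }
  if (grepl("^win_(min|max|var)_", name)) {
    radius <- as.integer(sub("^win_(min|max|var)_", "", name))
    kind <- sub("^win_(min|max|var)_.*$", "\\1", name)
    return(switch(kind,
      min = win_min(channel, radius),
      max = win_max(channel, radius),
      var = win_variance(channel, radius)
    ))
  }
  stop_config(sprintf("unknown feature filter: '%s'", name))
}

#' Extract per-pixel feature vectors
#'
#' @param image RGB array.
#' @param descriptor Feature descriptor (default
#'   [default_feature_descriptor()]); must list at least one filter.
#' @return Numeric matrix, one row per pixel (column-major pixel order), one
#'   column per channel x filter, named `ch<k>_<filter>`.
#' @export
extract_features <- function(image, descriptor = default_feature_descriptor()) {
  check_rgb(image)
  if (length(descriptor$filters) < 1L) {
    stop_config("feature descriptor must list at least one filter")
  }
  chans <- split_channels(image)
  cols <- vector("list", length(chans) * length(descriptor$filters))
  nms <- character(length(cols))
  j <- 0L
  for (k in seq_along(chans)) {
    for (f in descriptor$filters) {
      j <- j + 1L
      cols[[j]] <- as.numeric(apply_filter(chans[[k]], f))
      nms[j] <- sprintf("ch%d_%s", k, f)
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  out
}

#' Simulated expert annotations from ground truth
#'
#' Builds the sparse point annotations an expert would draw on a synthetic
#' section: bleed strokes from the 1-px-eroded bleed interiors (conservative
#' strokes that avoid the partially stained rim), tissue and background
#' points drawn half near the tissue boundary and intracerebral gaps (where
#' misclassification happens) and half uniformly, and every debris-artifact
#' pixel labeled with its true underlying class.
#'
#' @param truth A per-section `truth` list from [generate_section()].
#' @param n_per_class Target points for background and tissue (default 800).
#' @param seed RNG seed for the sampling.
#' @return Data frame (row, col, class) with class in
#'   background / tissue / bleed.
#' @export
annotate_from_truth <- function(truth, n_per_class = 800L, seed = 1L) {
  tissue <- truth$tissue
  bleeds <- truth$bleeds > 0L
  nr <- nrow(tissue)
  nc <- ncol(tissue)
  interior <- bleeds & win_min(bleeds, 1L)
  # keep whole tiny objects that erosion would delete
  ids <- unique(truth$bleeds[bleeds & !interior])
  for (id in ids[ids > 0L]) {
    if (!any(interior[truth$bleeds == id])) {
      interior[truth$bleeds == id] <- TRUE
    }
  }
  band <- win_max(tissue, 12L) & !win_min(tissue, 12L) # boundary/gap zone
  with_seed(seed, {
    pick <- function(mask, n) {
      idx <- which(mask)
      if (length(idx) == 0L) return(idx)
      idx[sample.int(length(idx), min(n, length(idx)))]
    }
    bleed_idx <- pick(interior, 3000L)
    bg_mask <- !tissue & !truth$artifacts
    ts_mask <- tissue & !bleeds & !truth$artifacts
    half <- ceiling(n_per_class / 2)
    bg_idx <- unique(c(pick(bg_mask & band, half), pick(bg_mask, half)))
    ts_idx <- unique(c(pick(ts_mask & band, half), pick(ts_mask, half)))
    art_idx <- which(truth$artifacts)
    to_df <- function(idx, cls) {
      if (length(idx) == 0L) {
        return(data.frame(row = integer(), col = integer(), class = character()))
      }
      data.frame(
        row = (idx - 1L) %% nr + 1L,
        col = (idx - 1L) %/% nr + 1L,
        class = cls
      )
    }
    rbind(
      to_df(bleed_idx, "bleed"),
      to_df(ts_idx, "tissue"),
      to_df(bg_idx, "background"),
      to_df(art_idx[tissue[art_idx]], "tissue"),
      to_df(art_idx[!tissue[art_idx]], "background")
    )
  })
}

#' Train the random-forest pixel classifier
#'
#' Fits a random forest on features extracted at the annotated pixels only.
#' With `bleed_bias = TRUE` (default) every bleed annotation is kept while
#' background and tissue annotations are subsampled to at most five times the
#' bleed count per class - the "bias toward smaller microbleeds" that keeps
#' rare bleed pixels from being swamped during training.
#'
#' @param annotations List of annotation data frames (row, col, class), one
#'   per training image; every class must appear in at least one image.
#' @param images List of RGB arrays matching `annotations`.
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth; 0 = unlimited (default).
#' @param seed Forest seed (default 42).
#' @param bleed_bias Apply bleed-biased class balancing (default TRUE).
#' @param descriptor Feature descriptor (default
#'   [default_feature_descriptor()]).
#' @return Object of class `cmh_pixel_classifier`: the fitted forest, the
#'   feature descriptor (and its id), class mapping (background 0, tissue 1,
#'   bleed 2), training accuracy on the annotations, and training metadata.
#' @export
train_pixel_classifier <- function(annotations, images, n_trees = 100L,
                                   max_depth = 0L, seed = 42L,
                                   bleed_bias = TRUE,
                                   descriptor = default_feature_descriptor()) {
  if (!is.list(annotations) || length(annotations) != length(images)) {
    stop_config("annotations must be a list parallel to images")
  }
  feats <- list()
  labels <- character()
  for (i in seq_along(images)) {
    ann <- annotations[[i]]
    if (nrow(ann) == 0L) next
    d <- dim(images[[i]])
    if (any(ann$row < 1L | ann$row > d[1] | ann$col < 1L | ann$col > d[2])) {
      stop_config(sprintf("annotation coordinates out of bounds in image %d", i))
    }
    fm <- extract_features(images[[i]], descriptor)
    idx <- (ann$col - 1L) * d[1] + ann$row
    feats[[length(feats) + 1L]] <- fm[idx, , drop = FALSE]
    labels <- c(labels, as.character(ann$class))
  }
  missing <- setdiff(CLASS_LEVELS, unique(labels))
  if (length(missing) > 0L) {
    stop_training(sprintf(
      "training annotations missing class(es): %s",
      paste(missing, collapse = ", ")
    ))
  }
  x <- do.call(rbind, feats)
  y <- factor(labels, levels = CLASS_LEVELS)
  if (bleed_bias) {
    nb <- sum(y == "bleed")
    keep <- with_seed(derive_seed(seed, 1L), {
      k <- which(y == "bleed")
      for (cls in c("background", "tissue")) {
        ci <- which(y == cls)
        if (length(ci) > 5L * nb) ci <- sort(sample(ci, 5L * nb))
        k <- c(k, ci)
      }
      sort(k)
    })
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  df <- data.frame(x, check.names = FALSE)
  df$.class <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, max.depth = max_depth, seed = seed,
    num.threads = 1L, verbose = FALSE
  )
  pred <- predict(forest, data = df, num.threads = 1L, seed = seed)$predictions
  model <- list(
    forest = forest,
    descriptor = descriptor,
    descriptor_id = descriptor$id,
    n_features = ncol(x),
    classes = setNames(0:2, CLASS_LEVELS),
    training_accuracy = mean(pred == y),
    metadata = list(
      seed = seed, n_trees = n_trees, max_depth = max_depth,
      n_training_pixels = nrow(x), n_images = length(images),
      bleed_bias = bleed_bias
    )
  )
  class(model) <- "cmh_pixel_classifier"
  model
}

#' @export
print.cmh_pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "CMH pixel classifier: %d trees, %d features, training accuracy %.3f\n",
    x$metadata$n_trees, x$n_features, x$training_accuracy
  ))
  invisible(x)
}

#' Predict a 0/1/2 label map for one section
#'
#' Per-pixel majority vote of the forest; codes 0 = background, 1 = tissue,
#' 2 = bleed. Inference is deterministic given a trained model.
#'
#' @param model A `cmh_pixel_classifier`.
#' @param image RGB array compatible with the model's feature descriptor.
#' @return Integer label matrix.
#' @export
predict_labels <- function(model, image) {
  stopifnot(inherits(model, "cmh_pixel_classifier"))
  if (model$descriptor$id != model$descriptor_id) {
    stop_inference("model feature descriptor does not match its recorded id")
  }
  fm <- extract_features(image, model$descriptor)
  if (ncol(fm) != model$n_features) {
    stop_inference(sprintf(
      "feature mismatch: model expects %d features, image yields %d",
      model$n_features, ncol(fm)
    ))
  }
  pred <- predict(model$forest, data = data.frame(fm, check.names = FALSE),
                  num.threads = 1L, seed = model$metadata$seed)$predictions
  matrix(model$classes[as.character(pred)], nrow(image), ncol(image))
}

#' Extract the bleed mask from a label map
#'
#' @param labels Integer label matrix with codes in \{0, 1, 2\}.
#' @return Logical mask of code-2 (bleed) pixels, ready for
#'   [analyze_particles()].
#' @export
labels_to_bleed_mask <- function(labels) {
  u <- unique(as.vector(labels))
  if (!all(u %in% 0:2)) {
    stop_data(sprintf("label codes outside {0,1,2}: %s",
                      paste(setdiff(u, 0:2), collapse = ", ")))
  }
  labels == 2L
}

#' Save / load a trained pixel classifier
#'
#' The archive records the feature descriptor id; [predict_labels()] refuses
#' to run a model whose extractor no longer matches.
#'
#' @param model A `cmh_pixel_classifier`.
#' @param path Archive file path.
#' @return `save_pixel_classifier`: invisibly, `path`;
#'   `load_pixel_classifier`: the model.
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "cmh_pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cmh_pixel_classifier")) {
    stop_data("file does not contain a pixel classifier")
  }
  if (model$descriptor$id != model$descriptor_id) {
    stop_inference("archived model has a mismatched feature descriptor")
  }
  model
}

#' Batch-segment a directory of section images
#'
#' Discovers TIFF images, extracts the numeric index from each filename,
#' renames to the canonical `sec_<index>` scheme, segments each with the
#' classifier and writes 8-bit label TIFFs (codes 0/1/2). A manifest CSV maps
#' original to canonical names. Unreadable files are skipped and counted;
#' duplicate indices are a hard error.
#'
#' @param model A `cmh_pixel_classifier`.
#' @param input_dir Directory containing `.tif` images.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (original, canonical, status)
#'   with attribute `n_failed`.
#' @export
batch_segment <- function(model, input_dir, output_dir) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  files <- files[!grepl("^truth_", files)]
  if (length(files) == 0L) stop_data("no input images")
  nums <- suppressWarnings(as.integer(gsub("\\D", "", tools::file_path_sans_ext(files))))
  if (anyNA(nums)) {
    stop_data(sprintf("cannot extract numeric index from: %s",
                      paste(files[is.na(nums)], collapse = ", ")))
  }
  if (anyDuplicated(nums)) {
    stop_data("duplicate numeric indices in input filenames")
  }
  ord <- order(nums)
  files <- files[ord]
  nums <- nums[ord]
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    original = files,
    canonical = sprintf("sec_%04d.tif", nums),
    status = "ok", stringsAsFactors = FALSE
  )
  n_failed <- 0L
  for (i in seq_along(files)) {
    img <- tryCatch(
      tiff::readTIFF(file.path(input_dir, files[i])) * 255,
      error = function(e) NULL
    )
    if (is.null(img) || length(dim(img)) != 3L) {
      manifest$status[i] <- "unreadable"
      n_failed <- n_failed + 1L
      next
    }
    labels <- predict_labels(model, img)
    tiff::writeTIFF(labels / 255,
                    file.path(output_dir, sprintf("labels_%04d.tif", nums[i])))
  }
  if (all(manifest$status != "ok")) stop_data("no readable input images")
  write.csv(manifest, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "n_failed") <- n_failed
  invisible(manifest)
}
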