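# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (per-threshold scans, queue-based flood fill) so they
# share no code path with the implementations they check.

# Exhaustive Otsu: scan every interior bin edge, recompute class weights and
# means from the histogram each time.
otsu_bruteforce <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v)
  hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(ceiling((v - lo) / (hi - lo) * n_bins), 1L), n_bins)
  centers <- seq_len(n_bins) - 0.5
  best_t <- NA_real_
  best_sb <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    in0 <- bin <= k
    w0 <- mean(in0)
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- mean(centers[bin[in0]])
    mu1 <- mean(centers[bin[!in0]])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best_sb + 1e-12) { # strict: ties keep the lowest threshold
      best_sb <- sb
      best_t <- edges[k + 1L]
    }
  }
  best_t
}

# Queue-based flood-fill labeling.
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc] || lab[rr, cc] != 0L) next
      cur <- cur + 1L
      queue <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(queue) > 0L) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          r2 <- p[1] + nb[k, 1]
          c2 <- p[2] + nb[k, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Flood fill of background from the border (hole-filling oracle).
fill_holes_oracle <- function(mask) {
  bg <- flood_fill_label(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Small, fast generator configs used across tests.
tiny_sim <- function(...) {
  defaults <- list(
    image_size_px = c(260, 340), n_sections = 3L, n_bleeds_total = 3L,
    bleed_diameter_range_um = c(15, 110), artifact_rate = 0, noise_sd = 0,
    misalignment_translation_px = 0, misalignment_rotation_deg = 0,
    rng_seed = 42L
  )
  do.call(slide_sim_config, utils::modifyList(defaults, list(...)))
}

# One lazily trained classifier shared across test files (training is the
# expensive step; inference determinism is still checked per test).
.test_cache <- new.env(parent = emptyenv())

test_classifier <- function() {
  if (is.null(.test_cache$model)) {
    cfg <- slide_sim_config(n_sections = 8L, n_bleeds_total = 30L,
                            artifact_rate = 2, rng_seed = 7001L)
    tr <- generate_stack(cfg)
    anns <- lapply(seq_along(tr$images), function(i) {
      annotate_from_truth(tr$truth[[i]], seed = 100L + i)
    })
    .test_cache$model <- train_pixel_classifier(anns, tr$images)
  }
  .test_cache$model
}
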