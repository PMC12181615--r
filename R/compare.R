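# Method-comparison harness: per-section ratios to a reference standard,
# ANOVA with Dunnett many-to-one contrasts across methods, Kruskal-Wallis
# with Dunn follow-up across treatment groups, object-level matching, and
# wall-time profiling.

#' Per-section method summary from particle tables
#'
#' @param particles_list List of [analyze_particles()] tables, one per
#'   section.
#' @return Data frame (section, count, area_um2).
#' @export
particle_summary <- function(particles_list) {
  do.call(rbind, lapply(seq_along(particles_list), function(i) {
    p <- particles_list[[i]]
    data.frame(section = i, count = nrow(p), area_um2 = sum(p$area_um2))
  }))
}

#' Match predicted objects to ground-truth objects by IoU
#'
#' A ground-truth object counts as detected when some 8-connected predicted
#' component overlaps it with intersection-over-union at or above the
#' threshold.
#'
#' @param truth_labels Integer ground-truth label matrix (per-object ids).
#' @param pred_mask Logical predicted mask.
#' @param iou_threshold Minimum IoU (default 0.3).
#' @return Data frame (id, area_px, best_iou, detected).
#' @export
match_objects <- function(truth_labels, pred_mask, iou_threshold = 0.3) {
  pred_lab <- cpp_label_components(pred_mask > 0, 8L)
  pred_sizes <- tabulate(pred_lab[pred_lab > 0L])
  ids <- sort(unique(truth_labels[truth_labels > 0L]))
  rows <- lapply(ids, function(id) {
    gt <- truth_labels == id
    a_gt <- sum(gt)
    over <- pred_lab[gt]
    over <- over[over > 0L]
    best <- 0
    if (length(over) > 0L) {
      for (pid in unique(over)) {
        inter <- sum(over == pid)
        best <- max(best, inter / (a_gt + pred_sizes[pid] - inter))
      }
    }
    data.frame(id = id, area_px = a_gt, best_iou = best,
               detected = best >= iou_threshold)
  })
  if (length(rows) == 0L) {
    return(data.frame(id = integer(), area_px = integer(),
                      best_iou = numeric(), detected = logical()))
  }
  do.call(rbind, rows)
}

#' Per-section ratios of a method to the reference standard
#'
#' Area and count ratios per matched section. Sections where both method and
#' reference are zero get ratio 1 (exact agreement on absence); sections
#' where the reference is zero but the method is not are flagged infinite and
#' excluded from downstream means, with the exclusion count reported.
#'
#' @param method_results,reference_results Data frames (section, count,
#'   area_um2) as from [particle_summary()]; section ids must match.
#' @return Data frame (section, count_ratio, area_ratio, excluded) with
#'   attribute `n_excluded`.
#' @export
ratio_to_reference <- function(method_results, reference_results) {
  m <- method_results[order(method_results$section), ]
  r <- reference_results[order(reference_results$section), ]
  if (nrow(m) != nrow(r) || !all(m$section == r$section)) {
    stop_data("method and reference section ids do not match")
  }
  one_ratio <- function(mm, rr) {
    ifelse(rr == 0 & mm == 0, 1, mm / rr) # rr = 0, mm > 0 yields Inf
  }
  out <- data.frame(
    section = m$section,
    count_ratio = one_ratio(m$count, r$count),
    area_ratio = one_ratio(m$area_um2, r$area_um2)
  )
  out$excluded <- !is.finite(out$count_ratio) | !is.finite(out$area_ratio)
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Compare segmentation methods against the reference
#'
#' One-way ANOVA across methods on per-section ratios (the reference's own
#' ratios, identically 1, are included as the control group), followed by
#' Dunnett many-to-one contrasts against the reference. Shapiro-Wilk
#' normality and Brown-Forsythe variance-equality diagnostics are reported
#' alongside. Significance level 0.05.
#'
#' @param ratio_tables Named list of [ratio_to_reference()] outputs (one per
#'   method); at least 2 methods with at least 3 usable sections each.
#' @param metric `"count"`, `"area"`, or both (default).
#' @return Object of class `cmh_comparison`: per-metric summary table
#'   (method, n, mean ratio, SEM, Dunnett p-value), ANOVA F and p,
#'   diagnostics, and exclusion counts.
#' @export
compare_methods <- function(ratio_tables, metric = c("count", "area")) {
  metric <- match.arg(metric, several.ok = TRUE)
  if (length(ratio_tables) < 2L || is.null(names(ratio_tables))) {
    stop_stats("need a named list of at least 2 methods")
  }
  res <- list()
  for (met in metric) {
    col <- paste0(met, "_ratio")
    long <- do.call(rbind, lapply(names(ratio_tables), function(nm) {
      tb <- ratio_tables[[nm]]
      tb <- tb[!tb$excluded, , drop = FALSE]
      data.frame(method = nm, section = tb$section, ratio = tb[[col]])
    }))
    ns <- table(long$method)
    if (any(ns < 3L)) {
      stop_stats("each method needs at least 3 usable sections")
    }
    ref <- data.frame(
      method = "reference",
      section = ratio_tables[[1]]$section,
      ratio = 1
    )
    long <- rbind(ref, long)
    long$method <- factor(long$method,
                          levels = c("reference", names(ratio_tables)))
    fit <- aov(ratio ~ method, data = long)
    # zero residual variance (methods agreeing exactly) is a legitimate
    # fixture; silence the perfect-fit warnings it triggers downstream
    atab <- suppressWarnings(summary(fit)[[1]])
    dunnett <- with_seed(1L, suppressWarnings({
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(method = "Dunnett"))
      summary(gl)
    }))
    pvals <- as.numeric(dunnett$test$pvalues)
    names(pvals) <- names(ratio_tables)
    smry <- do.call(rbind, lapply(levels(long$method), function(g) {
      v <- long$ratio[long$method == g]
      data.frame(
        method = g, n = length(v), mean_ratio = mean(v), sem = sem(v),
        p_vs_reference = if (g == "reference") NA_real_ else pvals[[g]]
      )
    }))
    shap <- vapply(levels(long$method), function(g) {
      v <- long$ratio[long$method == g]
      if (length(unique(v)) < 3L || length(v) < 3L || length(v) > 5000L) {
        return(NA_real_)
      }
      tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
    }, 0)
    bf <- tryCatch(
      car::leveneTest(ratio ~ method, data = long, center = median)[1, "Pr(>F)"],
      error = function(e) NA_real_
    )
    res[[met]] <- list(
      summary = smry,
      anova_F = atab["method", "F value"],
      anova_p = atab["method", "Pr(>F)"],
      shapiro_p = shap,
      brown_forsythe_p = bf,
      n_excluded = vapply(ratio_tables, function(tb) {
        attr(tb, "n_excluded") %||% 0L
      }, 0L)
    )
  }
  structure(res, class = "cmh_comparison", alpha = 0.05)
}

#' @export
print.cmh_comparison <- function(x, ...) {
  for (met in names(x)) {
    cat(sprintf("== %s ratio vs reference (ANOVA F = %.3f, p = %.3g) ==\n",
                met, x[[met]]$anova_F, x[[met]]$anova_p))
    s <- x[[met]]$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-14s n=%3d  ratio %.3f +/- %.3f%s\n",
                  s$method[i], s$n[i], s$mean_ratio[i], s$sem[i],
                  if (is.na(s$p_vs_reference[i])) "" else
                    sprintf("  (Dunnett p = %.3g)", s$p_vs_reference[i])))
    }
  }
  invisible(x)
}

# Dunn's rank-sum z statistics for many-to-one comparisons after
# Kruskal-Wallis, with tie correction.
dunn_many_to_one <- function(values, groups, control) {
  groups <- as.factor(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- table(groups)
  others <- setdiff(levels(groups), control)
  z <- vapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[control]] + 1 / ns[[g]]))
    (rbar[[g]] - rbar[[control]]) / se
  }, 0)
  p <- p.adjust(2 * pnorm(-abs(z)), method = "holm")
  data.frame(group = others, z = z, p_adj = p, row.names = NULL)
}

#' Compare CMH burden across treatment groups
#'
#' Kruskal-Wallis test across groups on per-brain normalized CMH area and
#' density, followed by Dunn's rank-based many-to-one comparisons against
#' the control group (the nonparametric analogue of a Dunnett contrast set),
#' Holm-adjusted. Effect direction is reported from group medians.
#'
#' @param burden Data frame with columns `group`, `brain`, and one or both
#'   of `area_fraction_pct`, `density_per_mm2`; at least 2 groups with at
#'   least 3 brains each.
#' @param control Control group name (default: first factor level).
#' @return Object of class `cmh_group_report`: per-metric Kruskal-Wallis
#'   statistic and p, Dunn table, and group medians.
#' @export
compare_groups <- function(burden, control = NULL) {
  burden$group <- as.factor(burden$group)
  if (nlevels(burden$group) < 2L) stop_stats("need at least 2 groups")
  if (any(table(burden$group) < 3L)) {
    stop_stats("each group needs at least 3 brains")
  }
  control <- control %||% levels(burden$group)[1]
  metrics <- intersect(c("area_fraction_pct", "density_per_mm2"),
                       names(burden))
  if (length(metrics) == 0L) stop_stats("no burden metric columns found")
  res <- lapply(metrics, function(met) {
    v <- burden[[met]]
    kw <- kruskal.test(v, burden$group)
    list(
      kw_statistic = unname(kw$statistic),
      kw_p = kw$p.value,
      dunn = dunn_many_to_one(v, burden$group, control),
      medians = tapply(v, burden$group, median)
    )
  })
  names(res) <- metrics
  structure(res, class = "cmh_group_report", control = control)
}

#' @export
print.cmh_group_report <- function(x, ...) {
  for (met in names(x)) {
    cat(sprintf("== %s: Kruskal-Wallis chi2 = %.3f, p = %.3g ==\n",
                met, x[[met]]$kw_statistic, x[[met]]$kw_p))
    md <- x[[met]]$medians
    cat("  medians:", paste(sprintf("%s = %.4g", names(md), md),
                            collapse = ", "), "\n")
    d <- x[[met]]$dunn
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %s vs %s: z = %.2f, p(adj) = %.3g\n",
                  d$group[i], attr(x, "control"), d$z[i], d$p_adj[i]))
    }
  }
  invisible(x)
}

#' Wall-time profiler for pipeline stages
#'
#' `new_timing()` creates a collector; `time_stage()` runs an expression and
#' records its elapsed wall time; `timing_table()` returns the per-stage
#' report (no assertions are made on absolute values - they are
#' hardware-dependent).
#'
#' @return `new_timing()`: a collector environment. `time_stage()`: the
#'   expression's value. `timing_table()`: data frame (stage, seconds).
#' @export
new_timing <- function() {
  env <- new.env(parent = emptyenv())
  env$stages <- character()
  env$seconds <- numeric()
  class(env) <- "cmh_timing"
  env
}

#' @rdname new_timing
#' @param timer A `cmh_timing` collector.
#' @param stage Stage name.
#' @param expr Expression to run and time.
#' @export
time_stage <- function(timer, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  timer$stages <- c(timer$stages, stage)
  timer$seconds <- c(timer$seconds, proc.time()[["elapsed"]] - t0)
  val
}

#' @rdname new_timing
#' @export
timing_table <- function(timer) {
  data.frame(stage = timer$stages, seconds = timer$seconds)
}

#' Bar plot of method ratios with SEM error bars
#'
#' @param comparison A `cmh_comparison`.
#' @param path PNG output path.
#' @param metric Which metric to plot (default `"count"`).
#' @return Invisibly, `path`.
#' @export
plot_ratio_bars <- function(comparison, path, metric = "count") {
  s <- comparison[[metric]]$summary
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  mids <- graphics::barplot(
    s$mean_ratio, names.arg = s$method,
    ylab = sprintf("%s ratio vs reference", metric),
    ylim = c(0, max(s$mean_ratio + s$sem) * 1.15), col = "steelblue"
  )
  suppressWarnings( # zero-length bars (SEM 0) draw nothing, silently
    graphics::arrows(mids, s$mean_ratio - s$sem, mids, s$mean_ratio + s$sem,
                     angle = 90, code = 3, length = 0.06)
  )
  graphics::abline(h = 1, lty = 2)
  invisible(path)
}
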