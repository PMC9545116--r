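#' Root-mean-square error as a percentage of the reference
#'
#' `100 * ||estimate - truth||_2 / ||truth||_2` over the mask voxels. Used
#' for whole-brain comparison of susceptibility or local-field maps against
#' ground truth; values near or above 100% are typical for noisy QSM
#' because the metric mixes bias, regularisation shrinkage and noise.
#'
#' @param estimate_3d,truth_3d 3D arrays.
#' @param mask 3D logical array (default: whole grid).
#' @param demean Subtract each map's mask-mean first (appropriate for
#'   reference-free local-field comparisons).
#' @return Scalar percentage.
#' @export
rmse_percent <- function(estimate_3d, truth_3d, mask = NULL, demean = FALSE) {
  mask <- as_mask(mask, dim(truth_3d))
  e <- estimate_3d[mask]
  t <- truth_3d[mask]
  if (demean) {
    e <- e - mean(e)
    t <- t - mean(t)
  }
  if (all(t == 0)) stop("reference is identically zero over the mask")
  100 * sqrt(sum((e - t)^2)) / sqrt(sum(t^2))
}

#' Regional means and SDs
#'
#' @param map_3d 3D array (e.g. susceptibility in ppm).
#' @param rois Named list of 3D logical ROI masks.
#' @param pipeline_tag Label recorded in the `pipeline` column.
#' @param subject Label recorded in the `subject` column.
#' @param mask Optional 3D logical array intersected with every ROI (e.g.
#'   the SHARP-eroded mask so all pipelines share support).
#' @return Tibble: `subject`, `pipeline`, `roi`, `mean`, `sd`, `n_voxels`.
#' @export
regional_stats <- function(map_3d, rois, pipeline_tag = "map",
                           subject = "subject1", mask = NULL) {
  shape <- dim(map_3d)
  mask <- as_mask(mask, shape)
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  rows <- lapply(names(rois), function(nm) {
    sel <- as_mask(rois[[nm]], shape) & mask
    v <- map_3d[sel]
    v <- v[is.finite(v)]
    if (!length(v)) stop("ROI '", nm, "' is empty after masking")
    tibble::tibble(subject = subject, pipeline = pipeline_tag, roi = nm,
                   mean = mean(v), sd = stats::sd(v), n_voxels = length(v))
  })
  do.call(rbind, rows)
}

#' Line profile through a volume
#'
#' Samples the volume at unit-spaced points along the segment from
#' `start_voxel` to `end_voxel` by nearest-voxel lookup; the profile has
#' `floor(segment length) + 1` samples.
#'
#' @param map_3d 3D array.
#' @param start_voxel,end_voxel Length-3 voxel coordinates (1-based).
#' @return List: `values`, `positions` (matrix of sampled voxel indices),
#'   `mean`, `sd`.
#' @export
line_profile <- function(map_3d, start_voxel, end_voxel) {
  shape <- dim(map_3d)
  if (any(start_voxel < 1) || any(start_voxel > shape) ||
      any(end_voxel < 1) || any(end_voxel > shape))
    stop("profile endpoints must lie inside the grid")
  if (all(start_voxel == end_voxel)) stop("identical endpoints")
  len <- sqrt(sum((end_voxel - start_voxel)^2))
  steps <- 0:floor(len)
  pts <- sapply(1:3, function(a)
    start_voxel[a] + steps / len * (end_voxel[a] - start_voxel[a]))
  idx <- pmin(pmax(round(pts), 1), matrix(shape, length(steps), 3, byrow = TRUE))
  vals <- map_3d[cbind(idx[, 1], idx[, 2], idx[, 3])]
  list(values = vals, positions = idx, mean = mean(vals),
       sd = stats::sd(vals))
}

#' Bland-Altman fixed-bias analysis of two pipelines
#'
#' For paired per-subject regional means from two pipelines:
#' `bias = mean(a - b)`, limits of agreement `bias +/- 1.96 SD(a - b)`, and
#' a negligibility flag `|bias| <= threshold` (default 0.01 ppm — below
#' that level inter-pipeline differences cannot be disentangled from the
#' intra-pipeline regional SD).
#'
#' @param per_subject_means_a,per_subject_means_b Equal-length paired
#'   numeric vectors (one value per subject).
#' @param roi ROI label recorded in the output.
#' @param pipelines Length-2 character vector naming the pair.
#' @param threshold_ppm Negligibility threshold (default 0.01).
#' @return Tibble: `roi`, `pipeline_a`, `pipeline_b`, `bias`, `loa_lower`,
#'   `loa_upper`, `negligible`.
#' @export
bland_altman <- function(per_subject_means_a, per_subject_means_b,
                         roi = "roi", pipelines = c("a", "b"),
                         threshold_ppm = 0.01) {
  a <- per_subject_means_a
  b <- per_subject_means_b
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  if (length(a) < 2) stop("need >= 2 paired subjects")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(roi = roi, pipeline_a = pipelines[1],
                 pipeline_b = pipelines[2], bias = bias,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 negligible = abs(bias) <= threshold_ppm)
}

#' Pairwise statistical comparison of pipelines
#'
#' For each ROI and each pair of pipelines, tests whether the per-subject
#' regional means differ systematically: the Shapiro-Wilk test is applied
#' to the paired differences and, if normality is rejected (p < 0.05), a
#' two-tailed exact sign test is used; otherwise a paired t-test. P values
#' are reported uncorrected and flagged at the 0.05 level. All-zero
#' differences leave the sign test undefined and are reported as
#' no-difference.
#'
#' @param df Long tibble with columns `subject`, `pipeline`, `roi`, `mean`
#'   (e.g. from stacking [regional_stats()] outputs).
#' @param rois Optional subset of ROIs to test.
#' @return Tibble: `roi`, `pipeline_a`, `pipeline_b`, `shapiro_p`, `test`
#'   (`"sign"`, `"t"`, or `"none"`), `statistic`, `p_value`, `significant`.
#' @export
compare_pipelines <- function(df, rois = NULL) {
  stopifnot(all(c("subject", "pipeline", "roi", "mean") %in% names(df)))
  rois <- rois %||% unique(df$roi)
  pipes <- unique(df$pipeline)
  out <- list()
  for (roi in rois) {
    for (i in seq_along(pipes)) for (j in seq_along(pipes)) {
      if (j <= i) next
      a <- df[df$roi == roi & df$pipeline == pipes[i], ]
      b <- df[df$roi == roi & df$pipeline == pipes[j], ]
      common <- intersect(a$subject, b$subject)
      if (length(common) < 3)
        stop("need >= 3 paired subjects for ", pipes[i], " vs ", pipes[j])
      d <- a$mean[match(common, a$subject)] - b$mean[match(common, b$subject)]
      if (all(d == 0)) {
        out[[length(out) + 1]] <- tibble::tibble(
          roi = roi, pipeline_a = pipes[i], pipeline_b = pipes[j],
          shapiro_p = NA_real_, test = "none", statistic = 0,
          p_value = 1, significant = FALSE)
        next
      }
      sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
      if (sw < 0.05) {
        npos <- sum(d > 0)
        nn <- sum(d != 0)
        bt <- stats::binom.test(npos, nn, p = 0.5,
                                alternative = "two.sided")
        row <- tibble::tibble(roi = roi, pipeline_a = pipes[i],
                              pipeline_b = pipes[j], shapiro_p = sw,
                              test = "sign", statistic = npos,
                              p_value = bt$p.value,
                              significant = bt$p.value < 0.05)
      } else {
        tt <- stats::t.test(d)
        row <- tibble::tibble(roi = roi, pipeline_a = pipes[i],
                              pipeline_b = pipes[j], shapiro_p = sw,
                              test = "t", statistic = unname(tt$statistic),
                              p_value = tt$p.value,
                              significant = tt$p.value < 0.05)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Pool per-subject regional statistics
#'
#' Checks that, per (pipeline, ROI), every intra-subject SD exceeds the
#' inter-subject SD of the means (the condition under which pooling mixes
#' comparable populations), then pools: the mean is the voxel-count-weighted
#' mean of subject means and the SD follows the law of total variance
#' (count-weighted within-subject variance plus between-subject variance).
#' A violated condition is recorded in `condition_ok` but pooling is still
#' computed.
#'
#' @param table Tibble from stacked [regional_stats()] rows (>= 2 subjects
#'   per pipeline/ROI).
#' @return Tibble: `pipeline`, `roi`, `pooled_mean`, `pooled_sd`,
#'   `n_subjects`, `n_voxels`, `inter_subject_sd`, `min_intra_sd`,
#'   `condition_ok`.
#' @export
pool_subjects <- function(table) {
  stopifnot(all(c("subject", "pipeline", "roi", "mean", "sd", "n_voxels")
                %in% names(table)))
  groups <- split(table, interaction(table$pipeline, table$roi, drop = TRUE))
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2) stop("need >= 2 subjects per (pipeline, roi)")
    w <- g$n_voxels / sum(g$n_voxels)
    pm <- sum(w * g$mean)
    within <- sum(w * g$sd^2)
    between <- sum(w * (g$mean - pm)^2)
    inter <- stats::sd(g$mean)
    tibble::tibble(pipeline = g$pipeline[1], roi = g$roi[1],
                   pooled_mean = pm, pooled_sd = sqrt(within + between),
                   n_subjects = nrow(g), n_voxels = sum(g$n_voxels),
                   inter_subject_sd = inter, min_intra_sd = min(g$sd),
                   condition_ok = min(g$sd) > inter)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise difference map
#'
#' Convenience writer for visual comparison of two susceptibility maps on
#' their shared support.
#'
#' @param map_a,map_b 3D arrays (or [chi_map()] objects).
#' @param mask Optional mask; defaults to the intersection of chi-map masks.
#' @return 3D array `a - b`, zero outside the mask.
#' @export
difference_map <- function(map_a, map_b, mask = NULL) {
  va <- if (inherits(map_a, "chi_map")) map_a$chi else map_a
  vb <- if (inherits(map_b, "chi_map")) map_b$chi else map_b
  if (is.null(mask) && inherits(map_a, "chi_map") &&
      inherits(map_b, "chi_map"))
    mask <- map_a$mask & map_b$mask
  mask <- as_mask(mask, dim(va))
  d <- va - vb
  d[!mask] <- 0
  d
}
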