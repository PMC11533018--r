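#' Trimmed mean of ROI voxel values
#'
#' Computes the mean and population standard deviation of the input once,
#' retains the values inside the closed interval `[mu - 2*sigma, mu + 2*sigma]`
#' and returns their arithmetic mean (no re-iteration). With zero spread all
#' values are retained.
#'
#' @param values numeric vector with at least 2 elements.
#' @return list with `trimmed_mean` and `n_used`.
#' @examples
#' trim_and_mean(c(rep(10, 100), 1000))
#' @export
trim_and_mean <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 values are required")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  keep <- values >= mu - 2 * sigma & values <= mu + 2 * sigma
  list(trimmed_mean = mean(values[keep]), n_used = sum(keep))
}

metric_of_map <- function(map) {
  if (inherits(map, "susceptibility_map")) "qsm_ppb"
  else if (inherits(map, "relaxation_map")) "r2star_s-1"
  else stop("map must be a susceptibility_map or relaxation_map")
}

map_values <- function(map) {
  if (inherits(map, "susceptibility_map")) map$chi else map$r2star
}

#' Per-ROI trimmed-mean statistics from a quantitative map
#'
#' For every labelled structure and hemisphere, gathers the voxels inside the
#' map's validity mask intersected with the reliability mask and applies the
#' mu +/- 2 sigma trimmed mean. ROIs with fewer than 2 usable voxels are
#' flagged and carry no value.
#'
#' @param map a `susceptibility_map` or `relaxation_map`.
#' @param labels integer label volume aligned with the map grid.
#' @param label_table data.frame with columns code, name, hemisphere (see
#'   [phantom_label_table()]).
#' @param reliability optional boolean volume of reliable voxels.
#' @param subject_id identifier recorded in each row.
#' @return data.frame (ROI table) with columns subject_id, roi_name,
#'   hemisphere, metric, trimmed_mean, n_voxels_used, n_voxels_total, flagged.
#' @export
roi_table <- function(map, labels, label_table, reliability = NULL,
                      subject_id = "subject") {
  vals <- map_values(map)
  if (!all(dim(labels) == dim(vals))) stop("labels are not aligned with the map grid")
  usable <- map$mask
  if (!is.null(reliability)) usable <- usable & reliability
  metric <- metric_of_map(map)
  rows <- lapply(seq_len(nrow(label_table)), function(i) {
    code <- label_table$code[i]
    in_roi <- labels == code
    n_total <- sum(in_roi)
    vox <- which(in_roi & usable)
    if (length(vox) < 2L) {
      data.frame(subject_id = subject_id, roi_name = label_table$name[i],
                 hemisphere = label_table$hemisphere[i], metric = metric,
                 trimmed_mean = NA_real_, n_voxels_used = length(vox),
                 n_voxels_total = n_total, flagged = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tm <- trim_and_mean(vals[vox])
      data.frame(subject_id = subject_id, roi_name = label_table$name[i],
                 hemisphere = label_table$hemisphere[i], metric = metric,
                 trimmed_mean = tm$trimmed_mean, n_voxels_used = tm$n_used,
                 n_voxels_total = n_total, flagged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Paired inter-hemispheric test per ROI
#'
#' Two-sided Wilcoxon signed-rank test across subjects on the left-minus-right
#' difference of trimmed means, per ROI and metric. With all differences zero
#' the p-value is 1 by convention. With fewer than 5 paired subjects the exact
#' test is used and the row is flagged.
#'
#' @param table an ROI table with L and R rows (from [roi_table()]).
#' @return data.frame with columns roi_name, metric, n_pairs, statistic,
#'   p_value, flagged.
#' @export
hemisphere_test <- function(table) {
  keys <- unique(table[table$hemisphere %in% c("L", "R"),
                       c("roi_name", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$roi_name == keys$roi_name[i] &
                   table$metric == keys$metric[i], ]
    l <- sub[sub$hemisphere == "L", c("subject_id", "trimmed_mean")]
    r <- sub[sub$hemisphere == "R", c("subject_id", "trimmed_mean")]
    mrg <- merge(l, r, by = "subject_id", suffixes = c("_l", "_r"))
    mrg <- mrg[stats::complete.cases(mrg), ]
    d <- mrg$trimmed_mean_l - mrg$trimmed_mean_r
    n <- length(d)
    flagged <- n < 5L
    if (n == 0L || all(d == 0)) {
      stat <- if (n > 0) 0 else NA_real_
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                                exact = n < 50))
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(roi_name = keys$roi_name[i], metric = keys$metric[i],
               n_pairs = n, statistic = stat, p_value = p, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge hemispheres into bilateral ROI values
#'
#' The bilateral value is the unweighted mean of the left and right trimmed
#' means. If one hemisphere is absent (flagged), the present value is
#' propagated and the row stays flagged.
#'
#' @param table an ROI table with L and R rows.
#' @return ROI table with hemisphere `"bilateral"`.
#' @export
merge_hemispheres <- function(table) {
  keys <- unique(table[, c("subject_id", "roi_name", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$subject_id == keys$subject_id[i] &
                   table$roi_name == keys$roi_name[i] &
                   table$metric == keys$metric[i] &
                   table$hemisphere %in% c("L", "R"), ]
    vals <- sub$trimmed_mean[!is.na(sub$trimmed_mean)]
    flagged <- any(sub$flagged) || length(vals) < 2L
    data.frame(subject_id = keys$subject_id[i], roi_name = keys$roi_name[i],
               hemisphere = "bilateral", metric = keys$metric[i],
               trimmed_mean = if (length(vals)) mean(vals) else NA_real_,
               n_voxels_used = sum(sub$n_voxels_used),
               n_voxels_total = sum(sub$n_voxels_total),
               flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between ROI volume and iron metrics
#'
#' Pearson and Spearman correlations (two-sided) between each ROI's volume --
#' raw and normalised by total intracranial volume -- and each iron metric's
#' trimmed mean across subjects. Zero-variance inputs yield a flagged,
#' undefined row.
#'
#' @param volumes data.frame with columns subject_id, roi_name, volume, tiv.
#' @param table a bilateral ROI table.
#' @return data.frame with one row per ROI, metric, volume measure and
#'   correlation type.
#' @export
volume_metric_correlation <- function(volumes, table) {
  keys <- unique(table[, c("roi_name", "metric")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- table[table$roi_name == keys$roi_name[i] &
                   table$metric == keys$metric[i], ]
    mrg <- merge(sub, volumes, by = c("subject_id", "roi_name"))
    mrg <- mrg[stats::complete.cases(mrg[, c("trimmed_mean", "volume", "tiv")]), ]
    for (vm in c("volume", "volume_tiv")) {
      v <- if (vm == "volume") mrg$volume else mrg$volume / mrg$tiv
      for (method in c("pearson", "spearman")) {
        degenerate <- nrow(mrg) < 3L ||
          stats::sd(v) == 0 || stats::sd(mrg$trimmed_mean) == 0
        if (degenerate) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- suppressWarnings(
            stats::cor.test(v, mrg$trimmed_mean, method = method,
                            alternative = "two.sided", exact = FALSE))
          r <- unname(ct$estimate); p <- ct$p.value
        }
        out[[length(out) + 1L]] <- data.frame(
          roi_name = keys$roi_name[i], metric = keys$metric[i],
          volume_measure = vm, method = method, n = nrow(mrg),
          estimate = r, p_value = p, flagged = degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
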