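# ROI quantification and evaluation metrics: Dice overlap, per-structure
# volume / mean FA / mean MD tables, symmetric volume difference,
# scan-rescan reproducibility summaries and cross-subject variability.

#' Dice overlap coefficient between two binary masks
#'
#' 2|A n B| / (|A| + |B|). Two empty masks are defined to have Dice 1
#' (with a warning).
#'
#' @param a,b logical arrays on the same grid (or anything coercible).
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  .stopIf(length(a) != length(b), "mask grids differ")
  s <- sum(a) + sum(b)
  if (s == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / s
}

#' Per-structure Dice between two label maps
#'
#' @param a,b \linkS4class{LabelMap}s on the same grid.
#' @param labels labels to evaluate (default: union of both maps).
#' @return named numeric vector of Dice coefficients.
#' @export
diceByLabel <- function(a, b, labels = NULL) {
  .stopIf(!identical(dim(a@data), dim(b@data)), "label map grids differ")
  if (is.null(labels)) labels <- sort(union(labelSet(a), labelSet(b)))
  out <- vapply(labels, function(l)
    suppressWarnings(diceCoefficient(a@data == l, b@data == l)), numeric(1))
  names(out) <- labels
  out
}

#' ROI statistics: volume, mean FA, mean MD per structure
#'
#' Volume is the voxel count times the voxel volume; mean FA and MD are
#' plain voxel averages within each structure. Background and labels in
#' the map's \code{excluded} slot (CSF compartments) are omitted; empty
#' structures are simply absent from the table.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param img the \linkS4class{MultiContrastImage} on the same grid.
#' @return data.frame with columns label, n_voxels, volume_mm3, mean_fa,
#'   mean_md.
#' @export
roiStats <- function(labels, img) {
  .stopIf(!identical(dim(labels@data), gridDim(img)),
          "labels and image must share one grid")
  voxVol <- prod(labels@spacing)
  fa <- img@channels$fa@data
  md <- img@channels$md@data
  lv <- as.integer(labels@data)
  keep <- setdiff(sort(unique(lv[lv != 0L])), labels@excluded)
  rows <- lapply(keep, function(l) {
    idx <- lv == l
    data.frame(label = l, n_voxels = sum(idx),
               volume_mm3 = sum(idx) * voxVol,
               mean_fa = mean(fa[idx]), mean_md = mean(md[idx]))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Symmetric percent volume difference
#'
#' 100 * |v1 - v2| / ((v1 + v2) / 2). The mean-of-two denominator makes the
#' measure symmetric; \code{denominator = "first"} divides by v1 instead.
#'
#' @param v1,v2 volumes in mm^3, non-negative and not both zero.
#' @param denominator "mean" (default) or "first".
#' @return percent difference.
#' @export
volumeDiffPercent <- function(v1, v2, denominator = c("mean", "first")) {
  denominator <- match.arg(denominator)
  .stopIf(any(v1 < 0 | v2 < 0), "volumes must be non-negative")
  .stopIf(any(v1 + v2 == 0), "volume difference undefined when both are zero")
  den <- switch(denominator, mean = (v1 + v2) / 2, first = v1)
  100 * abs(v1 - v2) / den
}

#' Cross-subject variability (std/mean) per structure
#'
#' Computes, per structure and per measure (volume, mean FA, mean MD), the
#' ratio of the sample standard deviation (n - 1) to the mean across
#' subjects. Structures absent in some subjects are computed over the
#' subjects where they are present, with the count reported.
#'
#' @param statsList list of \code{\link{roiStats}} tables, one per subject.
#' @return data.frame with columns label, n_subjects, cv_volume, cv_fa,
#'   cv_md.
#' @export
crossSubjectVariability <- function(statsList) {
  .stopIf(length(statsList) < 2L, "at least 2 subjects required")
  all <- do.call(rbind, statsList)
  labs <- sort(unique(all$label))
  cv <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x) / mean(x)
  out <- lapply(labs, function(l) {
    s <- all[all$label == l, ]
    data.frame(label = l, n_subjects = nrow(s),
               cv_volume = cv(s$volume_mm3), cv_fa = cv(s$mean_fa),
               cv_md = cv(s$mean_md))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Scan-rescan reproducibility report
#'
#' Per-structure absolute percent differences (mean-of-two denominator,
#' matching \code{\link{volumeDiffPercent}}) for volume, mean FA and mean
#' MD between two runs, with mean summaries over all matched structures
#' and over the structures at or above \code{smallStructureCutoff}
#' (default 1000 mm^3, mean of the two runs' volumes). Structures present
#' in only one run are reported in \code{unmatched} and excluded.
#'
#' @param run1,run2 \code{\link{roiStats}} tables of the two runs.
#' @param smallStructureCutoff volume cutoff in mm^3.
#' @return list with \code{perStructure} (data.frame), \code{summary} and
#'   \code{summaryLarge} (named means of the percent differences) and
#'   \code{unmatched} (label ids).
#' @export
scanRescanReport <- function(run1, run2, smallStructureCutoff = 1000) {
  common <- intersect(run1$label, run2$label)
  unmatched <- sort(c(setdiff(run1$label, common), setdiff(run2$label, common)))
  if (length(unmatched))
    warning(sprintf("%d unmatched structures excluded", length(unmatched)))
  r1 <- run1[match(common, run1$label), ]
  r2 <- run2[match(common, run2$label), ]
  pct <- function(x, y) 100 * abs(x - y) / ((x + y) / 2)
  per <- data.frame(label = common,
                    volume_mm3 = (r1$volume_mm3 + r2$volume_mm3) / 2,
                    pct_volume = pct(r1$volume_mm3, r2$volume_mm3),
                    pct_fa = pct(r1$mean_fa, r2$mean_fa),
                    pct_md = pct(r1$mean_md, r2$mean_md))
  summarize <- function(df) c(volume = mean(df$pct_volume),
                              fa = mean(df$pct_fa), md = mean(df$pct_md))
  list(perStructure = per, summary = summarize(per),
       summaryLarge = summarize(per[per$volume_mm3 >= smallStructureCutoff, ,
                                    drop = FALSE]),
       unmatched = unmatched)
}
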