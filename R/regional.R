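#' @include maps.R
NULL

#' Segment the ventilated lung from a ventilation image
#'
#' Voxels at or above \code{thresholdFrac} times the maximum signal
#' intensity are ventilated (default 10\% of maximum).
#'
#' @param vent numeric 3D ventilation volume
#' @param thresholdFrac fraction of the maximum intensity in (0, 1)
#' @return logical 3D array
#' @export
segmentVentilated <- function(vent, thresholdFrac = 0.10) {
  stopifnot(thresholdFrac > 0, thresholdFrac < 1)
  mx <- max(vent)
  if (mx <= 0) stop("all-zero ventilation volume")
  vent >= thresholdFrac * mx
}

#' Ventilation defect percentage
#'
#' VDP = (1 - VV/TCV) * 100, the share of the total lung cavity volume
#' (TCV) without ventilation signal. When masks are supplied the
#' ventilated volume is intersected with the cavity mask first, so VDP is
#' always in [0, 100].
#'
#' @param vv ventilated-volume voxel count, or a logical volume
#' @param tcv total-cavity voxel count, or a logical volume
#' @return VDP in percent
#' @examples
#' computeVdp(931, 1000)   # 6.9
#' @export
computeVdp <- function(vv, tcv) {
  if (is.array(vv) || is.logical(vv)) {
    stopifnot(is.array(tcv) || is.logical(tcv))
    vv <- sum(vv & tcv)
    tcv <- sum(tcv)
  }
  if (tcv <= 0) stop("empty total cavity volume")
  if (vv > tcv) stop("ventilated volume exceeds cavity volume; intersect masks first")
  (1 - vv / tcv) * 100
}

#' Lobe-wise regional summaries of quantitative maps
#'
#' Per-lobe mean, SD and voxel count for every metric of a
#' \linkS4class{QuantMaps}, restricted to the analysis mask. Empty lobes
#' yield rows with zero counts and NA statistics rather than errors.
#'
#' @param qm a \linkS4class{QuantMaps}
#' @param lobes integer 3D lobe-label volume (0 = outside lung)
#' @param lobeLabels character names for labels 1..max
#' @param animal,fio2 identifiers copied into the output rows
#' @return data.frame with columns animal, fio2, lobe, metric, mean, sd,
#'   n_voxels
#' @export
regionalSummaries <- function(qm, lobes,
                              lobeLabels = c("R1", "R2", "R3", "R4",
                                             "L1", "L2"),
                              animal = NA, fio2 = qm@fio2) {
  stopifnot(identical(dim(lobes), dim(qm@mask)))
  rows <- list()
  for (li in seq_along(lobeLabels)) {
    sel <- qm@mask & lobes == li
    for (nm in names(qm@maps)) {
      v <- qm@maps[[nm]][sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        animal = animal, fio2 = fio2, lobe = lobeLabels[li], metric = nm,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_voxels = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Paired t-test between the two oxygen levels
#'
#' Student's paired t on per-animal values; df = n - 1, two-sided p.
#' A zero-variance difference vector is flagged (t undefined) instead of
#' erroring.
#'
#' @param a,b per-animal paired measurements (equal length >= 2)
#' @return list with t, p, df, meanDiff, flagged
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = if (all(d == 0)) 1 else NA_real_,
                df = length(d) - 1L, meanDiff = mean(d), flagged = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), meanDiff = mean(d), flagged = FALSE)
}

#' Two-way ANOVA of regional effects
#'
#' Region (6 lobes) by oxygen (2 levels) ANOVA with interaction on
#' lobe-level animal means, via \code{aov}. With one observation per cell
#' the interaction is untestable and an explicit error is raised; an
#' entirely empty cell is reported by name. A zero residual (noiseless
#' degenerate input) is flagged.
#'
#' @param data data.frame with columns lobe, fio2, value (one metric)
#' @return list with pRegion, pOxygen, pInteraction, F statistics,
#'   degenerate flag
#' @export
regionalAnova <- function(data) {
  stopifnot(all(c("lobe", "fio2", "value") %in% names(data)))
  tab <- data
  tab$lobe <- factor(tab$lobe)
  tab$fio2 <- factor(tab$fio2)
  counts <- table(tab$lobe, tab$fio2)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: lobe ", levels(tab$lobe)[bad[1]], " at FiO2 ",
         levels(tab$fio2)[bad[2]])
  }
  if (all(counts == 1))
    stop("one observation per cell: interaction untestable")
  fit <- stats::aov(value ~ lobe * fio2, data = tab)
  sm <- summary(fit)[[1]]
  rownames(sm) <- trimws(rownames(sm))
  resMs <- sm["Residuals", "Mean Sq"]
  degenerate <- is.na(resMs) || resMs < .Machine$double.eps * 100
  getp <- function(row) if (degenerate) NA_real_ else sm[row, "Pr(>F)"]
  getf <- function(row) sm[row, "F value"]
  list(pRegion = getp("lobe"), pOxygen = getp("fio2"),
       pInteraction = getp("lobe:fio2"),
       fRegion = getf("lobe"), fOxygen = getf("fio2"),
       fInteraction = getf("lobe:fio2"), degenerate = degenerate)
}

#' Table-2-style ANOVA across metrics
#'
#' Runs \code{\link{regionalAnova}} for every metric of a regional table
#' (as produced by \code{\link{regionalSummaries}} over animals, or by
#' \code{\link{simulateRegionalData}}).
#'
#' @param regional data.frame with columns lobe, fio2, metric and value
#'   (or mean, used as the value)
#' @return data.frame with one row per metric: p_region, p_oxygen,
#'   p_interaction
#' @export
regionalAnovaTable <- function(regional) {
  if (!"value" %in% names(regional) && "mean" %in% names(regional))
    regional$value <- regional$mean
  out <- lapply(split(regional, regional$metric), function(df) {
    a <- regionalAnova(df)
    data.frame(metric = df$metric[1], p_region = a$pRegion,
               p_oxygen = a$pOxygen, p_interaction = a$pInteraction)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
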