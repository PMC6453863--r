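#' Expand an axisymmetric WSS profile into sector elements
#'
#' An axisymmetric solution carries one WSS value per axial station; on the
#' mounted lumen that station is a full ring. This replicates each station
#' across circumferential sectors (element angle at the sector centre) with
#' area weight proportional to `wall_radius * dz * dtheta`, producing the
#' long-format wall-element table that [sectorize()] consumes.
#'
#' @param wss data.frame from [compute_wss()].
#' @param segment_bounds Optional list of mm ranges (as in a
#'   `vessel_phantom`'s `segment_bounds`) used to label elements.
#' @param sector_deg Sector width (degrees).
#' @return data.frame: `axial_um`, `angle_deg`, `area`, `wss_pa`, `segment`.
#' @export
axisym_wss_elements <- function(wss, segment_bounds = NULL, sector_deg = 5) {
  centers <- seq(sector_deg / 2, 360 - sector_deg / 2, by = sector_deg)
  n <- nrow(wss)
  k <- length(centers)
  seg <- rep("scaffolded", n)
  if (!is.null(segment_bounds)) {
    z <- wss$axial_um / 1000
    seg <- ifelse(z < segment_bounds$scaffolded[1], "proximal_native",
                  ifelse(z >= segment_bounds$scaffolded[2], "distal_native",
                         "scaffolded"))
  }
  dz <- if (n > 1) stats::median(diff(sort(unique(wss$axial_um)))) else 1
  data.frame(axial_um = rep(wss$axial_um, each = k),
             angle_deg = rep(centers, n),
             area = rep(wss$wall_radius_mm * dz, each = k) * sector_deg,
             wss_pa = rep(wss$wss_pa, each = k),
             on_strut = rep(wss$on_strut, each = k),
             segment = rep(seg, each = k))
}

#' Bin wall shear stress into 5-degree x 200-micron cells
#'
#' Builds the ESS map: the area-weighted mean WSS of the wall elements whose
#' centroid falls in each half-open cell `[k*5, (k+1)*5)` degrees by
#' `[k*200, (k+1)*200)` um. Cells without elements are marked missing (NA),
#' never imputed as zero.
#'
#' @param elements data.frame with `axial_um`, `angle_deg` (in [0, 360)),
#'   `area`, `wss_pa` and optionally `segment`.
#' @param interval_um Axial bin width (um).
#' @param sector_deg Sector width (degrees); 5 gives the canonical 72.
#' @param origin_um Axial origin of interval 0.
#' @return Object of class `ess_map`: `ess` (sectors x intervals matrix, Pa,
#'   NA = missing), `area`, `n`, `segment` per interval, and bin metadata.
#' @export
sectorize <- function(elements, interval_um = 200, sector_deg = 5,
                      origin_um = 0) {
  if (any(elements$angle_deg < 0 | elements$angle_deg >= 360)) {
    stop("element angles must lie in [0, 360)", call. = FALSE)
  }
  n_sector <- as.integer(round(360 / sector_deg))
  si <- floor(elements$angle_deg / sector_deg) + 1L
  ii <- floor((elements$axial_um - origin_um) / interval_um)
  i0 <- min(ii)
  intervals <- seq(i0, max(ii))
  ki <- ii - i0 + 1L
  ess <- matrix(NA_real_, n_sector, length(intervals))
  area <- matrix(0, n_sector, length(intervals))
  nmat <- matrix(0L, n_sector, length(intervals))
  wsum <- tapply(elements$area * elements$wss_pa, list(si, ki), sum)
  asum <- tapply(elements$area, list(si, ki), sum)
  cnt <- tapply(rep(1L, nrow(elements)), list(si, ki), sum)
  rs <- as.integer(rownames(wsum)); cs <- as.integer(colnames(wsum))
  ess[rs, cs] <- wsum / asum
  area[rs, cs] <- ifelse(is.na(asum), 0, asum)
  nmat[rs, cs] <- ifelse(is.na(cnt), 0L, cnt)
  segment <- rep(NA_character_, length(intervals))
  if (!is.null(elements$segment)) {
    tab <- tapply(elements$segment, ki, function(s) names(which.max(table(s))))
    segment[as.integer(names(tab))] <- unname(tab)
  }
  structure(list(ess = ess, area = area, n = nmat,
                 intervals = intervals, segment = segment,
                 sector_deg = sector_deg, interval_um = interval_um,
                 origin_um = origin_um),
            class = "ess_map")
}

#' Low / very-low ESS classification
#'
#' Classifies each non-missing cell with strict thresholds: low ESS is
#' < 1.0 Pa and very-low ESS is < 0.5 Pa (very-low cells are also low; a
#' cell at exactly a threshold is not below it).
#'
#' @param map An `ess_map`.
#' @param low_pa,very_low_pa Thresholds (Pa).
#' @return List: `labels` (matrix: `normal`, `low`, `very_low`; NA for
#'   missing cells), `frac_low`, `frac_very_low` (fractions of non-missing
#'   cells).
#' @export
classify_ess <- function(map, low_pa = 1.0, very_low_pa = 0.5) {
  stopifnot(inherits(map, "ess_map"))
  e <- map$ess
  lab <- ifelse(is.na(e), NA_character_,
                ifelse(e < very_low_pa, "very_low",
                       ifelse(e < low_pa, "low", "normal")))
  ok <- !is.na(e)
  list(labels = lab,
       frac_low = mean(e[ok] < low_pa),
       frac_very_low = mean(e[ok] < very_low_pa))
}

#' Summarize an ESS map
#'
#' Mean, SD, median and low/very-low fractions of the non-missing cells at
#' device level, per cross-section (axial interval; its median is the
#' per-cross-section statistic used for distribution plots), or per segment
#' (scaffolded vs proximal/distal native).
#'
#' @param map An `ess_map`.
#' @param level `"device"`, `"cross_section"` or `"segment"`.
#' @return data.frame with `mean_pa`, `sd_pa`, `median_pa`, `frac_low`,
#'   `frac_very_low`, `n_cells` per group.
#' @export
ess_summary <- function(map, level = c("device", "cross_section", "segment")) {
  stopifnot(inherits(map, "ess_map"))
  level <- match.arg(level)
  one <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("no non-missing ESS cells at the requested level",
                            call. = FALSE)
    data.frame(mean_pa = mean(vals),
               sd_pa = if (length(vals) > 1) stats::sd(vals) else 0,
               median_pa = stats::median(vals),
               frac_low = mean(vals < 1.0),
               frac_very_low = mean(vals < 0.5),
               n_cells = length(vals))
  }
  if (level == "device") {
    out <- one(as.vector(map$ess))
  } else if (level == "cross_section") {
    keep <- colSums(!is.na(map$ess)) > 0
    out <- do.call(rbind, lapply(which(keep), function(k) {
      cbind(interval = map$intervals[k], one(map$ess[, k]))
    }))
  } else {
    segs <- unique(map$segment[!is.na(map$segment)])
    out <- do.call(rbind, lapply(segs, function(sg) {
      cbind(segment = sg, one(as.vector(map$ess[, which(map$segment == sg)])))
    }))
  }
  rownames(out) <- NULL
  out
}

#' Long-format export of an ESS map
#'
#' @param map An `ess_map`.
#' @param scaffold_id Identifier column value.
#' @return data.frame `scaffold_id`, `frame_interval`, `sector`, `ess_pa`,
#'   `segment` (missing cells omitted).
#' @export
ess_map_long <- function(map, scaffold_id = "S01") {
  idx <- which(!is.na(map$ess), arr.ind = TRUE)
  data.frame(scaffold_id = scaffold_id,
             frame_interval = map$intervals[idx[, 2]],
             sector = idx[, 1] - 1L,
             ess_pa = map$ess[idx],
             segment = map$segment[idx[, 2]])
}
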