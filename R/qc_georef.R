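# Georeferencing quality control: horizontal/vertical position error of
# mosaics against RTK ground control, and validation of image-derived canopy
# heights against field measurements.

#' Horizontal position error (RMS) of GCPs
#'
#' Root-mean-square horizontal error over the ground control points:
#' \deqn{HPE = \sqrt{\sum_i (EE_i^2 + NE_i^2) / n}}
#' where EE and NE are the per-point easting and northing errors
#' (observed - true).
#'
#' @param gcps data.frame with columns E_true, N_true, E_obs, N_obs (the
#'   format of \code{\link{generateGcpErrors}} / \code{\link{readGCPs}}).
#' @return HPE in metres.
#' @export
computeHPE <- function(gcps) {
  if (is.null(gcps) || nrow(gcps) < 1) stop("empty GCP set")
  ee <- gcps$E_obs - gcps$E_true
  ne <- gcps$N_obs - gcps$N_true
  sqrt(sum(ee^2 + ne^2) / nrow(gcps))
}

#' Vertical position error from an elevation transect
#'
#' The elevation change of a transect is the sum of absolute elevation
#' differences between contiguous points. VPE is the rectified transect's
#' change minus the non-rectified one, divided by the number of segments
#' (default 4 in the field protocol). The signed value can be negative;
#' the absolute value is reported alongside since published tables list
#' magnitudes without a sign convention.
#'
#' @param rectified,nonRectified ordered point elevations (equal length,
#'   nSegments + 1 points) from the rectified and non-rectified surfaces.
#' @return list with vpe (signed), vpe_abs, delta_z_rectified,
#'   delta_z_non_rectified and n_segments.
#' @export
computeVPE <- function(rectified, nonRectified) {
  if (length(rectified) != length(nonRectified))
    stop("rectified and non-rectified series lengths differ (",
         length(rectified), " vs ", length(nonRectified), ")")
  if (length(rectified) < 2) stop("need at least 2 transect points")
  dzr <- sum(abs(diff(rectified)))
  dznr <- sum(abs(diff(nonRectified)))
  n <- length(rectified) - 1L
  vpe <- (dzr - dznr) / n
  list(vpe = vpe, vpe_abs = abs(vpe),
       delta_z_rectified = dzr, delta_z_non_rectified = dznr,
       n_segments = n)
}

#' Validate image-derived canopy heights against field measurements
#'
#' Pearson correlation between ground-truth canopy heights and UAS-derived
#' ones on paired plots, with two-sided p-value and stars; zero variance in
#' either vector flags the cell NA.
#'
#' @param chGt,chUas paired canopy heights, m (n >= 3).
#' @return one-row data.frame: feature, trait, r, p, stars, n.
#' @export
validateHeights <- function(chGt, chUas) {
  if (length(chGt) != length(chUas)) stop("height vectors must be paired")
  if (length(chGt) < 3) stop("need at least 3 paired heights")
  cell <- .pearsonCell(chGt, chUas)
  data.frame(feature = "CH_uas", trait = "CH_gt", r = cell$r, p = cell$p,
             stars = .starsFor(cell$p), n = cell$n, stringsAsFactors = FALSE)
}

#' Read and write GCP coordinate pairs as CSV
#'
#' Columns: id, E_true, N_true, Z_true, E_obs, N_obs, Z_obs (metres).
#'
#' @param path file path.
#' @param gcps data.frame in the same layout.
#' @return \code{readGCPs}: data.frame; \code{writeGCPs}: the path,
#'   invisibly.
#' @export
readGCPs <- function(path) {
  readTable(path, schema = list(
    required = c("id", "E_true", "N_true", "Z_true", "E_obs", "N_obs", "Z_obs"),
    numeric = c("E_true", "N_true", "Z_true", "E_obs", "N_obs", "Z_obs")))
}

#' @rdname readGCPs
#' @export
writeGCPs <- function(gcps, path) writeTable(gcps, path)
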