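#' Assemble the per-pixel recovery-driver table for a landscape
#'
#' Computes, for every burned pixel, the four driver categories used in the
#' tiered attribution models: site/environmental conditions (elevation, TPI,
#' TRASP, D8 flow direction, soil, subzone), pre-fire conditions and fire
#' impacts (pre-fire basal area, landcover, species, patch size, distance to
#' live edge), climate normals (11 annual/seasonal variables), and post-fire
#' climate anomalies (the z-score of each variable's min/max extreme over
#' post-fire years 1..5 against the 1981-2010 normal). Flat cells with
#' undefined aspect get the neutral TRASP value 0.5.
#'
#' @param landscape A `fire_landscape` from [generate_landscape()].
#' @return Data frame (rows aligned with `landscape$truth`) with a
#'   `categories` attribute mapping each driver to its category.
#' @export
compute_drivers <- function(landscape) {
  stopifnot(inherits(landscape, "fire_landscape"))
  truth <- landscape$truth
  pix <- truth$pixel_id
  ras <- landscape$rasters
  lv <- landscape$raster_levels

  trasp_r <- trasp(ras$aspect)
  trasp_r[is.na(trasp_r)] <- 0.5                # flat-cell convention
  flow_r <- flow_direction_raster(ras$elevation)

  env <- data.frame(
    Elev = ras$elevation[pix],
    TPI = ras$tpi[pix],
    TRASP = trasp_r[pix],
    Flow_direction = factor(flow_r[pix],
                            levels = c(0L, 1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)),
    Soil = factor(ras$soil[pix], levels = lv$soil),
    Subzone = factor(ras$subzone[pix], levels = lv$subzone)
  )

  # fire impacts per fire-year mask; other fires' pixels count as unburned
  fy_mat <- landscape$fire$fire_year
  patch_ha <- matrix(NA_real_, nrow(fy_mat), ncol(fy_mat))
  edge_m <- matrix(NA_real_, nrow(fy_mat), ncol(fy_mat))
  for (y in sort(unique(landscape$fire$fire_years))) {
    mask <- !is.na(fy_mat) & fy_mat == y
    if (!any(mask)) next
    bb <- which(mask, arr.ind = TRUE)
    r0 <- max(1L, min(bb[, 1]) - 1L); r1 <- min(nrow(mask), max(bb[, 1]) + 1L)
    c0 <- max(1L, min(bb[, 2]) - 1L); c1 <- min(ncol(mask), max(bb[, 2]) + 1L)
    sub <- mask[r0:r1, c0:c1, drop = FALSE]
    pm <- patch_metrics(sub, landscape$config$pixel_size_m)
    patch_ha[r0:r1, c0:c1][sub] <- pm$patch_ha[sub]
    edge_m[r0:r1, c0:c1][sub] <- pm$edge_m[sub]
  }
  prefire <- data.frame(
    Prefire_BA = ras$prefire_ba[pix],
    Prefire_landcover = factor(ras$prefire_landcover[pix],
                               levels = lv$prefire_landcover),
    Prefire_species = factor(ras$prefire_species[pix],
                             levels = lv$prefire_species),
    Patch_ha = patch_ha[pix],
    Edge_m = edge_m[pix]
  )

  cvt <- climate_variable_table()
  climate <- as.data.frame(setNames(
    lapply(cvt$variable, function(v) landscape$climate$normals[[v]][pix]),
    cvt$variable
  ))
  anomaly <- as.data.frame(setNames(
    lapply(seq_len(nrow(cvt)), function(i) {
      v <- cvt$variable[i]
      climate_anomaly(landscape$climate$yearly[[v]],
                      landscape$climate$normals[[v]][pix],
                      landscape$climate$sd[[v]], kind = cvt$kind[i])
    }),
    cvt$anomaly
  ))

  out <- cbind(env, prefire, climate, anomaly)
  attr(out, "categories") <- c(
    setNames(rep("environment", ncol(env)), names(env)),
    setNames(rep("prefire_fire", ncol(prefire)), names(prefire)),
    setNames(rep("climate", ncol(climate)), names(climate)),
    setNames(rep("anomaly", ncol(anomaly)), names(anomaly))
  )
  out
}
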