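## Threshed-panicle compensation and per-panicle yield traits.
##
## A mechanical thresher never strips a rice panicle completely: on average
## some spikelets (mostly unfilled ones) stay attached. Counting those
## residual spikelets on the threshed panicle (TPSN) and adding them to the
## conveyor-imaged count recovers the true total, which is what the
## compensation below implements.

#' Compensate a conveyor spikelet total with the threshed-panicle count
#'
#' @param conveyor_total Spikelet count from the conveyor grain images.
#' @param tpsn Residual spikelet count detected on the threshed panicle.
#' @return `conveyor_total + tpsn`. Vectorised.
#' @examples
#' compensate_total(90, 10)  # 100
#' @export
compensate_total <- function(conveyor_total, tpsn) {
  if (any(conveyor_total < 0) || any(tpsn < 0)) {
    stopf("counts must be non-negative")
  }
  conveyor_total + tpsn
}

#' Compute per-panicle yield traits
#'
#' Builds one yield-trait record: compensated total spikelet number,
#' unfilled count, seed setting rate (filled / total), thousand grain
#' weight when a filled-batch weight is available, and mean grain
#' length/width. The seed setting rate is also reported against the
#' *uncompensated* conveyor total (`seed_setting_rate_uncomp`) so the
#' effect of compensation can be inspected per record.
#'
#' @param barcode Sample identifier entered by the operator.
#' @param conveyor_total Total spikelet count from the conveyor images.
#' @param filled_count Filled spikelet count (the air separator routes
#'   filled spikelets to their own conveyor, so identity is physical, not
#'   image-based).
#' @param tpsn Residual spikelet count from the threshed panicle.
#' @param filled_weight_g Optional filled-batch weight in grams.
#' @param shapes Optional data.frame of isolated-grain shapes with columns
#'   `GL_mm`, `GW_mm` (as from [analyze_grains()]).
#' @return One-row data.frame (a yield-trait record) with columns
#'   `barcode`, `conveyor_total_count`, `tpsn`, `total_spikelets`,
#'   `filled_count`, `unfilled_count`, `seed_setting_rate`,
#'   `seed_setting_rate_uncomp`, `filled_weight_g`,
#'   `thousand_grain_weight_g`, `mean_GL_mm`, `mean_GW_mm`.
#' @examples
#' compute_traits("B1", conveyor_total = 90, filled_count = 80, tpsn = 10)
#' @export
compute_traits <- function(barcode, conveyor_total, filled_count, tpsn,
                           filled_weight_g = NA_real_, shapes = NULL) {
  if (!is_count(conveyor_total) || !is_count(filled_count) ||
        !is_count(tpsn)) {
    stopf("counts must be non-negative integers")
  }
  total <- compensate_total(conveyor_total, tpsn)
  if (filled_count > total) {
    stopf("filled_count (%d) exceeds the compensated total (%d)",
          filled_count, total)
  }
  rate <- if (total > 0) filled_count / total else NA_real_
  rate_uncomp <- if (conveyor_total > 0) {
    min(filled_count / conveyor_total, 1)
  } else {
    NA_real_
  }
  tgw <- if (!is.na(filled_weight_g) && filled_count > 0) {
    1000 * filled_weight_g / filled_count
  } else {
    NA_real_   # undefined, reported as missing rather than 0
  }
  data.frame(
    barcode = as.character(barcode),
    conveyor_total_count = as.integer(conveyor_total),
    tpsn = as.integer(tpsn),
    total_spikelets = as.integer(total),
    filled_count = as.integer(filled_count),
    unfilled_count = as.integer(total - filled_count),
    seed_setting_rate = rate,
    seed_setting_rate_uncomp = rate_uncomp,
    filled_weight_g = filled_weight_g,
    thousand_grain_weight_g = tgw,
    mean_GL_mm = if (!is.null(shapes) && nrow(shapes)) {
      mean(shapes$GL_mm)
    } else {
      NA_real_
    },
    mean_GW_mm = if (!is.null(shapes) && nrow(shapes)) {
      mean(shapes$GW_mm)
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
}

#' Threshing error percentage
#'
#' The share of a panicle's spikelets left on the threshed panicle,
#' `100 * tpsn / total_spikelets` - the error that total spikelet counts
#' would carry without compensation.
#'
#' @param tpsn Residual spikelet count(s).
#' @param total_spikelets Compensated total(s), > 0.
#' @return Percentage value(s). Vectorised.
#' @examples
#' threshing_error_pct(10, 100)  # 10
#' @export
threshing_error_pct <- function(tpsn, total_spikelets) {
  if (any(total_spikelets <= 0)) stopf("total_spikelets must be > 0")
  if (any(tpsn < 0)) stopf("tpsn must be >= 0")
  100 * tpsn / total_spikelets
}
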