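#' Background-corrected integrated density
#'
#' The final signal of a measured region is its integrated density minus the
#' region area times the mean of the (three) background fluorescence
#' readings taken on the same image. Negative corrected signals are
#' retained and flagged, not clamped.
#'
#' @param integrated_density raw integrated density of the region.
#' @param area region area in pixels^2 (> 0).
#' @param bg matrix or data frame of background mean-fluorescence readings
#'   (one row per measurement, typically 3 columns), or a numeric vector
#'   for a single measurement.
#' @return Data frame `signal, flag_negative`.
#' @export
#' @examples
#' corrected_signal(1000, 100, c(2, 2, 2))  # 800
corrected_signal <- function(integrated_density, area, bg) {
  if (any(area <= 0)) stop("area must be positive")
  bgm <- if (is.null(dim(bg))) mean(bg) else rowMeans(as.matrix(bg))
  sig <- integrated_density - area * bgm
  data.frame(signal = sig, flag_negative = sig < 0)
}

#' Partition a cell's signal into nuclear and cytoplasmic components
#'
#' The cytoplasmic signal is the total-cell signal minus the nuclear signal
#' (exact conservation); the ratio is cytoplasmic over total, defined only
#' for positive totals.
#'
#' @param total_corrected,nuclear_corrected background-corrected signals per
#'   cell (vectorised).
#' @return Data frame `nuclear, cytoplasmic, cyto_over_total,
#'   flag_undefined`.
#' @export
#' @examples
#' partition_cell(800, 300)  # cytoplasmic 500, ratio 0.625
partition_cell <- function(total_corrected, nuclear_corrected) {
  cyto <- total_corrected - nuclear_corrected
  bad <- total_corrected <= 0
  ratio <- ifelse(bad, NA_real_, cyto / total_corrected)
  data.frame(nuclear = nuclear_corrected, cytoplasmic = cyto,
             cyto_over_total = ratio, flag_undefined = bad)
}

#' Quantify an smFISH region-measurement table
#'
#' Full per-cell pipeline: background-correct the `total_cell` and
#' `nucleus` rows of each cell, then partition into nuclear and cytoplasmic
#' signal.
#'
#' @param measurements data frame with columns `cell, region,
#'   integrated_density, area, bg1, bg2, bg3`; exactly one `total_cell` and
#'   one `nucleus` row per cell.
#' @return Data frame per cell: `cell, total, nuclear, cytoplasmic,
#'   cyto_over_total, flag_negative, flag_undefined`.
#' @export
smfish_quantify <- function(measurements) {
  need <- c("cell", "region", "integrated_density", "area",
            "bg1", "bg2", "bg3")
  if (!all(need %in% names(measurements)))
    stop("measurement table needs columns: ", paste(need, collapse = ", "))
  tot <- measurements[measurements$region == "total_cell", , drop = FALSE]
  nuc <- measurements[measurements$region == "nucleus", , drop = FALSE]
  cells <- unique(measurements$cell)
  if (anyDuplicated(tot$cell) || anyDuplicated(nuc$cell) ||
      !setequal(tot$cell, cells) || !setequal(nuc$cell, cells))
    stop("each cell needs exactly one total_cell and one nucleus row")
  nuc <- nuc[match(tot$cell, nuc$cell), , drop = FALSE]
  cs_t <- corrected_signal(tot$integrated_density, tot$area,
                           tot[, c("bg1", "bg2", "bg3")])
  cs_n <- corrected_signal(nuc$integrated_density, nuc$area,
                           nuc[, c("bg1", "bg2", "bg3")])
  part <- partition_cell(cs_t$signal, cs_n$signal)
  # report the total as nuclear + cytoplasmic so conservation is bit-exact
  # (differs from the corrected total by at most one ulp)
  data.frame(cell = tot$cell, total = part$nuclear + part$cytoplasmic, part,
             flag_negative = cs_t$flag_negative | cs_n$flag_negative,
             stringsAsFactors = FALSE, row.names = NULL)
}
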