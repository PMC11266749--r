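# Per-cell RNA concentration from mid-nucleus z-slices, and P4-vs-P1
# enrichment.
#
# The concentration statistic is
#     [P] = (intensity / area of cell) - (intensity / area of nucleus)
# on the z-slice centred on the nucleus: the transcriptionally silent
# nucleus carries only background, so the nuclear term cancels any uniform
# background shared by cytoplasm and nucleus. Enrichment is
# [P4] / mean([P1]) over a cohort of (at least three) P1 blastomeres.

#' Mid-nucleus slice index
#'
#' The z-slice maximizing the nucleus mask area (ties to the lower slice) —
#' the operational reading of "centred on the nucleus".
#'
#' @param roi a `cell_roi` with 3D masks.
#' @return a 0-based slice index.
#' @export
mid_nucleus_slice <- function(roi) {
  stopifnot(inherits(roi, "cell_roi"))
  if (length(dim(roi$nucleus_mask)) != 3L) stop("need 3D masks")
  areas <- apply(roi$nucleus_mask, 1, sum)
  which.max(areas) - 1L
}

#' Per-cell concentration from one z-slice
#'
#' @param slice_image 2D (y, x) intensity matrix — the raw slice; the
#'   nuclear term serves as the background control.
#' @param cell_mask,nucleus_mask 2D masks for this slice.
#' @param lineage lineage label recorded in the result.
#' @param slice_index 0-based z index recorded in the result.
#' @return a one-row data frame: `lineage`, `concentration` (counts per
#'   pixel), `slice_index`, `cell_area_px`, `nucleus_area_px`. A negative
#'   concentration (nucleus brighter than cytoplasm) is allowed but logged.
#' @export
cell_concentration <- function(slice_image, cell_mask, nucleus_mask,
                               lineage = NA_character_,
                               slice_index = NA_integer_) {
  stopifnot(is.matrix(slice_image),
            identical(dim(slice_image), dim(cell_mask)),
            identical(dim(slice_image), dim(nucleus_mask)))
  cell_mask <- cell_mask != 0; nucleus_mask <- nucleus_mask != 0
  if (any(nucleus_mask & !cell_mask)) stop("nucleus not contained in cell")
  a_cell <- sum(cell_mask); a_nuc <- sum(nucleus_mask)
  if (a_nuc < 1 || a_cell <= a_nuc)
    stop("need cell area > nucleus area > 0")
  conc <- sum(slice_image[cell_mask]) / a_cell -
    sum(slice_image[nucleus_mask]) / a_nuc
  if (conc < 0)
    gf_log("negative concentration (%.3g): nucleus brighter than cytoplasm", conc)
  data.frame(lineage = lineage, concentration = conc,
             slice_index = slice_index, cell_area_px = a_cell,
             nucleus_area_px = a_nuc, stringsAsFactors = FALSE)
}

#' Concentration of a whole stack at the mid-nucleus slice
#'
#' Convenience wrapper: picks the mid-nucleus slice of `roi` and applies
#' [cell_concentration()] with the 2D masks of that slice.
#'
#' @param stack an `image_stack`.
#' @param roi a `cell_roi` with 3D masks matching the stack.
#' @return see [cell_concentration()].
#' @export
stack_concentration <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"))
  z <- mid_nucleus_slice(roi)
  cell_concentration(stack$voxels[z + 1L, , ],
                     roi$cell_mask[z + 1L, , ],
                     roi$nucleus_mask[z + 1L, , ],
                     lineage = roi$lineage, slice_index = z)
}

#' P4 enrichment over the P1 cohort
#'
#' @param conc_p4 a concentration record (or scalar) for the P4 cell.
#' @param conc_p1 concentration records (or numeric vector) for the P1
#'   cohort; at least `min_p1` values are required.
#' @param min_p1 minimum P1 cohort size (default 3, the protocol cohort).
#' @return the ratio `[P4] / mean([P1])`.
#' @export
p4_enrichment <- function(conc_p4, conc_p1, min_p1 = 3L) {
  val <- function(x) if (is.data.frame(x)) x$concentration else as.numeric(x)
  p4 <- val(conc_p4)
  p1 <- if (is.data.frame(conc_p1)) conc_p1$concentration
        else unlist(lapply(conc_p1, val))
  stopifnot(length(p4) == 1L)
  if (length(p1) < min_p1)
    stop("need at least ", min_p1, " P1 concentration records, got ", length(p1))
  m <- mean(p1)
  if (m <= 0) stop("mean P1 concentration is not positive; cannot form a ratio")
  p4 / m
}
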