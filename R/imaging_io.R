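# Image stacks, cell ROIs, pipeline configuration and table I/O.
#
# Conventions (global to the package):
#   * voxel arrays are stored in (z, y, x) axis order;
#   * coordinates are 0-based, in fractional pixel units for x/y and
#     fractional slice units for z;
#   * distances/tolerances are in pixels (x, y) and slices (z), never nm;
#     physical geometry (pixel_size_xy, z_step, nm) is carried as metadata.

LINEAGES <- c("P1", "P2", "P3", "P4", "somatic")

#' Construct a 3D image stack
#'
#' The basic substrate of the pipeline: a (z, y, x) voxel grid plus the
#' physical geometry of the acquisition. Values must be finite and
#' non-negative (camera counts).
#'
#' @param voxels numeric 3D array in (z, y, x) order; a matrix is promoted to
#'   a single-slice stack with a warning.
#' @param pixel_size_xy lateral pixel size in nm.
#' @param z_step axial slice spacing in nm.
#' @param channel free-text channel label (e.g. `"rna"`, `"granule"`).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_xy = 65, z_step = 300,
                        channel = "rna") {
  if (is.matrix(voxels)) {
    warning("2D image promoted to a single-slice stack")
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.numeric(voxels))
    stop("`voxels` must be a numeric 3D array in (z, y, x) order")
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1")
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  if (any(voxels < 0)) stop("voxel values must be >= 0")
  if (!isTRUE(pixel_size_xy > 0) || !isTRUE(z_step > 0))
    stop("pixel_size_xy and z_step must be > 0")
  structure(list(voxels = voxels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, channel = as.character(channel)),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack '%s': %d slices x %d x %d px, %g nm/px, %g nm/slice\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_xy, x$z_step))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a TIFF z-stack
#'
#' Reads a (multi-page) TIFF into an `image_stack` in (z, y, x) order.
#' Samples are read as stored (`as.is`), so the 16-bit integer stacks
#' written by [write_stack()] come back as the original camera counts.
#' Files lacking resolution metadata fall back to the supplied geometry
#' defaults.
#'
#' @param path TIFF file path.
#' @param pixel_size_xy,z_step geometry defaults (nm) used when the file
#'   carries no resolution tags.
#' @param channel channel label to attach.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, pixel_size_xy = 65, z_step = 300,
                       channel = "rna") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  info <- attr(pages[[1]], "info")
  if (!is.null(info) && !is.null(info$x.resolution) && info$x.resolution > 0) {
    # TIFF resolution is pixels per unit; unit handling is out of scope, we
    # only honour tags our own writer never emits, so defaults usually apply.
    pixel_size_xy <- 1e7 / info$x.resolution
  }
  if (length(pages) == 1L && length(dim(pages[[1]])) == 2L)
    warning("2D TIFF promoted to a single-slice stack: ", path)
  nz <- length(pages)
  d2 <- dim(pages[[1]])[1:2]
  vox <- array(0, dim = c(nz, d2[1], d2[2]))
  for (z in seq_len(nz)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # first sample of multi-sample
    if (!is.numeric(pg)) stop("non-numeric pixel data in ", path)
    vox[z, , ] <- pg
  }
  image_stack(vox, pixel_size_xy = pixel_size_xy, z_step = z_step,
              channel = channel)
}

#' Write an image stack to TIFF
#'
#' Stores voxels as a 16-bit unsigned-integer multi-page TIFF (one page per
#' z-slice) — the standard raw-microscopy representation. Values must be
#' integer camera counts in `[0, 65535]`; such stacks round-trip exactly
#' through [read_stack()].
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (max(v) > 65535 || any(v != round(v)))
    stop("stacks are stored as 16-bit TIFF: voxel values must be integer ",
         "counts in [0, 65535]")
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none", reduce = FALSE),
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Construct a cell/nucleus region of interest
#'
#' Masks may be 3D (z, y, x) or a single 2D (y, x) slice; the nucleus must be
#' contained in the cell and strictly smaller.
#'
#' @param cell_mask,nucleus_mask logical arrays of identical shape.
#' @param lineage one of `"P1"`, `"P2"`, `"P3"`, `"P4"`, `"somatic"`.
#' @return an object of class `cell_roi` with precomputed areas/volumes.
#' @export
cell_roi <- function(cell_mask, nucleus_mask, lineage = "somatic") {
  lineage <- match.arg(lineage, LINEAGES)
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stop("cell and nucleus masks must have identical dimensions")
  cell_mask <- cell_mask != 0; nucleus_mask <- nucleus_mask != 0
  if (any(nucleus_mask & !cell_mask))
    stop("nucleus mask must be contained in the cell mask")
  vc <- sum(cell_mask); vn <- sum(nucleus_mask)
  if (!(vc > vn && vn > 0))
    stop("need cell volume > nucleus volume > 0")
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 lineage = lineage, volume_vox = c(cell = vc, nucleus = vn)),
            class = "cell_roi")
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("cell_roi [%s]: cell %d vox, nucleus %d vox (%s)\n", x$lineage,
              x$volume_vox["cell"], x$volume_vox["nucleus"],
              paste(dim(x$cell_mask), collapse = " x ")))
  invisible(x)
}

#' Pipeline configuration
#'
#' Every analysis constant is a named, overridable key. Defaults follow the
#' published protocol: 50 px rolling-ball background subtraction, Gaussian
#' blur sigma 1 for granule segmentation, a ~150 nm diffraction-limited PSF,
#' clusters defined as >= 4 molecules in one spot, colocalization tolerance
#' 2 px in x/y and 2 slices in z, and a 2 px pad on granule bounding cubes.
#'
#' @param background_radius_px rolling-ball radius for background
#'   subtraction (px).
#' @param blur_sigma Gaussian blur sigma for granule segmentation (px).
#' @param psf_width_nm nominal diffraction-limited spot size (nm); carried
#'   as metadata.
#' @param psf_sigma_xy_px,psf_sigma_z_slices Gaussian PSF sd used by the
#'   spot fitter, in pixels / slices.
#' @param cluster_min_molecules molecules per focus at/above which a spot is
#'   called a cluster.
#' @param coloc_tol_xy_px,coloc_tol_z_slices cluster-cluster colocalization
#'   tolerances.
#' @param cube_pad_px pad added to the granule minor radius when building
#'   membership cubes.
#' @param detect_threshold absolute detection threshold on the
#'   background-subtracted stack; `NULL` selects the automatic
#'   median + k * MAD rule.
#' @param auto_threshold_k `k` of the automatic threshold rule.
#' @param min_separation_px non-maximum-suppression radius for candidate
#'   seeds (px/slices, Chebyshev).
#' @param min_calibration_spots minimum somatic spot count required to
#'   calibrate the single-molecule intensity.
#' @param min_granule_vox minimum connected-component volume kept as a
#'   granule (voxels).
#' @param min_threshold_contrast minimum height of the granule threshold
#'   above the image median, in robust deviations (MADs) of the blurred
#'   marker channel; below it the channel is treated as structureless and
#'   no granules are called.
#' @param manual_granule_threshold fallback granule threshold when
#'   maximum-entropy thresholding fails; `NULL` means no fallback.
#' @param watershed_3d apply the watershed in full 3D instead of per slice.
#' @param watershed_tolerance watershed merge tolerance (see
#'   [EBImage::watershed()]).
#' @param pixel_size_xy,z_step acquisition geometry defaults (nm).
#' @param rng_seed seed recorded into run manifests.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(background_radius_px = 50L,
                            blur_sigma = 1,
                            psf_width_nm = 150,
                            psf_sigma_xy_px = 1.0,
                            psf_sigma_z_slices = 1.1,
                            cluster_min_molecules = 4L,
                            coloc_tol_xy_px = 2L,
                            coloc_tol_z_slices = 2L,
                            cube_pad_px = 2L,
                            detect_threshold = NULL,
                            auto_threshold_k = 8,
                            min_separation_px = 2L,
                            min_calibration_spots = 50L,
                            min_granule_vox = 4L,
                            min_threshold_contrast = 5,
                            manual_granule_threshold = NULL,
                            watershed_3d = FALSE,
                            watershed_tolerance = 1,
                            pixel_size_xy = 65,
                            z_step = 300,
                            rng_seed = NULL) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("background_radius_px", "blur_sigma", "psf_width_nm",
           "psf_sigma_xy_px", "psf_sigma_z_slices", "coloc_tol_xy_px",
           "coloc_tol_z_slices", "min_separation_px", "pixel_size_xy",
           "z_step")
  for (k in pos) if (!isTRUE(cfg[[k]] > 0)) stop("config `", k, "` must be > 0")
  if (!isTRUE(cfg$cube_pad_px >= 0)) stop("config `cube_pad_px` must be >= 0")
  if (!isTRUE(cfg$cluster_min_molecules >= 2))
    stop("config `cluster_min_molecules` must be >= 2")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected; missing keys take their defaults.
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# ---- tabular I/O -----------------------------------------------------------

SPOT_COLUMNS <- c("id", "z", "y", "x", "intensity", "residual", "edge",
                  "lineage", "n_molecules", "is_cluster", "granule_id")
GRANULE_COLUMNS <- c("granule_id", "z", "y", "x", "minor_radius_px",
                     "major_radius_px", "volume_vox")
SCREEN_COLUMNS <- c("transcript_id", "foci_P1", "foci_P2", "foci_P3",
                    "foci_P4", "pgc_pattern", "group")

table_kind <- function(df) {
  if (all(c("intensity", "x") %in% names(df))) return("spot")
  if ("minor_radius_px" %in% names(df)) return("granule")
  if ("transcript_id" %in% names(df)) return("screen")
  stop("cannot infer table kind from columns: ",
       paste(names(df), collapse = ", "))
}

validate_table <- function(df, kind = table_kind(df)) {
  req <- switch(kind,
                spot = c("id", "z", "y", "x", "intensity"),
                granule = GRANULE_COLUMNS,
                screen = c("transcript_id", "foci_P1", "foci_P2", "foci_P3",
                           "foci_P4", "pgc_pattern"))
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(kind, " table missing columns: ",
                         paste(miss, collapse = ", "))
  if (kind == "spot" && nrow(df)) {
    if (any(!is.finite(df$intensity)))
      stop("spot table has non-finite intensity values")
    if (any(df$intensity <= 0)) stop("spot intensities must be > 0")
  }
  if (kind == "granule" && nrow(df)) {
    if (any(!(df$major_radius_px >= df$minor_radius_px & df$minor_radius_px > 0)))
      stop("granule radii must satisfy major >= minor > 0")
    if (any(df$volume_vox < 1)) stop("granule volumes must be >= 1 voxel")
  }
  invisible(kind)
}

#' Write / read a result table as CSV
#'
#' Tables are validated against their invariants before writing. Column
#' order is fixed (documented per table kind), floats are written at full
#' precision (`%.17g`), and `read_table()` is the exact inverse on valid
#' tables.
#'
#' @param df a spot, granule or screen table (data frame).
#' @param path CSV path.
#' @export
write_table <- function(df, path) {
  kind <- validate_table(df)
  order_cols <- switch(kind, spot = SPOT_COLUMNS, granule = GRANULE_COLUMNS,
                       screen = SCREEN_COLUMNS)
  cols <- c(intersect(order_cols, names(df)), setdiff(names(df), order_cols))
  df <- df[, cols, drop = FALSE]
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df)
  df
}
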