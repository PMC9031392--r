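#' Write an image series to disk with a CSV manifest
#'
#' Frames are written as greyscale PNG (8-bit) or TIFF files plus a
#' manifest CSV with columns `file, sample_id, blend_label, time_h`. For a
#' synthetic series the ground-truth table is written alongside as
#' `<sample_id>_truth.csv`.
#'
#' @param series an [image_series()].
#' @param dir output directory (created if missing).
#' @param format `"png"` (default) or `"tiff"` (needs the tiff package).
#' @return Invisibly, the manifest path.
#' @export
write_image_series <- function(series, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  files <- sprintf("%s_t%04d.%s", series$sample_id,
                   seq_along(series$frames), ext)
  for (i in seq_along(series$frames)) {
    f <- clamp01(to_grey(series$frames[[i]]))
    path <- file.path(dir, files[i])
    if (format == "png") {
      png::writePNG(f, path)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_phb("the tiff package is required for TIFF output")
      tiff::writeTIFF(f, path)
    }
  }
  manifest <- data.frame(file = files, sample_id = series$sample_id,
                         blend_label = series$blend_label,
                         time_h = series$times)
  manifest_path <- file.path(dir, sprintf("%s_manifest.csv", series$sample_id))
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  if (!is.null(series$truth))
    utils::write.csv(series$truth,
                     file.path(dir, sprintf("%s_truth.csv", series$sample_id)),
                     row.names = FALSE)
  invisible(manifest_path)
}

read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_phb("the tiff package is required to read TIFF frames")
      tiff::readTIFF(path)
    },
    stop_phb("unsupported frame format: '%s'", ext)
  )
  to_grey(img)
}

#' Read one image series from a CSV manifest
#'
#' @param manifest_path CSV with columns `file, sample_id, blend_label,
#'   time_h`; frame paths are resolved relative to the manifest's
#'   directory. The manifest must describe a single sample.
#' @param well optional boolean well mask.
#' @return An [image_series()].
#' @export
read_image_series <- function(manifest_path, well = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "sample_id", "blend_label", "time_h")
  if (!all(need %in% names(man)))
    stop_phb("manifest must have columns %s", paste(need, collapse = ", "))
  if (length(unique(man$sample_id)) != 1L)
    stop_phb("manifest describes more than one sample_id")
  man <- man[order(man$time_h), , drop = FALSE]
  frames <- lapply(file.path(dirname(manifest_path), man$file), read_frame)
  image_series(frames, man$time_h, sample_id = man$sample_id[1],
               blend_label = man$blend_label[1], well = well)
}

#' Read spectra from two-column CSV files via a manifest
#'
#' @param manifest_path CSV with columns `file, time_h`; each spectrum
#'   file is a two-column CSV `(ppm, intensity)`, resolved relative to the
#'   manifest.
#' @return A list of [spectrum()]s ordered by time.
#' @export
read_spectra <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "time_h") %in% names(man)))
    stop_phb("spectra manifest must have columns file, time_h")
  man <- man[order(man$time_h), , drop = FALSE]
  lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(dirname(manifest_path), man$file[i]))
    spectrum(d[[1]], d[[2]], label = man$file[i], time_h = man$time_h[i])
  })
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec a [spectrum()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write binary masks of a series as 0/255 PNG files
#'
#' @param binary a [binarize_series()] result.
#' @param dir output directory.
#' @return Invisibly, the file paths.
#' @export
write_masks <- function(binary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_mask_t%04d.png", binary$sample_id,
                                  seq_along(binary$masks)))
  for (i in seq_along(binary$masks)) {
    png::writePNG(binary$masks[[i]] * 1, paths[i])
  }
  invisible(paths)
}
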