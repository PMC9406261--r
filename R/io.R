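## Raster conventions, used everywhere: row-major, origin top-left,
## pixel-center sampling; masks are logical in memory and 0/255 in files.
## The tiff package stores 32-bit float pages clamped to [0, 1], so stacks
## are written divided by a global intensity scale recorded in a JSON
## sidecar (<stem>.json) together with wavelengths and pixel size.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a lambda stack as multi-page float TIFF with a JSON sidecar
#'
#' One 32-bit float page per wavelength. Intensities are stored divided by
#' a global scale (their maximum) to fit the TIFF float range; the scale,
#' the wavelength list and the pixel size go to a sidecar file
#' `<stem>.json`, from which [readLambdaStack()] restores the stack
#' exactly.
#'
#' @param stack a [LambdaStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeLambdaStack <- function(stack, path) {
  stopifnot(is(stack, "LambdaStack"))
  scale <- max(stack@data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(nPlanes(stack)),
                  function(i) stack@data[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(wavelengths_nm = stack@wavelengths,
               intensity_scale = scale,
               pixel_size_um = if (is.na(stack@pixelSize)) NULL else
                 stack@pixelSize)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## "480:10", "480:10:22" or "480,490,..." -> numeric wavelengths
parseWavelengthSpec <- function(spec, nPages) {
  if (is.numeric(spec))
    return(as.numeric(spec))
  if (grepl(",", spec, fixed = TRUE))
    return(as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]]))
  parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2L)
    return(seq(parts[1], by = parts[2], length.out = nPages))
  if (length(parts) == 3L)
    return(seq(parts[1], by = parts[2], length.out = parts[3]))
  stop("cannot parse wavelength spec '", spec,
       "'; use start:step, start:step:count, or a comma list")
}

#' Read a lambda stack from a multi-page TIFF
#'
#' Wavelengths come from the JSON sidecar written by [writeLambdaStack()]
#' when present; otherwise they must be given explicitly as a numeric
#' vector or a string (`"480:10"`, `"480:10:22"`, or a comma-separated
#' list). A stack without either is an error — wavelengths are never
#' guessed.
#'
#' @param path TIFF path.
#' @param wavelengths explicit wavelength spec (optional when a sidecar
#'   exists; overrides it when given).
#' @param pixelSize pixel size in micrometres; overrides the sidecar.
#' @return A [LambdaStack-class].
#' @export
readLambdaStack <- function(path, wavelengths = NULL, pixelSize = NULL) {
  if (!file.exists(path))
    stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, asGreyMatrix)
  scale <- 1
  scPx <- NA_real_
  scWl <- NULL
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    scWl <- meta$wavelengths_nm
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    if (!is.null(meta$pixel_size_um)) scPx <- meta$pixel_size_um
  }
  if (is.null(wavelengths)) wavelengths <- scWl
  if (is.null(wavelengths))
    stop("no wavelength metadata found for ", path,
         "; supply wavelengths explicitly (e.g. \"480:10\")")
  wl <- parseWavelengthSpec(wavelengths, length(pages))
  if (length(wl) != length(pages))
    stop("wavelength count mismatch: ", length(wl), " wavelengths for ",
         length(pages), " planes")
  if (is.null(pixelSize)) pixelSize <- scPx
  LambdaStack(lapply(pages, function(p) p * scale), wl,
              pixelSize = pixelSize)
}

## collapse an RGB(A) page read by readTIFF to one grey matrix
asGreyMatrix <- function(p) {
  if (length(dim(p)) == 3L) {
    if (dim(p)[3] >= 3L) p <- (p[, , 1] + p[, , 2] + p[, , 3]) / 3
    else p <- p[, , 1]
  }
  p
}

#' Read a single-channel intensity image from TIFF
#'
#' @param path TIFF path.
#' @param page page index for multi-page files (default 1).
#' @return Numeric matrix in the file's stored scale ([0, 1] for integer
#'   TIFFs as read by the tiff package).
#' @export
readIntensityImage <- function(path, page = 1L) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (page > length(pages))
    stop("page ", page, " requested but ", path, " has ",
         length(pages), " page(s)")
  asGreyMatrix(pages[[page]])
}

#' Read a FITC/TRITC channel pair
#'
#' Either two single-channel TIFFs, or one two-page TIFF with the page
#' indices of each channel.
#'
#' @param fitcPath,tritcPath TIFF paths; give the same path twice (or
#'   `tritcPath = NULL`) with `fitcPage`/`tritcPage` for a two-channel
#'   file.
#' @param fitcPage,tritcPage page indices (defaults 1 and 2 when both
#'   channels come from one file, else 1 and 1).
#' @param pixelSize pixel size in micrometres (optional).
#' @return A [ChannelPair-class].
#' @export
readChannelPair <- function(fitcPath, tritcPath = NULL, fitcPage = NULL,
                            tritcPage = NULL, pixelSize = NA_real_) {
  onefile <- is.null(tritcPath) || identical(fitcPath, tritcPath)
  if (is.null(tritcPath)) tritcPath <- fitcPath
  if (is.null(fitcPage)) fitcPage <- 1L
  if (is.null(tritcPage)) tritcPage <- if (onefile) 2L else 1L
  ChannelPair(readIntensityImage(fitcPath, fitcPage),
              readIntensityImage(tritcPath, tritcPage),
              pixelSize = pixelSize)
}

#' Write / read a binary mask as 8-bit TIFF (0/255)
#'
#' @param mask logical (or 0/1) matrix.
#' @param path TIFF path.
#' @return `writeMask` returns `path` invisibly; `readMask` a logical
#'   matrix.
#' @export
writeMask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  readIntensityImage(path) > 0
}

#' Write a peak map as float TIFF plus a pseudo-colour rendering
#'
#' The quantitative map stores wavelength / 1000 (so 550 nm is 0.55) in a
#' 32-bit float TIFF, with 0 as the invalid-pixel sentinel. The companion
#' `<stem>_rgb.tif` is an 8-bit rendering mapping the wavelength range
#' from blue through green to red for quick inspection.
#'
#' @param peakmap a [PeakMap-class].
#' @param path output TIFF path for the quantitative map.
#' @return `path`, invisibly.
#' @export
writePeakMap <- function(peakmap, path) {
  stopifnot(is(peakmap, "PeakMap"))
  q <- peakmap@peak / 1000
  q[is.na(q)] <- 0
  tiff::writeTIFF(q, path, bits.per.sample = 32L, reduce = FALSE)
  rng <- range(peakmap@wavelengths)
  frac <- (peakmap@peak - rng[1]) / (rng[2] - rng[1])
  frac[is.na(frac)] <- 0
  rgb <- array(0, dim = c(dim(frac), 3))
  rgb[, , 1] <- pmax(0, frac * 2 - 1)          # red grows past midrange
  rgb[, , 2] <- 1 - abs(frac * 2 - 1)          # green peaks midrange
  rgb[, , 3] <- pmax(0, 1 - frac * 2)          # blue at short wavelengths
  invalid <- is.na(peakmap@peak)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[invalid] <- 0
    rgb[, , ch] <- plane
  }
  tiff::writeTIFF(rgb, paste0(tools::file_path_sans_ext(path), "_rgb.tif"),
                  bits.per.sample = 8L)
  invisible(path)
}

#' Write a spectrum profile as a two-column CSV
#'
#' Columns `wavelength_nm, mean_intensity`.
#'
#' @param profile a [SpectrumProfile-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(profile, path) {
  stopifnot(is(profile, "SpectrumProfile"))
  df <- data.frame(wavelength_nm = profile@wavelengths,
                   mean_intensity = profile@meanIntensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write quantification results as CSV
#'
#' Fixed header
#' `file,tissue_threshold,blood_threshold,tissue_area_px,blood_area_px,tissue_area_um2,blood_area_um2,blood_percent`;
#' pixel areas as integers, square-micrometre areas and percentages with
#' two decimals (empty when the pixel size is unknown). Re-reading the
#' file recovers the values at that precision.
#'
#' @param results a [QuantResult-class] or list of them.
#' @param path CSV path.
#' @param files source-image labels, one per result (default `image_1`,
#'   ...).
#' @return `path`, invisibly.
#' @export
writeReport <- function(results, path, files = NULL) {
  if (is(results, "QuantResult"))
    results <- list(results)
  if (length(results) == 0L)
    stop("no results to report")
  if (is.null(files))
    files <- paste0("image_", seq_along(results))
  fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  rows <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    paste(files[i], r@tissueThreshold, r@bloodThreshold, r@tissueAreaPx,
          r@bloodAreaPx, fmt2(r@tissueAreaUm2), fmt2(r@bloodAreaUm2),
          fmt2(r@bloodPercent), sep = ",")
  }, character(1))
  header <- paste("file", "tissue_threshold", "blood_threshold",
                  "tissue_area_px", "blood_area_px", "tissue_area_um2",
                  "blood_area_um2", "blood_percent", sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

specKeyMap <- c(width = "width_px", height = "height_px",
                pixelSize = "pixel_size_um", rbcDiameter = "rbc_diameter_um",
                rbcCount = "rbc_count", tissueFillFraction =
                  "tissue_fill_fraction", seed = "seed")

#' Serialise a PhantomSpec to / from a YAML config file
#'
#' Keys: `width_px`, `height_px`, `pixel_size_um`, `wavelength_grid`,
#' `tissue_model` / `blood_model` (each `peak_wavelength`,
#' `bandwidth_sigma`, `amplitude`), `rbc_diameter_um`, `rbc_count`,
#' `vessel_regions` (list of `center`, `axes`, `angle`),
#' `tissue_fill_fraction`, `noise` (`poisson_scale`, `gaussian_sigma`) and
#' `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param path YAML path.
#' @return `writePhantomSpec` returns `path` invisibly;
#'   `readPhantomSpec` a [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  modelList <- function(m) list(peak_wavelength = m@peak,
                                bandwidth_sigma = m@sigma,
                                amplitude = m@amplitude)
  obj <- list(width_px = spec@width, height_px = spec@height,
              pixel_size_um = spec@pixelSize,
              wavelength_grid = spec@wavelengths,
              tissue_model = modelList(spec@tissueModel),
              blood_model = modelList(spec@bloodModel),
              rbc_diameter_um = spec@rbcDiameter,
              rbc_count = spec@rbcCount,
              vessel_regions = spec@vesselRegions,
              tissue_fill_fraction = spec@tissueFillFraction,
              noise = list(poisson_scale = spec@noise$poissonScale,
                           gaussian_sigma = spec@noise$gaussianSigma),
              seed = spec@seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$seed))
    stop("config has no seed; unseeded phantom generation is an error")
  model <- function(m, default) {
    if (is.null(m)) return(default)
    SpectralModel(m$peak_wavelength, m$bandwidth_sigma, m$amplitude)
  }
  args <- list(seed = obj$seed)
  if (!is.null(obj$width_px)) args$width <- obj$width_px
  if (!is.null(obj$height_px)) args$height <- obj$height_px
  if (!is.null(obj$pixel_size_um)) args$pixelSize <- obj$pixel_size_um
  if (!is.null(obj$wavelength_grid)) args$wavelengths <- obj$wavelength_grid
  args$tissueModel <- model(obj$tissue_model, tissueModel())
  args$bloodModel <- model(obj$blood_model, bloodModel())
  if (!is.null(obj$rbc_diameter_um)) args$rbcDiameter <- obj$rbc_diameter_um
  if (!is.null(obj$rbc_count)) args$rbcCount <- obj$rbc_count
  if (!is.null(obj$vessel_regions))
    args$vesselRegions <- lapply(obj$vessel_regions, function(v)
      list(center = as.numeric(v$center), axes = as.numeric(v$axes),
           angle = if (is.null(v$angle)) 0 else v$angle))
  if (!is.null(obj$tissue_fill_fraction))
    args$tissueFillFraction <- obj$tissue_fill_fraction
  if (!is.null(obj$noise))
    args$noise <- list(poissonScale = obj$noise$poisson_scale,
                       gaussianSigma = obj$noise$gaussian_sigma)
  do.call(PhantomSpec, args)
}

#' Write a rendered phantom to a directory
#'
#' Writes `stack.tif` (+ sidecar), `fitc.tif`, `tritc.tif`,
#' `tissue_mask.tif`, `blood_mask.tif` and `truth.json` (the spec seed and
#' the exact ground-truth blood percentage).
#'
#' @param phantom a [Phantom-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "Phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLambdaStack(phantom@stack, file.path(dir, "stack.tif"))
  ch <- phantom@channels
  scale <- max(ch@fitc, ch@tritc, 1e-12)
  tiff::writeTIFF(ch@fitc / scale, file.path(dir, "fitc.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(ch@tritc / scale, file.path(dir, "tritc.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  writeMask(phantom@tissueMask, file.path(dir, "tissue_mask.tif"))
  writeMask(phantom@bloodMask, file.path(dir, "blood_mask.tif"))
  jsonlite::write_json(list(seed = phantom@spec@seed,
                            channel_intensity_scale = scale,
                            true_blood_percent = phantom@trueBloodPercent,
                            tissue_area_px = sum(phantom@tissueMask),
                            blood_area_px = sum(phantom@bloodMask)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
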