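# File formats. Image-like objects go to multi-page float32 TIFF with a
# JSON sidecar (`<path>.json`) recording the affine intensity scaling
# (pages are stored rescaled to [0, 1]; float TIFF round trips through the
# tiff package only inside that range), the page order and any metadata /
# config echo. Histograms go to CSV, summaries and truth to JSON, run
# configurations to YAML.

sidecar_path <- function(path) paste0(path, ".json")

write_pages_tiff <- function(pages, path, page_names, meta = list()) {
  stopifnot(is.list(pages), length(pages) == length(page_names))
  vals <- unlist(pages, use.names = FALSE)
  if (all(is.na(vals))) vals <- 0
  lo <- min(vals, na.rm = TRUE)
  hi <- max(vals, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(p) {
    p[is.na(p)] <- lo          # masked pixels encoded via the mask page
    (p - lo) / scale
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    c(list(offset = lo, scale = scale, pages = page_names,
           n_pages = length(pages), height = nrow(pages[[1]]),
           width = ncol(pages[[1]])), meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_pages_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  raw <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(raw, function(p) p * meta$scale + meta$offset)
  names(pages) <- meta$pages
  list(pages = pages, meta = meta)
}

#' Write / read a Mueller image as multi-page TIFF
#'
#' 16 float32 pages in row-major element order m11, m12, ..., m44, plus a
#' JSON sidecar (`<path>.json`) holding the value scaling and metadata.
#'
#' @param img A [mueller_image()].
#' @param path Output TIFF path.
#' @param meta Named list merged into the sidecar (config echo etc.).
#' @return `path`, invisibly (writer); a [mueller_image()] (reader).
#' @export
write_mueller_tiff <- function(img, path, meta = list()) {
  stopifnot(inherits(img, "mueller_image"))
  nm <- as.vector(t(outer(1:4, 1:4, function(i, j) paste0("m", i, j))))
  pages <- list()
  for (i in 1:4) for (j in 1:4)
    pages[[length(pages) + 1L]] <- img[, , i, j]
  write_pages_tiff(pages, path, nm,
                   c(list(kind = "mueller_image",
                          element_order = "m11..m44 row-major"), meta))
}

#' @rdname write_mueller_tiff
#' @export
read_mueller_tiff <- function(path) {
  r <- read_pages_tiff(path)
  stopifnot(identical(r$meta$kind, "mueller_image"), length(r$pages) == 16L)
  H <- nrow(r$pages[[1]]); W <- ncol(r$pages[[1]])
  arr <- array(0, c(H, W, 4L, 4L))
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    arr[, , i, j] <- r$pages[[k]]
  }
  mueller_image(arr)
}

#' Write / read an intensity stack as multi-page TIFF
#'
#' One float32 page per acquisition frame plus the JSON sidecar with the
#' serialized protocol.
#'
#' @param stack An `intensity_stack` from [simulate_stack()].
#' @param path Output TIFF path.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly (writer); an `intensity_stack` (reader).
#' @export
write_stack_tiff <- function(stack, path, meta = list()) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  protocol <- attr(stack, "protocol")
  d <- dim(stack)
  pages <- lapply(seq_len(d[1]), function(k) matrix(stack[k, , ], d[2], d[3]))
  write_pages_tiff(pages, path, sprintf("frame%02d", seq_len(d[1])),
                   c(list(kind = "intensity_stack",
                          protocol = unclass(protocol)), meta))
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  r <- read_pages_tiff(path)
  stopifnot(identical(r$meta$kind, "intensity_stack"))
  n <- length(r$pages)
  H <- nrow(r$pages[[1]]); W <- ncol(r$pages[[1]])
  arr <- array(0, c(n, H, W))
  for (k in seq_len(n)) arr[k, , ] <- r$pages[[k]]
  pr <- r$meta$protocol
  protocol <- acquisition_protocol(pr$n_frames, pr$psg_step, pr$psa_step,
                                   pr$psg_retardance, pr$psa_retardance,
                                   pr$polarizer_axes)
  structure(arr, protocol = protocol,
            class = c("intensity_stack", "array"))
}

#' Write / read parameter maps as multi-page TIFF
#'
#' Seven float32 pages (theta, delta_lr, Delta, alphaP, alphaQ, D, mask)
#' plus the JSON sidecar; angles are stored in degrees. On read, pixels
#' whose mask bit flags a parameter as undefined are restored to `NA`.
#'
#' @param maps A `param_maps` object from [decompose_image()].
#' @param path Output TIFF path.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly (writer); a `param_maps` (reader).
#' @export
write_param_maps_tiff <- function(maps, path, meta = list()) {
  stopifnot(inherits(maps, "param_maps"))
  nm <- c("theta", "delta_lr", "Delta", "alphaP", "alphaQ", "D", "mask")
  pages <- lapply(nm, function(n) {
    p <- maps[[n]]
    storage.mode(p) <- "double"
    p
  })
  write_pages_tiff(pages, path,
                   nm, c(list(kind = "param_maps", angle_unit = "deg"), meta))
}

#' @rdname write_param_maps_tiff
#' @export
read_param_maps_tiff <- function(path) {
  r <- read_pages_tiff(path)
  stopifnot(identical(r$meta$kind, "param_maps"))
  maps <- r$pages
  mask <- matrix(as.integer(round(maps$mask)), nrow(maps$mask), ncol(maps$mask))
  maps$mask <- mask
  maps$theta[bitwAnd(mask, MASK_THETA_UNDEFINED) != 0L] <- NA_real_
  maps$alphaP[bitwAnd(mask, MASK_ALPHAP_FLOOR) != 0L] <- NA_real_
  maps$alphaQ[bitwAnd(mask, MASK_ALPHAQ_FLOOR) != 0L] <- NA_real_
  bad <- bitwAnd(mask, MASK_DECOMP_FAILED) != 0L
  for (n in c("theta", "delta_lr", "Delta", "alphaP", "alphaQ", "D"))
    maps[[n]][bad] <- NA_real_
  structure(maps, class = "param_maps", dim_hw = dim(mask))
}

#' Write / read an axial FDH as CSV
#'
#' Two columns: `bin_center_deg`, `mass`. The bin width and sample count
#' travel in commented header lines.
#'
#' @param fdh An [build_fdh()] histogram.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); an `axial_fdh` (reader).
#' @export
write_fdh_csv <- function(fdh, path) {
  stopifnot(inherits(fdh, "axial_fdh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_deg=%g n_samples=%d",
                     fdh$bin_width, fdh$n_samples), con)
  write.csv(data.frame(bin_center_deg = fdh$bin_centers, mass = fdh$mass),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fdh_csv
#' @export
read_fdh_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("bin_width_deg=([0-9.]+) n_samples=([0-9]+)", hdr))[[1]]
  df <- read.csv(path, comment.char = "#")
  structure(list(bin_width = as.numeric(m[2]),
                 bin_centers = df$bin_center_deg, mass = df$mass,
                 n_samples = as.integer(m[3])),
            class = "axial_fdh")
}

#' Write a bimodal summary (plus provenance) as JSON
#'
#' @param summary A `bimodal_summary` from [classify_peaks()].
#' @param path Output JSON path.
#' @param provenance Named list echoed under `"provenance"` (input files,
#'   bin width, thresholds, seed).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, provenance = list()) {
  stopifnot(inherits(summary, "bimodal_summary"))
  jsonlite::write_json(c(unclass(summary), list(provenance = provenance)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

truth_to_json <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  tr <- unclass(truth)
  tr$layers <- lapply(tr$layers, unclass)
  tr$regions <- NULL  # bulky; regions are reproducible from config + seed
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
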