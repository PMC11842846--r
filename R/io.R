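#' Write a labeled monolayer to TIFF files
#'
#' Writes `cell_labels.tif`, `nucleus_labels.tif` and one 16-bit TIFF per
#' intensity channel into `dir`, plus a `monolayer.json` sidecar holding
#' the pixel size, the channel names, and the generator parameters and
#' seed when present.
#'
#' @param monolayer A `labeled_monolayer`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @seealso [read_monolayer()]
#' @export
write_monolayer <- function(monolayer, dir) {
  check_monolayer(monolayer)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write16 <- function(m, path) {
    if (max(m) > 65535) abort("image values exceed the 16-bit range.")
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  }
  write16(monolayer$cell_labels, file.path(dir, "cell_labels.tif"))
  write16(monolayer$nucleus_labels, file.path(dir, "nucleus_labels.tif"))
  for (ch in names(monolayer$channels)) {
    write16(round(monolayer$channels[[ch]]),
            file.path(dir, paste0(ch, ".tif")))
  }
  par <- monolayer$params
  sidecar <- list(
    pixel_size = monolayer$pixel_size,
    channels = names(monolayer$channels),
    n_clipped = monolayer$n_clipped %||% 0L
  )
  if (!is.null(par)) {
    par_list <- unclass(par)
    par_list$channels <- as.data.frame(par_list$channels)
    sidecar$params <- par_list
    sidecar$seed <- par$seed
  }
  jsonlite::write_json(sidecar, file.path(dir, "monolayer.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labeled monolayer from TIFF files
#'
#' Reads a directory written by [write_monolayer()], or any directory with
#' `cell_labels.tif`, `nucleus_labels.tif` and channel TIFFs sharing the
#' label-id convention (integer labels, 0 background).
#'
#' @param dir Directory containing the TIFF files and optional
#'   `monolayer.json` sidecar.
#' @param pixel_size Micrometres per pixel; overrides the sidecar value.
#' @return A `labeled_monolayer`.
#' @export
read_monolayer <- function(dir, pixel_size = NULL) {
  if (!dir.exists(dir)) abort(sprintf("directory `%s` not found.", dir))
  sidecar_path <- file.path(dir, "monolayer.json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    list()
  }
  read16 <- function(path) round(tiff::readTIFF(path) * 65535)
  cell <- read16(file.path(dir, "cell_labels.tif"))
  nuc <- read16(file.path(dir, "nucleus_labels.tif"))
  storage.mode(cell) <- "integer"
  storage.mode(nuc) <- "integer"
  ch_names <- sidecar$channels %||% {
    tifs <- list.files(dir, pattern = "\\.tif$")
    setdiff(sub("\\.tif$", "", tifs), c("cell_labels", "nucleus_labels"))
  }
  channels <- lapply(ch_names, function(ch) {
    read16(file.path(dir, paste0(ch, ".tif")))
  })
  names(channels) <- ch_names
  structure(
    list(
      cell_labels = cell,
      nucleus_labels = nuc,
      channels = channels,
      pixel_size = pixel_size %||% sidecar$pixel_size %||% 1,
      params = NULL,
      n_clipped = sidecar$n_clipped %||% 0L,
      ground_truth = NULL
    ),
    class = "labeled_monolayer"
  )
}
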