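#' Write a FieldImage as multi-page 16-bit TIFF
#'
#' One page per channel, in channel order; intensities are rounded and
#' clipped to 0..65535. Ground truth, when present, is written alongside as
#' \code{<stem>_cells.csv} / \code{<stem>_puncta.csv}.
#'
#' @param field a \code{\linkS4class{FieldImage}}
#' @param path output .tif path
#' @param writeTruth also write ground-truth CSVs (default TRUE)
#' @return invisibly, the path
#' @export
writeField <- function(field, path, writeTruth = TRUE) {
  stopifnot(is(field, "FieldImage"))
  pages <- lapply(field@channels, function(ch)
    pmin(pmax(round(ch), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (writeTruth && length(field@truth)) {
    stem <- sub("\\.tiff?$", "", path)
    if (!is.null(field@truth$cells))
      utils::write.csv(field@truth$cells, paste0(stem, "_cells.csv"),
                       row.names = FALSE)
    if (!is.null(field@truth$puncta))
      utils::write.csv(field@truth$puncta, paste0(stem, "_puncta.csv"),
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a multi-page TIFF as a FieldImage
#'
#' @param path .tif path
#' @param channelNames names for the pages, recycled from
#'   c("stain", "dsdna", "gfp", "dye") when NULL
#' @param pixelSizeUm micrometres per pixel
#' @return a \code{\linkS4class{FieldImage}} with intensities on the
#'   0..65535 scale
#' @export
readField <- function(path, channelNames = NULL, pixelSizeUm = 1.24) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * 65535
  })
  if (is.null(channelNames))
    channelNames <- c("stain", "dsdna", "gfp", "dye")[seq_along(pages)]
  names(pages) <- channelNames
  new("FieldImage", channels = pages, pixelSize = pixelSizeUm,
      bitDepth = 16, truth = list(), metadata = list(path = path))
}

#' Write / read an integer label map as 16-bit TIFF
#' @param label integer label matrix (values up to 65535)
#' @param path .tif path
#' @return invisibly the path / the label matrix
#' @export
writeLabelMap <- function(label, path) {
  stopifnot(max(label) <= 65535)
  tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Read a droplet amplitude CSV
#'
#' Accepts either the package's own layout (columns ch1, ch2) or a
#' QX200-style amplitude export ("Ch1 Amplitude", "Ch2 Amplitude").
#'
#' @param path CSV path
#' @return data.frame with columns ch1, ch2 (plus any extra columns)
#' @export
readDropletCsv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(d))))
  c1 <- which(nm %in% c("ch1", "ch1amplitude"))[1]
  c2 <- which(nm %in% c("ch2", "ch2amplitude"))[1]
  if (is.na(c1) || is.na(c2))
    stop("no ch1/ch2 (or 'Ch1 Amplitude'/'Ch2 Amplitude') columns in ", path)
  names(d)[c(c1, c2)] <- c("ch1", "ch2")
  d
}

#' Write / read pipeline or generator configuration as YAML
#'
#' @param config a named list (e.g. a SynthFieldConfig or pipeline params)
#' @param path .yml path
#' @return invisibly the path / the configuration list
#' @export
writeConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(v) {
    if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) unname(v[i, ]))
    else if (!is.null(names(v))) as.list(v)
    else v
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(v) {
    if (is.list(v) && length(v)) {
      len <- vapply(v, length, integer(1))
      if (is.null(names(v)) && all(len > 1) && length(unique(len)) == 1)
        do.call(rbind, v)                       # matrix rows
      else if (all(len == 1) && !is.null(names(v)))
        unlist(v)                               # named vector
      else v
    } else v
  })
}
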