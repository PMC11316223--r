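#' Read a multi-channel TIFF into an image set
#'
#' Reads a single- or multi-page (grayscale pages) TIFF and splits the pages
#' into channels according to `channel_map`. Multi-plane z-stacks are not
#' interpreted here; pass each plane as its own page and reduce with
#' [max_project()] if needed.
#'
#' @param path path to a TIFF / OME-TIFF file.
#' @param channel_map named integer vector mapping channel roles to 1-based
#'   page indices, e.g. `c(nuclei = 1, actin = 2, fa = 3)`. Must cover the
#'   roles `nuclei`, `actin` and `fa`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param condition,day,replicate metadata stored on the returned set.
#' @return An [image_set].
#' @export
read_image_set <- function(path, channel_map, pixel_size,
                           condition = "unspecified", day = NA_integer_,
                           replicate = "r1") {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("nuclei", "actin", "fa")
  miss <- setdiff(required, names(channel_map))
  if (length(miss))
    stop("channel_map missing required role(s): ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  channels <- list()
  for (role in names(channel_map)) {
    idx <- channel_map[[role]]
    if (idx < 1L || idx > length(pages))
      stop("channel index ", idx, " for role '", role, "' out of range (",
           length(pages), " page(s))")
    px <- pages[[idx]]
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # drop degenerate colour axis
    channels[[role]] <- channel_image(px, pixel_size = pixel_size, role = role)
  }
  image_set(channels, condition = condition, day = day, replicate = replicate)
}

#' Write an image set as a multi-page grayscale TIFF
#'
#' Pages are written in the order of `set$channels`; intensities are clipped
#' to `[0, 1]` and stored as 16-bit samples, so data on the 1/65535 grid
#' (any 8/16-bit source) round-trips bit-exactly.
#'
#' @param set an [image_set].
#' @param path output file path.
#' @return `path`, invisibly. The page order is returned in attribute
#'   `"channel_order"`.
#' @export
write_image_set <- function(set, path) {
  stopifnot(inherits(set, "image_set"))
  pages <- lapply(set$channels, function(ch) {
    px <- ch$pixels
    px[px < 0] <- 0
    px[px > 1] <- 1
    px
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L)
  structure(invisible(path), channel_order = names(set$channels))
}

#' Write a result table as CSV
#'
#' All pipeline tables are written as plain CSV with a stable column order
#' and full numeric precision (15 significant digits), so files are diffable
#' and read back value-exact.
#'
#' @param table a data.frame (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- out[[nm]]
      # %.17g round-trips IEEE doubles exactly through read.csv
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[nm]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV path.
#' @return data.frame with strings kept as character.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
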