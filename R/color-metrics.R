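#' Foreground mask of a root photograph
#'
#' A pixel is background iff all three channels are at least
#' `white_threshold` (near-white board test); everything else is foreground.
#'
#' @param image a `pixel_image` (see [generate_carrot_image()] or
#'   [read_image_png()]).
#' @param white_threshold intensity in [0, 255] (default 250).
#' @return logical matrix marking foreground, with attribute `empty` set
#'   TRUE when no foreground pixel was found.
#' @export
foreground_mask <- function(image, white_threshold = 250) {
  if (white_threshold < 0 || white_threshold > 255)
    stop("white_threshold outside [0, 255]")
  mask <- !(image$R >= white_threshold & image$G >= white_threshold &
              image$B >= white_threshold)
  attr(mask, "empty") <- !any(mask)
  mask
}

#' RGB intensity fractions over the foreground
#'
#' The default pixel index: each channel's fraction is its intensity sum
#' over foreground pixels divided by the total intensity of all three
#' channels there, so the three fractions sum to 1. The alternative
#' `mode = "dominant"` counts, per foreground pixel, which channel is
#' strictly largest and reports classification fractions (ties split
#' equally).
#'
#' @param image a `pixel_image`.
#' @param mask logical foreground mask (default: [foreground_mask()]).
#' @param mode `"intensity"` (default) or `"dominant"`.
#' @return object of class `rgb_fractions`: list with `red_fraction`,
#'   `green_fraction`, `blue_fraction`, `foreground_pixel_count`, `mode`.
#' @export
rgb_fractions <- function(image, mask = foreground_mask(image),
                          mode = c("intensity", "dominant")) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("empty foreground mask")
  r <- as.numeric(image$R[mask]); g <- as.numeric(image$G[mask])
  b <- as.numeric(image$B[mask])
  if (mode == "intensity") {
    tot <- sum(r) + sum(g) + sum(b)
    if (tot == 0) stop("all-black foreground: fractions undefined")
    fr <- c(sum(r), sum(g), sum(b)) / tot
  } else {
    mx <- pmax(r, g, b)
    w <- cbind(r == mx, g == mx, b == mx)
    w <- w / rowSums(w)
    fr <- colMeans(w)
  }
  structure(list(red_fraction = fr[1], green_fraction = fr[2],
                 blue_fraction = fr[3], foreground_pixel_count = sum(mask),
                 mode = mode),
            class = "rgb_fractions")
}

#' @export
print.rgb_fractions <- function(x, ...) {
  cat(sprintf("RGB fractions (%s): R %.4f, G %.4f, B %.4f over %d px\n",
              x$mode, x$red_fraction, x$green_fraction, x$blue_fraction,
              x$foreground_pixel_count))
  invisible(x)
}

#' Per-image RGB fractions for a set of images, as a screening dataset
#'
#' Computes [rgb_fractions()] for every image and assembles an
#' [omics_dataset()] of the three fractions, ready for [screen_dataset()].
#'
#' @param images list of `pixel_image`s.
#' @param group 0/1 label per image.
#' @param white_threshold passed to [foreground_mask()].
#' @param mode passed to [rgb_fractions()].
#' @return an `omics_dataset` with features red/green/blue_fraction.
#' @export
color_screen_dataset <- function(images, group, white_threshold = 250,
                                 mode = "intensity") {
  fr <- t(vapply(images, function(im) {
    f <- rgb_fractions(im, foreground_mask(im, white_threshold), mode = mode)
    c(red_fraction = f$red_fraction, green_fraction = f$green_fraction,
      blue_fraction = f$blue_fraction)
  }, numeric(3)))
  omics_dataset(fr, sample_ids = sprintf("img%02d", seq_along(images)),
                group = group, compartment = "root", category = "color")
}

#' Read/write `pixel_image` objects as PNG
#'
#' Thin wrappers over the `png` package; intensities are stored 0-255.
#' @param image a `pixel_image`.
#' @param path PNG file path.
#' @export
write_image_png <- function(image, path) {
  arr <- array(0, dim = c(nrow(image$R), ncol(image$R), 3))
  arr[, , 1] <- image$R / 255
  arr[, , 2] <- image$G / 255
  arr[, , 3] <- image$B / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  structure(list(R = matrix(as.integer(round(arr[, , 1] * 255)), nrow(arr)),
                 G = matrix(as.integer(round(arr[, , 2] * 255)), nrow(arr)),
                 B = matrix(as.integer(round(arr[, , 3] * 255)), nrow(arr)),
                 background = 255L),
            class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat("pixel_image:", nrow(x$R), "x", ncol(x$R), "px\n")
  invisible(x)
}
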