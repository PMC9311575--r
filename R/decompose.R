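#' Decompose an H&E image into nuclei and non-nuclei parts
#'
#' Hematoxylin stains nuclei purple-blue and eosin stains cytoplasm and
#' extracellular matrix pink-red, so a nuclei segmentation mask splits a
#' patch into two medically meaningful components. Given the original image
#' `I_main` and a binary mask `M`, the nuclei-only image is the elementwise
#' product `I_down = M * I_main` (broadcast over the three channels) and the
#' non-nuclei image is the remainder `I_top = I_main - I_down`. With 8-bit
#' integer intensities the decomposition is exact: `down + top == main`
#' pixel for pixel.
#'
#' @param image `H x W x 3` numeric array (8-bit `[0, 255]` or `[0, 1]`).
#' @param mask `H x W` binary matrix; must match the image spatially.
#' @return a `decomposed_triplet`: list with components `main`, `down`
#'   (nuclei only) and `top` (non-nuclei only), all the same shape as
#'   `image`.
#' @examples
#' img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
#' msk <- matrix(rbinom(64, 1, 0.3), 8, 8)
#' tri <- decompose_image(img, msk)
#' stopifnot(all(tri$down + tri$top == tri$main))
#' @export
decompose_image <- function(image, mask) {
  check_rgb_image(image)
  check_mask(mask, image)
  down <- image * as.vector(mask) # recycles over channels
  top <- image - down
  structure(list(main = image, down = down, top = top),
            class = "decomposed_triplet")
}

#' Tiling geometry for high-resolution images
#'
#' @param target_height,target_width size in pixels the image is resized to
#'   before tiling; both must be exact multiples of `patch_size`.
#' @param patch_size square patch edge in pixels (default 512, the
#'   conventional patch size for H&E classification).
#' @return a `tiling_spec` list.
#' @export
tiling_spec <- function(target_height, target_width, patch_size = 512L) {
  if (patch_size < 1L || target_height < 1L || target_width < 1L)
    stop("tiling dimensions must be positive", call. = FALSE)
  if (target_height %% patch_size != 0L || target_width %% patch_size != 0L)
    stop("target dimensions must be exact integer multiples of patch_size",
         call. = FALSE)
  structure(list(target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 patch_size = as.integer(patch_size)),
            class = "tiling_spec")
}

#' Number of patches a tiling specification produces
#'
#' @param spec a [tiling_spec()].
#' @return `(target_height / patch_size) * (target_width / patch_size)`.
#' @export
n_patches <- function(spec) {
  stopifnot(inherits(spec, "tiling_spec"))
  as.integer((spec$target_height %/% spec$patch_size) *
               (spec$target_width %/% spec$patch_size))
}

#' Resize an image so it tiles exactly
#'
#' High-resolution slides rarely measure an exact multiple of the patch
#' size, so they are first resampled to the nearest tiling-friendly
#' geometry (for example 4548 x 7548 slides resized to 4608 x 7680, which
#' tile into 135 patches of 512 x 512). Images are interpolated bilinearly;
#' use `resize_mask()` for masks, which must stay binary.
#'
#' @param image `H x W x 3` array.
#' @param spec a [tiling_spec()].
#' @return image of exactly `spec$target_height x spec$target_width x 3`.
#' @export
resize_for_tiling <- function(image, spec) {
  check_rgb_image(image)
  stopifnot(inherits(spec, "tiling_spec"))
  if (dim(image)[1] == spec$target_height && dim(image)[2] == spec$target_width)
    return(image)
  # EBImage indexes dim 1 as `w`; our arrays are height-first, so map
  # height -> w and width -> h.
  out <- EBImage::resize(image, w = spec$target_height, h = spec$target_width,
                         filter = "bilinear")
  array(as.numeric(out), dim = c(spec$target_height, spec$target_width, 3L))
}

#' Resize a binary mask with nearest-neighbour sampling
#'
#' @param mask `H x W` binary matrix.
#' @param target_height,target_width output size in pixels.
#' @return binary matrix of the requested size.
#' @export
resize_mask <- function(mask, target_height, target_width) {
  check_mask(mask)
  out <- EBImage::resize(mask, w = target_height, h = target_width,
                         filter = "none")
  m <- matrix(as.numeric(out), target_height, target_width)
  check_mask(m)
  m
}

#' Cut an image into non-overlapping square patches
#'
#' Patches are emitted in raster (row-major) order with 0-based `(row, col)`
#' grid indices; patch `(r, c)` covers pixel rows `r * p + 1 .. (r + 1) * p`.
#' Stitching the patches back together ([stitch_tiles()]) reproduces the
#' input exactly.
#'
#' @param image `H x W x 3` array whose dimensions are exact multiples of
#'   `patch_size` (use [resize_for_tiling()] first otherwise).
#' @param patch_size square patch edge in pixels.
#' @return list of `list(patch, row, col)` of length `(H/p) * (W/p)`.
#' @export
tile_image <- function(image, patch_size = 512L) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]; p <- as.integer(patch_size)
  if (h %% p != 0L || w %% p != 0L)
    stop("image dimensions must be exact multiples of patch_size; ",
         "resize with resize_for_tiling() first", call. = FALSE)
  nr <- h %/% p; nc <- w %/% p
  out <- vector("list", nr * nc)
  i <- 1L
  for (r in seq_len(nr) - 1L) {
    for (cc in seq_len(nc) - 1L) {
      out[[i]] <- list(
        patch = image[r * p + seq_len(p), cc * p + seq_len(p), , drop = FALSE],
        row = r, col = cc
      )
      i <- i + 1L
    }
  }
  out
}

#' Reassemble tiled patches into one image
#'
#' @param tiles list produced by [tile_image()].
#' @return the reassembled `H x W x 3` array.
#' @export
stitch_tiles <- function(tiles) {
  stopifnot(length(tiles) > 0)
  p <- dim(tiles[[1]]$patch)[1]
  nr <- max(vapply(tiles, function(t) t$row, integer(1))) + 1L
  nc <- max(vapply(tiles, function(t) t$col, integer(1))) + 1L
  img <- array(0, dim = c(nr * p, nc * p, 3L))
  for (t in tiles)
    img[t$row * p + seq_len(p), t$col * p + seq_len(p), ] <- t$patch
  img
}

#' Photometric and geometric augmentation of a patch
#'
#' Implements the augmentation family used to balance class frequencies:
#' `zoom`, `flip`, `constant` (intensity shift), `brightness`, `contrast`
#' and `crop`. Any parameter left unspecified is drawn reproducibly from
#' `seed`, so an augmentation call is a pure function of
#' `(image, op, params, seed)`.
#'
#' Operations and their parameters:
#' \describe{
#'   \item{zoom}{`factor` (> 1 zooms in: resize then centre-crop back to the
#'     input size; < 1 zooms out: shrink and pad with `fill`).}
#'   \item{flip}{`direction`: `"horizontal"` (mirror columns) or
#'     `"vertical"` (mirror rows).}
#'   \item{constant}{`shift`: value added to every channel, clipped to the
#'     intensity range.}
#'   \item{brightness}{`delta`: additive brightness change, clipped.}
#'   \item{contrast}{`factor`: intensities rescaled about the image mean,
#'     `x -> mean + factor * (x - mean)`, clipped.}
#'   \item{crop}{`row`, `col`, `height`, `width` (1-based top-left corner);
#'     returns the window itself.}
#' }
#'
#' @param image `H x W x 3` array.
#' @param op one of `"zoom"`, `"flip"`, `"constant"`, `"brightness"`,
#'   `"contrast"`, `"crop"`.
#' @param params named list of operation parameters (see Details).
#' @param seed integer seed used for any unspecified random parameter.
#' @return augmented image.
#' @export
augment_image <- function(image, op, params = list(), seed = 1L) {
  check_rgb_image(image)
  ops <- c("zoom", "flip", "constant", "brightness", "contrast", "crop")
  if (!op %in% ops)
    stop("unknown augmentation op: ", op, call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  hi <- if (max(image) > 1) 255 else 1 # intensity ceiling for clipping
  clip <- function(x) pmin(pmax(x, 0), hi)
  # local, restartable RNG so augmentation never disturbs the caller's stream
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    list(
      unif = stats::runif(4),
      int = sample.int(2L, 1L)
    )
  })

  switch(op,
    flip = {
      direction <- params$direction %||% c("horizontal", "vertical")[rng$int]
      if (direction == "horizontal") image[, w:1, , drop = FALSE]
      else image[h:1, , , drop = FALSE]
    },
    zoom = {
      factor <- params$factor %||% (1 + 0.2 * rng$unif[1])
      fill <- params$fill %||% hi
      if (abs(factor - 1) < 1e-12) return(image)
      nh <- max(1L, round(h * factor)); nw <- max(1L, round(w * factor))
      big <- EBImage::resize(image, w = nh, h = nw, filter = "bilinear")
      big <- array(as.numeric(big), dim = c(nh, nw, 3L))
      out <- array(fill, dim = c(h, w, 3L))
      if (factor >= 1) {
        r0 <- (nh - h) %/% 2; c0 <- (nw - w) %/% 2
        out <- big[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
      } else {
        r0 <- (h - nh) %/% 2; c0 <- (w - nw) %/% 2
        out[r0 + seq_len(nh), c0 + seq_len(nw), ] <- big
      }
      clip(out)
    },
    constant = clip(image + (params$shift %||% (hi * 0.1 * (2 * rng$unif[1] - 1)))),
    brightness = clip(image + (params$delta %||% (hi * 0.2 * (2 * rng$unif[1] - 1)))),
    contrast = {
      factor <- params$factor %||% (0.5 + rng$unif[1])
      m <- mean(image)
      clip(m + factor * (image - m))
    },
    crop = {
      ch <- params$height %||% (h %/% 2)
      cw <- params$width %||% (w %/% 2)
      r0 <- params$row %||% (1L + floor(rng$unif[1] * (h - ch + 1)))
      c0 <- params$col %||% (1L + floor(rng$unif[2] * (w - cw + 1)))
      if (r0 < 1 || c0 < 1 || r0 + ch - 1 > h || c0 + cw - 1 > w)
        stop("crop window out of bounds", call. = FALSE)
      image[r0 + seq_len(ch) - 1L, c0 + seq_len(cw) - 1L, , drop = FALSE]
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
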