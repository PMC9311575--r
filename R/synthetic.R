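#' Specification of a synthetic H&E classification task
#'
#' Describes a family of synthetic hematoxylin-and-eosin-like patches:
#' purple-blue elliptical nuclei scattered without overlap on a pink
#' textured background, together with the exact binary mask of the rendered
#' nuclei. The class signal is carried either by nuclei morphology (the
#' per-class ellipse semi-axis ranges differ), by the background texture
#' (the per-class spatial frequency differs), or by both. Whatever does not
#' carry signal is drawn from a distribution common to all classes, so e.g.
#' on a `"nuclei"` task the non-nuclei image is class-uninformative by
#' construction.
#'
#' @param num_classes number of classes (default 3).
#' @param image_size square patch edge in pixels (default 64; training
#'   tests use the same size so the suite stays CPU-friendly).
#' @param signal_carrier `"nuclei"`, `"background"` or `"both"`.
#' @param nuclei_count_range integer range of nuclei per patch.
#' @param nuclei_axis_ranges list of length `num_classes`; element `k` is
#'   `c(min, max)` for the ellipse semi-axes (pixels) of class `k`. When the
#'   carrier excludes nuclei every class uses the pooled default range.
#' @param background_frequency numeric vector of length `num_classes`:
#'   background texture frequency in cycles per patch for each class. When
#'   the carrier excludes background every class uses the common default.
#' @param background_amplitude peak amplitude of the sinusoidal background
#'   texture, in 8-bit intensity units.
#' @param color_jitter standard deviation of the per-nucleus /
#'   per-background colour perturbation, in 8-bit intensity units.
#' @return a `synthetic_task_spec` list.
#' @export
synthetic_task_spec <- function(num_classes = 3L,
                                image_size = 64L,
                                signal_carrier = c("nuclei", "background", "both"),
                                nuclei_count_range = c(3L, 6L),
                                nuclei_axis_ranges = NULL,
                                background_frequency = NULL,
                                background_amplitude = 45,
                                color_jitter = 6) {
  signal_carrier <- match.arg(signal_carrier)
  num_classes <- as.integer(num_classes)
  stopifnot(num_classes >= 2L, image_size >= 16L,
            length(nuclei_count_range) == 2L,
            nuclei_count_range[1] >= 1L)

  nuclei_signal <- signal_carrier %in% c("nuclei", "both")
  background_signal <- signal_carrier %in% c("background", "both")

  if (is.null(nuclei_axis_ranges)) {
    nuclei_axis_ranges <- if (nuclei_signal) {
      # ordered size classes (small -> large nuclei) with separated ranges,
      # so class membership is unambiguous from nuclei morphology alone,
      # sized so the largest class still places without overlap on 64 px
      lapply(seq_len(num_classes), function(k) c(2 + 2.5 * (k - 1), 4 + 2.5 * (k - 1)))
    } else {
      rep(list(c(3, 6)), num_classes)
    }
  }
  if (is.null(background_frequency)) {
    background_frequency <- if (background_signal) {
      # widely separated spatial frequencies (2, 8, 14, ... cycles/patch)
      # so texture scale is visually unmistakable between classes
      2 + 6 * (seq_len(num_classes) - 1)
    } else {
      rep(3, num_classes)
    }
  }
  stopifnot(length(nuclei_axis_ranges) == num_classes,
            length(background_frequency) == num_classes)

  structure(list(num_classes = num_classes,
                 image_size = as.integer(image_size),
                 signal_carrier = signal_carrier,
                 nuclei_count_range = as.integer(nuclei_count_range),
                 nuclei_axis_ranges = nuclei_axis_ranges,
                 background_frequency = background_frequency,
                 background_amplitude = background_amplitude,
                 color_jitter = color_jitter),
            class = "synthetic_task_spec")
}

# hematoxylin-ish nuclei and eosin-ish background palettes (8-bit RGB)
.nucleus_rgb <- c(96, 56, 150)
.background_rgb <- c(238, 180, 196)

#' Render one synthetic H&E sample
#'
#' The background is a pink field modulated by a smooth sinusoidal texture
#' at the class's spatial frequency plus seeded pixel noise; nuclei are
#' hard-edged (no anti-aliasing) purple-blue ellipses placed by rejection
#' sampling so they never overlap. The returned mask is exactly the set of
#' rendered nucleus pixels, so `decompose_image(image, mask)$down` is zero
#' everywhere outside the ellipses.
#'
#' @param spec a [synthetic_task_spec()].
#' @param label 1-based class index, `<= spec$num_classes`.
#' @param seed integer seed; the sample is a pure function of
#'   `(spec, label, seed)`.
#' @return list with `image` (`S x S x 3`, 8-bit integers), `mask`
#'   (`S x S` in `{0,1}`) and `label`.
#' @export
generate_sample <- function(spec, label, seed) {
  stopifnot(inherits(spec, "synthetic_task_spec"),
            label >= 1L, label <= spec$num_classes)
  s <- spec$image_size
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # --- background: pink base + class-frequency sinusoidal texture + noise
  f <- spec$background_frequency[label]
  xs <- matrix(seq_len(s), s, s, byrow = TRUE)
  ys <- matrix(seq_len(s), s, s)
  phase <- stats::runif(2, 0, 2 * pi)
  tex <- sin(2 * pi * f * xs / s + phase[1]) * sin(2 * pi * f * ys / s + phase[2])
  noise <- matrix(stats::rnorm(s * s, 0, spec$color_jitter), s, s)
  image <- array(0, dim = c(s, s, 3L))
  for (ch in 1:3)
    image[, , ch] <- .background_rgb[ch] + spec$background_amplitude * tex + noise

  # --- nuclei: rejection-sampled non-overlapping ellipses, exact mask
  cr <- spec$nuclei_count_range
  n_nuc <- if (cr[1] == cr[2]) cr[1] else sample(seq(cr[1], cr[2]), 1L)
  axr <- spec$nuclei_axis_ranges[[label]]
  mask <- matrix(0, s, s)
  placed <- 0L
  tries <- 0L
  while (placed < n_nuc) {
    tries <- tries + 1L
    if (tries > 100L * n_nuc)
      stop("could not place ", n_nuc, " non-overlapping nuclei in ", s, "x", s,
           " pixels; reduce counts or axis sizes", call. = FALSE)
    a <- stats::runif(1, axr[1], axr[2])
    b <- stats::runif(1, axr[1], axr[2])
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 1 + a, s - a)
    cy <- stats::runif(1, 1 + b, s - b)
    # pixel membership of the rotated ellipse
    dx <- ys - cy   # row offset
    dy <- xs - cx   # column offset
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    if (any(mask[inside] == 1)) next # would overlap an earlier nucleus
    mask[inside] <- 1
    jit <- stats::rnorm(3, 0, spec$color_jitter)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[inside] <- .nucleus_rgb[ch] + jit[ch]
      image[, , ch] <- plane
    }
    placed <- placed + 1L
  }

  image <- round(pmin(pmax(image, 0), 255))
  list(image = image, mask = mask, label = as.integer(label))
}

#' Generate a balanced labelled synthetic dataset
#'
#' Produces `n_per_class * num_classes` samples with per-sample seeds
#' derived from `seed`, so the dataset is reproducible and every sample is
#' independently regenerable. The rare draw whose nuclei cannot be placed
#' without overlap is retried under the next derived seed (up to 5 times),
#' which keeps the dataset a pure function of `seed`.
#'
#' @param spec a [synthetic_task_spec()].
#' @param n_per_class samples per class.
#' @param seed master integer seed.
#' @return list of samples as returned by [generate_sample()], in
#'   class-blocked order.
#' @export
generate_dataset <- function(spec, n_per_class, seed = 1L) {
  stopifnot(n_per_class >= 1L)
  out <- vector("list", n_per_class * spec$num_classes)
  i <- 1L
  for (label in seq_len(spec$num_classes)) {
    for (j in seq_len(n_per_class)) {
      # distinct, reproducible per-sample seed; stays within 32-bit range
      sseed <- (as.integer(seed) + 7919L * (i - 1L)) %% .Machine$integer.max
      for (attempt in 0:4) {
        out[[i]] <- tryCatch(
          generate_sample(spec, label, (sseed + attempt * 1000003L) %%
                            .Machine$integer.max),
          error = function(e) if (attempt == 4L) stop(e) else NULL)
        if (!is.null(out[[i]])) break
      }
      i <- i + 1L
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes `sample_%04d.png`, `mask_%04d.png` and a `labels.csv` with columns
#' `filename, mask_filename, label`.
#'
#' @param dataset list of samples from [generate_dataset()].
#' @param dir output directory, created if needed.
#' @return path of the labels CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    fn <- sprintf("sample_%04d.png", i)
    mn <- sprintf("mask_%04d.png", i)
    write_image(dataset[[i]]$image, file.path(dir, fn))
    write_mask(dataset[[i]]$mask, file.path(dir, mn))
    data.frame(filename = fn, mask_filename = mn, label = dataset[[i]]$label)
  })
  csv <- file.path(dir, "labels.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `labels.csv`.
#' @return list of samples with `image`, `mask`, `label`.
#' @export
read_dataset <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "labels.csv"))
  lapply(seq_len(nrow(tab)), function(i) {
    list(image = read_image(file.path(dir, tab$filename[i])),
         mask = read_mask(file.path(dir, tab$mask_filename[i])),
         label = as.integer(tab$label[i]))
  })
}
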