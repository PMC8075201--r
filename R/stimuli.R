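# ---- stimulus sets ----------------------------------------------------------

.STYLES <- c("normal", "italic", "bold")

.new_stimulus_set <- function(condition, images, replication_factor = 1L) {
  meta <- data.frame(
    letter  = vapply(images, `[[`, "", "letter"),
    font_id = vapply(images, `[[`, "", "font_id"),
    style   = vapply(images, `[[`, "", "style"),
    stringsAsFactors = FALSE
  )
  x <- t(vapply(images, `[[`, numeric(900), "vector"))
  structure(
    list(condition = condition, images = images, x = x, meta = meta,
         replication_factor = replication_factor),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %s: %d images (%d unique), %d letters\n",
              x$condition, nrow(x$meta),
              nrow(unique(x$meta)), length(unique(x$meta$letter))))
  invisible(x)
}

#' Assemble a training stimulus set
#'
#' Builds the high-entropy (`"TC-HE"`) or low-entropy (`"TC-LE"`) training
#' set. TC-HE crosses the 9 high-entropy fonts with the three styles,
#' giving 27 versions of each of the 26 letters (702 images). TC-LE uses
#' the 2 low-entropy fonts in the normal style only (52 unique images);
#' those 52 are then replicated cyclically, in fixed order, until the set
#' size matches TC-HE's 702, so both conditions provide the same number of
#' learning trials.
#'
#' @param condition `"TC-HE"` or `"TC-LE"`.
#' @param registry Font registry; see [font_registry()].
#' @param replicate_le Replicate TC-LE to the TC-HE size (default `TRUE`);
#'   set `FALSE` to obtain the 52 unique images.
#' @return A `stimulus_set`: images (list and row-wise `x` matrix of
#'   length-900 vectors), metadata and the replication factor used.
#' @examples
#' nrow(build_training_set("TC-HE")$x)   # 702
#' @export
build_training_set <- function(condition = c("TC-HE", "TC-LE"),
                               registry = font_registry(),
                               replicate_le = TRUE) {
  condition <- match.arg(condition)
  he_fonts <- registry$font_id[registry$role == "train_he"]
  le_fonts <- registry$font_id[registry$role == "train_le"]
  if (length(he_fonts) < 9L || length(le_fonts) < 2L) {
    stop("registry must provide at least 9 high-entropy and 2 low-entropy ",
         "training fonts")
  }
  if (any(registry$font_id[registry$role == "test"] %in% c(he_fonts, le_fonts))) {
    stop("test fonts must be disjoint from training fonts")
  }

  if (condition == "TC-HE") {
    grid <- expand.grid(style = .STYLES, font = he_fonts, letter = LETTERS,
                        stringsAsFactors = FALSE)
    imgs <- Map(function(l, f, s) render_glyph(l, f, s, registry),
                grid$letter, grid$font, grid$style)
    .new_stimulus_set("TC-HE", unname(imgs))
  } else {
    grid <- expand.grid(font = le_fonts, letter = LETTERS,
                        stringsAsFactors = FALSE)
    imgs <- unname(Map(function(l, f) render_glyph(l, f, "normal", registry),
                       grid$letter, grid$font))
    n_unique <- length(imgs)                       # 52
    if (!replicate_le) return(.new_stimulus_set("TC-LE", imgs, 1L))
    target <- 27L * 26L                            # match the TC-HE size
    idx <- rep_len(seq_len(n_unique), target)      # cyclic fill
    .new_stimulus_set("TC-LE", imgs[idx],
                      replication_factor = as.integer(ceiling(target / n_unique)))
  }
}

#' Assemble the held-out test set
#'
#' 26 letters times 4 held-out fonts times 3 styles = 312 images, each
#' reduced in contrast by halving every pixel's luminosity to make
#' recognition more challenging; test fonts never occur in either training
#' condition.
#'
#' @inheritParams build_training_set
#' @param contrast_factor Divisor applied to every pixel (default 2).
#' @return A `stimulus_set` with condition `"TEST"`.
#' @export
build_test_set <- function(registry = font_registry(), contrast_factor = 2) {
  test_fonts <- registry$font_id[registry$role == "test"]
  if (length(test_fonts) < 4L) stop("registry must provide 4 test fonts")
  train_fonts <- registry$font_id[registry$role != "test"]
  if (any(test_fonts %in% train_fonts)) {
    stop("test fonts overlap the training registry: ",
         paste(intersect(test_fonts, train_fonts), collapse = ", "))
  }
  grid <- expand.grid(style = .STYLES, font = test_fonts, letter = LETTERS,
                      stringsAsFactors = FALSE)
  imgs <- Map(function(l, f, s) {
    reduce_contrast(render_glyph(l, f, s, registry), contrast_factor)
  }, grid$letter, grid$font, grid$style)
  .new_stimulus_set("TEST", unname(imgs))
}

#' Reduce the contrast of a stimulus image
#'
#' Divides every pixel luminosity by `factor`, preserving the image
#' metadata. `factor = 2` is the transformation applied to the test set.
#'
#' @param image A `stimulus_image`.
#' @param factor Positive divisor.
#' @return The transformed `stimulus_image`.
#' @export
reduce_contrast <- function(image, factor = 2) {
  stopifnot(inherits(image, "stimulus_image"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("factor must be a positive number")
  }
  image$pixels <- image$pixels / factor
  image$vector <- image$vector / factor
  image
}

# ---- input-side measures ----------------------------------------------------

#' Count the active pixels of a stimulus
#'
#' A pixel is "active" when its luminosity exceeds `threshold`; the
#' mid-gray default discounts the faint anti-aliasing halo around each
#' stroke. This is the per-image statistic used to compare the global
#' amount of information of the two training conditions.
#'
#' @param image A `stimulus_image`.
#' @param threshold Activity threshold on luminosity (default 0.5).
#' @return Integer count in 0..900.
#' @export
active_pixel_count <- function(image, threshold = 0.5) {
  stopifnot(inherits(image, "stimulus_image"))
  sum(image$pixels > threshold)
}

#' Perimetric complexity of a glyph
#'
#' Binarizes the image at `threshold` and returns the ratio between the
#' glyph's surface and its perimeter: ink area (number of active pixels)
#' divided by ink perimeter (number of pixel edges exposed to background
#' under 4-connectivity, image border included). The conventional Pelli
#' form, perimeter squared over area, is available with `pelli = TRUE`.
#'
#' @param image A `stimulus_image`.
#' @param threshold Binarization threshold (default 0.5).
#' @param pelli If `TRUE` return perimeter^2 / area instead of the default
#'   area / perimeter.
#' @return A positive scalar; a single active pixel gives 1/4 = 0.25 under
#'   the default definition.
#' @export
perimetric_complexity <- function(image, threshold = 0.5, pelli = FALSE) {
  stopifnot(inherits(image, "stimulus_image"))
  b <- image$pixels > threshold
  area <- sum(b)
  if (area == 0L) stop("binarized glyph is empty; cannot compute complexity")
  pad <- matrix(FALSE, nrow(b) + 2L, ncol(b) + 2L)
  pad[2:(nrow(b) + 1L), 2:(ncol(b) + 1L)] <- b
  core <- pad[2:(nrow(b) + 1L), 2:(ncol(b) + 1L)]
  # exposed edges: active cell faces a non-active 4-neighbour
  perim <- sum(core & !pad[1:nrow(b), 2:(ncol(b) + 1L)]) +
           sum(core & !pad[3:(nrow(b) + 2L), 2:(ncol(b) + 1L)]) +
           sum(core & !pad[2:(nrow(b) + 1L), 1:ncol(b)]) +
           sum(core & !pad[2:(nrow(b) + 1L), 3:(ncol(b) + 2L)])
  if (pelli) perim^2 / area else area / perim
}

#' Pixel-space entropy profile of a stimulus set
#'
#' Estimates the entropy of a stimulus set as the dimensionality of its
#' pixel distribution: a principal component analysis of the raw
#' length-900 pixel vectors (covariance scale; pixels share a common
#' unit). The more components needed to explain the variance, the higher
#' the entropy of the set.
#'
#' @param set A `stimulus_set` with at least 2 images.
#' @return An object of class `entropy_profile`: list with `explained`
#'   (proportion of variance per component) and `cumulative` (its
#'   non-decreasing cumulative sum, ending at 1).
#' @export
entropy_profile <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  x <- set$x
  if (nrow(x) < 2L) stop("need at least 2 images to estimate an entropy profile")
  v <- sum(apply(x, 2, stats::var))
  if (v < 1e-24) {
    warning("all images in the set are identical; degenerate profile")
    return(structure(list(explained = 1, cumulative = 1,
                          condition = set$condition),
                     class = "entropy_profile"))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  explained <- ev / sum(ev)
  structure(list(explained = explained, cumulative = cumsum(explained),
                 condition = set$condition),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  k99 <- components_to_reach(x, 0.99)
  cat(sprintf("<entropy_profile> %s: %d components, %d needed for 99%% variance\n",
              x$condition %||% "?", length(x$explained), k99))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Components needed to reach a cumulative variance level
#'
#' @param profile An `entropy_profile`.
#' @param level Target cumulative proportion of variance (default 0.99).
#' @return The smallest component count whose cumulative explained
#'   variance reaches `level`.
#' @export
components_to_reach <- function(profile, level = 0.99) {
  stopifnot(inherits(profile, "entropy_profile"))
  which(profile$cumulative >= level - 1e-12)[1]
}

#' @export
plot.entropy_profile <- function(x, n = 100, ...) {
  k <- seq_len(min(n, length(x$cumulative)))
  graphics::plot(k, 100 * x$cumulative[k], type = "l", ylim = c(0, 100),
                 xlab = "principal component",
                 ylab = "cumulative explained variance (%)", ...)
  invisible(x)
}

# ---- export -----------------------------------------------------------------

#' Export a stimulus set to PNG images and a manifest CSV
#'
#' Writes one 8-bit grayscale PNG per image, named
#' `<letter>_<font>_<style>.png` (an index prefix keeps replicated TC-LE
#' items distinct), plus `manifest.csv` with letter, font, style and
#' condition. Requires the `png` package.
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
export_stimuli <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- set$meta
  m$condition <- set$condition
  m$file <- sprintf("%04d_%s_%s_%s.png", seq_len(nrow(m)),
                    m$letter, m$font_id, m$style)
  for (i in seq_len(nrow(m))) {
    png::writePNG(set$images[[i]]$pixels, file.path(dir, m$file[i]))
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
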