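# ---- procedural letterforms -------------------------------------------------
#
# Every capital letter is a set of polyline strokes in an abstract em box:
# x in [0, w], y in [0, 1] with y = 0 at the baseline and y = 1 at cap
# height. "Fonts" are parameter vectors (width, stroke weight, slant,
# serifs, bowl squareness) applied to the same skeletons, which keeps
# rendering fully deterministic and platform independent.

.seg <- function(x1, y1, x2, y2) cbind(c(x1, x2), c(y1, y2))

# superellipse arc from angle a0 to a1 (degrees); e = 2 is an ellipse,
# larger e squares off the bowls
.arc <- function(cx, cy, rx, ry, a0, a1, e = 2, n = 28) {
  t <- seq(a0, a1, length.out = n) * pi / 180
  k <- 2 / e
  cbind(cx + rx * sign(cos(t)) * abs(cos(t))^k,
        cy + ry * sign(sin(t)) * abs(sin(t))^k)
}

# strokes for one letter; `e` is the bowl-superellipse exponent of the font
.letter_strokes <- function(letter, e = 2) {
  A <- function(...) list(...)
  switch(letter,
    "A" = A(cbind(c(0, .4, .8), c(0, 1, 0)), .seg(.14, .35, .66, .35)),
    "B" = A(.seg(0, 0, 0, 1), .arc(0, .76, .45, .24, 90, -90, e),
            .arc(0, .26, .52, .26, 90, -90, e)),
    "C" = A(.arc(.45, .5, .45, .5, 50, 310, e)),
    "D" = A(.seg(0, 0, 0, 1), .arc(0, .5, .58, .5, 90, -90, e)),
    "E" = A(.seg(0, 0, 0, 1), .seg(0, 1, .6, 1), .seg(0, .52, .5, .52),
            .seg(0, 0, .6, 0)),
    "F" = A(.seg(0, 0, 0, 1), .seg(0, 1, .6, 1), .seg(0, .52, .48, .52)),
    "G" = A(.arc(.45, .5, .45, .5, 45, 315, e), .seg(.5, .42, .9, .42),
            .seg(.9, .42, .9, .16)),
    "H" = A(.seg(0, 0, 0, 1), .seg(.7, 0, .7, 1), .seg(0, .5, .7, .5)),
    "I" = A(.seg(0, 0, 0, 1)),
    "J" = A(.seg(.55, 1, .55, .25), .arc(.275, .25, .275, .25, 0, -180, e)),
    "K" = A(.seg(0, 0, 0, 1), .seg(0, .42, .62, 1), .seg(.22, .62, .66, 0)),
    "L" = A(.seg(0, 0, 0, 1), .seg(0, 0, .6, 0)),
    "M" = A(cbind(c(0, 0, .42, .84, .84), c(0, 1, .3, 1, 0))),
    "N" = A(cbind(c(0, 0, .72, .72), c(0, 1, 0, 1))),
    "O" = A(.arc(.42, .5, .42, .5, 0, 360, e, n = 40)),
    "P" = A(.seg(0, 0, 0, 1), .arc(0, .74, .5, .26, 90, -90, e)),
    "Q" = A(.arc(.42, .5, .42, .5, 0, 360, e, n = 40),
            .seg(.5, .28, .82, -.06)),
    "R" = A(.seg(0, 0, 0, 1), .arc(0, .74, .5, .26, 90, -90, e),
            .seg(.14, .48, .66, 0)),
    "S" = A(.arc(.4, .75, .38, .25, 40, 270, e),
            .arc(.4, .25, .38, .25, 90, -140, e)),
    "T" = A(.seg(0, 1, .72, 1), .seg(.36, 0, .36, 1)),
    "U" = A(cbind(c(0, 0), c(1, .3)), .arc(.36, .3, .36, .3, 180, 360, e),
            cbind(c(.72, .72), c(.3, 1))),
    "V" = A(cbind(c(0, .36, .72), c(1, 0, 1))),
    "W" = A(cbind(c(0, .22, .45, .68, .9), c(1, 0, .62, 0, 1))),
    "X" = A(.seg(0, 0, .7, 1), .seg(0, 1, .7, 0)),
    "Y" = A(.seg(0, 1, .36, .48), .seg(.72, 1, .36, .48),
            .seg(.36, .48, .36, 0)),
    "Z" = A(cbind(c(0, .7, 0, .7), c(1, 1, 0, 0))),
    stop("unknown letter: ", letter)
  )
}

# Park-Miller stream for font shape coefficients; exact in doubles and
# independent of R's global RNG
.font_stream <- function(seed, n) {
  s <- as.double(seed %% 2147483647L)
  if (s == 0) s <- 1
  u <- numeric(n)
  for (i in seq_len(n)) {
    s <- (16807 * s) %% 2147483647
    u[i] <- s / 2147483647
  }
  u
}

# each font owns a smooth quadratic warp of the shared skeletons: tapering,
# bowing and a monotone vertical remap (crossbar height), so fonts differ in
# letterform geometry and not only in stroke parameters
.font_warp <- function(shape_seed, amount = 0.55) {
  a <- (2 * .font_stream(shape_seed, 5) - 1) * amount
  function(p) {
    x <- p[, 1]; y <- p[, 2]
    y2 <- y + 1.6 * a[5] * y * (1 - y)              # mid-height shift
    cbind(x * (1 + a[1] * (y2 - 0.5)) + a[2] * (y2 - 0.5)^2,
          y2 * (1 + 0.5 * a[3] * (x - 0.5)) + a[4] * (x - 0.5)^2)
  }
}

# horizontal serif ticks at the ends of near-vertical stroke terminals
.add_serifs <- function(strokes, len = 0.14) {
  out <- strokes
  for (s in strokes) {
    n <- nrow(s)
    for (idx in list(c(1, 2), c(n, n - 1))) {
      p <- s[idx[1], ]; q <- s[idx[2], ]
      d <- q - p
      if (abs(d[2]) > abs(d[1]) * 1.5) {
        out[[length(out) + 1]] <- .seg(p[1] - len / 2, p[2],
                                       p[1] + len / 2, p[2])
      }
    }
  }
  out
}

# ---- font registry ----------------------------------------------------------

#' Procedural font registry
#'
#' The stimulus generator draws letterforms from a fixed registry of 15
#' parameterised procedural fonts: 9 reserved for the high-entropy training
#' condition (`hf1`-`hf9`), 2 for the low-entropy condition (`lf1`, `lf2`)
#' and 4 held out for the test set (`tf1`-`tf4`). Each font is a row of
#' shape parameters applied to shared stroke skeletons, so rendering is
#' deterministic and needs no font files.
#'
#' @return A data frame with one row per font: `font_id`, `role` (one of
#'   `"train_he"`, `"train_le"`, `"test"`), `width` (em-box width scale),
#'   `stroke` (stroke half-width in em units), `slant` (horizontal shear
#'   per unit height), `serif` (logical), `squareness` (superellipse
#'   exponent of the bowls; 2 = elliptical) and `shape_seed` (seed of the
#'   font's deterministic skeleton warp, its typeface identity).
#' @examples
#' font_registry()
#' @export
font_registry <- function() {
  data.frame(
    font_id = c(paste0("hf", 1:9), "lf1", "lf2", paste0("tf", 1:4)),
    role = c(rep("train_he", 9), rep("train_le", 2), rep("test", 4)),
    width      = c(.80, .62, .95, .75, .70, .88, .58, .82, .72,
                   .78, .68, .85, .64, .92, .74),
    stroke     = c(.050, .062, .042, .078, .038, .066, .052, .058, .045,
                   .052, .060, .056, .046, .070, .040),
    slant      = c(0, 0, 0, .06, -.05, .04, .12, 0, -.08,
                   0, .03, .05, -.04, 0, .10),
    serif      = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                   FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    squareness = c(2, 2, 2, 2.6, 2, 3.4, 2, 2.4, 2,
                   2, 2, 2.2, 2, 3, 2),
    shape_seed = c(101L, 211L, 307L, 401L, 503L, 601L, 701L, 809L, 907L,
                   1013L, 1103L, 1201L, 1301L, 1409L, 1511L),
    stringsAsFactors = FALSE
  )
}

.font_params <- function(font_id, registry = font_registry()) {
  i <- match(font_id, registry$font_id)
  if (is.na(i)) {
    stop("unknown font_id '", font_id, "'; known fonts: ",
         paste(registry$font_id, collapse = ", "))
  }
  registry[i, ]
}

# ---- rasterizer -------------------------------------------------------------

.CANVAS <- 30L
.MARGIN <- 2

# min distance from each point in P (m x 2) to segment a-b
.dist_to_seg <- function(px, py, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  l2 <- dx * dx + dy * dy
  if (l2 < 1e-12) {
    sqrt((px - a[1])^2 + (py - a[2])^2)
  } else {
    t <- pmin(1, pmax(0, ((px - a[1]) * dx + (py - a[2]) * dy) / l2))
    sqrt((px - a[1] - t * dx)^2 + (py - a[2] - t * dy)^2)
  }
}

# glyph render cache: rendering is pure, so memoise on (letter, font, style)
.glyph_cache <- new.env(parent = emptyenv())

#' Render one letter glyph to a 30x30 grayscale stimulus
#'
#' Rasterizes a procedural letterform onto the 30-by-30 canvas that feeds
#' the 900-neuron input layer. The glyph is sheared by the font (plus
#' style) slant, scaled to fit the canvas with a 2-pixel margin preserving
#' aspect ratio, centred on its ink bounding box and drawn with a 1-pixel
#' anti-aliasing band, yielding luminosities in [0, 1]. Rendering is a pure
#' function of its arguments: the same call always returns the identical
#' bitmap.
#'
#' @param letter Single uppercase character `"A"`-`"Z"`.
#' @param font_id A font identifier present in `registry`.
#' @param style One of `"normal"`, `"italic"` (extra shear) or `"bold"`
#'   (stroke width times 1.9).
#' @param registry Font registry data frame, by default [font_registry()].
#' @return An object of class `stimulus_image`: a list with `letter`,
#'   `font_id`, `style`, `pixels` (30x30 matrix, row 1 = top) and `vector`
#'   (length-900 row-major flattening).
#' @examples
#' img <- render_glyph("A", "hf1", "bold")
#' range(img$pixels)
#' @export
render_glyph <- function(letter, font_id, style = "normal",
                         registry = font_registry()) {
  stopifnot(is.character(letter), nchar(letter) == 1L)
  if (!letter %in% LETTERS) stop("letter must be one of A-Z, got '", letter, "'")
  style <- match.arg(style, c("normal", "italic", "bold"))
  key <- paste(letter, font_id, style, sep = "|")
  hit <- .glyph_cache[[key]]
  if (!is.null(hit)) return(hit)

  fp <- .font_params(font_id, registry)
  slant <- fp$slant + if (style == "italic") 0.3 else 0
  halfw <- fp$stroke * if (style == "bold") 1.9 else 1

  strokes <- .letter_strokes(letter, e = fp$squareness)
  if (fp$serif) strokes <- .add_serifs(strokes)
  warp <- .font_warp(fp$shape_seed)
  strokes <- lapply(strokes, function(s) {
    s <- warp(s)
    cbind((s[, 1] + slant * s[, 2]) * fp$width, s[, 2])
  })

  pts <- do.call(rbind, strokes)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  w <- hi[1] - lo[1]; h <- hi[2] - lo[2]
  inner <- .CANVAS - 2 * .MARGIN
  sc <- inner / max(w + 2 * halfw, h + 2 * halfw)
  # centre the ink bounding box (stroke extent included) on the canvas
  ox <- .CANVAS / 2 - sc * (lo[1] + hi[1]) / 2
  oy <- .CANVAS / 2 - sc * (lo[2] + hi[2]) / 2
  r_px <- halfw * sc

  gx <- rep(seq_len(.CANVAS) - 0.5, times = .CANVAS)        # x by column
  gy <- rep(seq_len(.CANVAS) - 0.5, each = .CANVAS)         # y from bottom
  dmin <- rep(Inf, .CANVAS * .CANVAS)
  for (s in strokes) {
    sp <- cbind(s[, 1] * sc + ox, s[, 2] * sc + oy)
    for (i in seq_len(nrow(sp) - 1L)) {
      dmin <- pmin(dmin, .dist_to_seg(gx, gy, sp[i, ], sp[i + 1L, ]))
    }
  }
  lum <- pmin(1, pmax(0, r_px + 0.5 - dmin))  # 1-px anti-alias band
  # lum is ordered y-from-bottom rows; flip so matrix row 1 is the top row
  pix <- matrix(lum, nrow = .CANVAS, ncol = .CANVAS, byrow = TRUE)
  pix <- pix[.CANVAS:1, , drop = FALSE]
  if (!any(pix > 0)) stop("glyph '", letter, "' rendered empty for font ", font_id)

  img <- structure(
    list(letter = letter, font_id = font_id, style = style,
         pixels = pix, vector = as.vector(t(pix))),
    class = "stimulus_image"
  )
  assign(key, img, envir = .glyph_cache)
  img
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image> letter %s, font %s, style %s, %d active px\n",
              x$letter, x$font_id, x$style, active_pixel_count(x)))
  invisible(x)
}

#' @export
plot.stimulus_image <- function(x, ...) {
  graphics::image(t(x$pixels[nrow(x$pixels):1, ]),
                  col = grDevices::gray.colors(64, 0, 1),
                  axes = FALSE, asp = 1,
                  main = paste(x$letter, x$font_id, x$style), ...)
  invisible(x)
}
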