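# shared fixtures: all built in code at test time

# a stimulus_image with arbitrary pixel content
make_image <- function(pixels, letter = "A", font_id = "fx",
                       style = "normal") {
  structure(
    list(letter = letter, font_id = font_id, style = style,
         pixels = pixels, vector = as.vector(t(pixels))),
    class = "stimulus_image"
  )
}

blank30 <- function(fill = 0) matrix(fill, 30, 30)

# small training schedules for unit tests (the full 40 x 120 schedule is
# exercised by the acceptance suite)
tiny_train <- function(seed = 1L, epochs = 2L, batches = 5L, ...) {
  train_config(epochs = epochs, batches_per_epoch = batches, seed = seed, ...)
}

tiny_readout <- function(seed = 1L, epochs = 20L) {
  readout_config(epochs = epochs, batches_per_epoch = 10L, seed = seed)
}

# brute-force exposed-edge counter (4-connectivity), independent of the
# implementation in perimetric_complexity()
brute_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) p <- p + 1L
    }
  }
  p
}

# synthetic eigen_spectrum from explained proportions (eigenvalues on the
# correlation scale for a given number of variables)
fake_spectrum <- function(explained, n_vars = length(explained)) {
  structure(
    list(eigenvalues = explained * n_vars, explained = explained,
         n_components = length(explained), n_dropped = 0L,
         letter = NA_character_, network_id = NA_character_),
    class = "eigen_spectrum"
  )
}
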