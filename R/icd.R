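# ---- internal computational dynamics (ICD) ---------------------------------

#' Recorder for hidden-layer-2 activation trajectories
#'
#' Creates a recorder that [train_dbn()] invokes after every layer-2
#' mini-batch update (one learning cycle). At each cycle the recorder
#' presents its probe images and stores the activation of all 800
#' second-layer units; a default 40 x 120 = 4,800-cycle run is condensed
#' online into an 800 x 240 micro-stage matrix per letter (per-neuron
#' sample SD over non-overlapping windows of `window` adjacent cycles)
#' without holding full trajectories in memory.
#'
#' Two recording conventions are controlled by arguments:
#'
#' * `sample_states` (default `FALSE`): record the deterministic
#'   mean-field probabilities of the hidden units. With `TRUE`, one
#'   Bernoulli draw per unit, probe and cycle (from R's random stream)
#'   is recorded instead — the stochastic states the network emits
#'   during learning; the micro-stage SD then mixes learning dynamics
#'   with each unit's Bernoulli variability profile.
#' * `version_collapse`: how a letter's several probe versions collapse
#'   into one matrix. `"mean_sd"` (default) computes the windowed SD for
#'   every version separately and averages the SD matrices, preserving
#'   each unit's variability level; `"mean_activation"` averages the
#'   activations across versions first and takes the SD of that mean
#'   trajectory. The two coincide for single-version probes.
#'
#' @param probe_set A `stimulus_set` supplying probe images; duplicated
#'   (letter, font, style) rows — e.g. low-entropy replication — are
#'   collapsed to unique versions.
#' @param letters Letters to record (default: all letters present).
#' @param window Cycles per micro-stage (default 20).
#' @param keep_cycles Also retain per-letter neuron-by-cycle matrices of
#'   the version-averaged recorded activations.
#' @param sample_states Record mean-field probabilities (default) or
#'   sampled binary states.
#' @param version_collapse `"mean_sd"` (default) or `"mean_activation"`.
#' @param network_id Provenance label stored with the outputs.
#' @return An object of class `icd_recorder` with methods `$record()`
#'   (called by the trainer), `$microstages()` — a named list of
#'   `microstage_matrix` (neurons x micro-stages), `$cycles()` — named
#'   list of `icd_recording` (neurons x cycles, if kept) and
#'   `$n_cycles()`.
#' @export
icd_recorder <- function(probe_set, letters = NULL, window = 20L,
                         keep_cycles = FALSE, sample_states = FALSE,
                         version_collapse = c("mean_sd", "mean_activation"),
                         network_id = "net1") {
  stopifnot(inherits(probe_set, "stimulus_set"), window >= 2L)
  version_collapse <- match.arg(version_collapse)
  keep <- !duplicated(probe_set$meta)
  meta <- probe_set$meta[keep, , drop = FALSE]
  x <- probe_set$x[keep, , drop = FALSE]
  if (is.null(letters)) letters <- sort(unique(meta$letter))
  sel <- meta$letter %in% letters
  meta <- meta[sel, , drop = FALSE]
  x <- x[sel, , drop = FALSE]
  absent <- setdiff(letters, meta$letter)
  if (length(absent)) {
    stop("no probe image for letter(s): ", paste(absent, collapse = ", "))
  }

  # aggregation matrix: per-letter mean over that letter's probe versions
  agg <- outer(letters, meta$letter, `==`) * 1
  agg <- agg / rowSums(agg)
  n_probe <- nrow(x)

  env <- new.env(parent = emptyenv())
  env$window <- as.integer(window)
  env$letters <- letters
  env$network_id <- network_id
  env$probes <- x
  env$buf <- NULL                 # window x probes x units, allocated lazily
  env$n_units <- NA_integer_
  env$pos <- 0L
  env$cycles_seen <- 0L
  env$sd_cols <- list()           # one (letters x units) matrix per window
  env$cyc_cols <- if (keep_cycles) list() else NULL

  flush_window <- function() {
    w <- env$window
    if (version_collapse == "mean_sd") {
      s1 <- rowSums(env$buf, dims = 2)         # probes x units
      s2 <- rowSums(env$buf^2, dims = 2)
      v <- (s2 - s1^2 / w) / (w - 1)
      v[v < 0] <- 0                            # tiny negative roundoff
      env$sd_cols[[length(env$sd_cols) + 1L]] <- agg %*% sqrt(v)
    } else {
      # SD of the per-letter mean trajectory
      m <- vapply(seq_len(w), function(k) agg %*% env$buf[, , k],
                  matrix(0, nrow(agg), env$n_units))
      s1 <- rowSums(m, dims = 2)
      s2 <- rowSums(m^2, dims = 2)
      v <- (s2 - s1^2 / w) / (w - 1)
      v[v < 0] <- 0
      env$sd_cols[[length(env$sd_cols) + 1L]] <- sqrt(v)
    }
    env$pos <- 0L
  }

  env$record <- function(a_versions) {
    if (sample_states) {
      a_versions <- (matrix(stats::runif(length(a_versions)),
                            nrow(a_versions)) < a_versions) * 1
    }
    if (is.null(env$buf)) {
      env$buf <- array(0, dim = c(n_probe, ncol(a_versions), env$window))
      env$n_units <- ncol(a_versions)
    }
    env$pos <- env$pos + 1L
    env$buf[, , env$pos] <- a_versions         # contiguous slab write
    env$cycles_seen <- env$cycles_seen + 1L
    if (!is.null(env$cyc_cols)) {
      env$cyc_cols[[env$cycles_seen]] <- agg %*% a_versions
    }
    if (env$pos == env$window) flush_window()
    invisible(NULL)
  }

  env$n_cycles <- function() env$cycles_seen

  env$microstages <- function() {
    if (env$pos != 0L) {
      warning(env$pos, " trailing cycle(s) did not fill a window and were ",
              "dropped from the micro-stage matrices")
    }
    out <- lapply(seq_along(env$letters), function(i) {
      m <- vapply(env$sd_cols, function(sc) sc[i, ], numeric(env$n_units))
      structure(m, class = c("microstage_matrix", class(m)),
                letter = env$letters[i], network_id = env$network_id,
                window = env$window)
    })
    names(out) <- env$letters
    out
  }

  env$cycles <- function() {
    if (is.null(env$cyc_cols)) stop("recorder was created with keep_cycles = FALSE")
    out <- lapply(seq_along(env$letters), function(i) {
      m <- vapply(env$cyc_cols, function(a) a[i, ], numeric(env$n_units))
      structure(m, class = c("icd_recording", class(m)),
                letter = env$letters[i], network_id = env$network_id)
    })
    names(out) <- env$letters
    out
  }

  class(env) <- "icd_recorder"
  env
}

#' @export
print.icd_recorder <- function(x, ...) {
  cat(sprintf("<icd_recorder> %d letters, window %d, %d cycles recorded\n",
              length(x$letters), x$window, x$cycles_seen))
  invisible(x)
}

#' Condense a neuron-by-cycle recording into micro-stage SDs
#'
#' Splits the cycle axis into consecutive non-overlapping windows of
#' `window` cycles and returns, for every neuron and window, the sample
#' standard deviation (n - 1 denominator) of its activation — the
#' micro-stage score that foregrounds local variation across adjacent
#' learning cycles. A 800 x 4,800 recording with the default window of 20
#' becomes an 800 x 240 micro-stage matrix.
#'
#' @param recording Numeric matrix, neurons x cycles (e.g. an
#'   `icd_recording`).
#' @param window Cycles per micro-stage (default 20); must divide the
#'   cycle count exactly.
#' @return A `microstage_matrix` (neurons x cycles/window), non-negative.
#' @export
microstage_sd <- function(recording, window = 20L) {
  stopifnot(is.matrix(recording), window >= 2L)
  n_cyc <- ncol(recording)
  if (n_cyc %% window != 0L) {
    stop("cycle count (", n_cyc, ") is not divisible by the window (",
         window, ")")
  }
  n_win <- n_cyc %/% window
  out <- matrix(0, nrow(recording), n_win)
  for (w in seq_len(n_win)) {
    sub <- recording[, ((w - 1L) * window + 1L):(w * window), drop = FALSE]
    ctr <- sub - rowMeans(sub)
    out[, w] <- sqrt(rowSums(ctr^2) / (window - 1))
  }
  structure(out, class = c("microstage_matrix", class(out)),
            letter = attr(recording, "letter"),
            network_id = attr(recording, "network_id"),
            window = as.integer(window))
}

#' @export
print.microstage_matrix <- function(x, ...) {
  cat(sprintf("<microstage_matrix> %d neurons x %d micro-stages (letter %s)\n",
              nrow(x), ncol(x), attr(x, "letter") %||% "?"))
  invisible(x)
}
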