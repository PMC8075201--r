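# ---- delta-rule read-out classifier ----------------------------------------

#' Configuration for the read-out classifier
#'
#' @param epochs Maximum training epochs (default 500).
#' @param learning_rate Delta-rule learning rate (default 0.1).
#' @param batches_per_epoch Mini-batches per epoch (default 120, the same
#'   granularity as the unsupervised phase).
#' @param tol Relative plateau tolerance on the training mean squared
#'   error; training stops early when the error improves by less than
#'   `tol` over `patience` consecutive epochs.
#' @param patience Plateau patience in epochs (default 10).
#' @param seed Integer seed for shuffling.
#' @return A list of class `readout_config`.
#' @export
readout_config <- function(epochs = 500L, learning_rate = 0.1,
                           batches_per_epoch = 120L, tol = 1e-5,
                           patience = 10L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batches_per_epoch = as.integer(batches_per_epoch),
                 tol = tol, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "readout_config")
}

#' Train the read-out classifier by the delta rule
#'
#' Stacks a 26-unit logistic output layer on the second hidden layer and
#' trains it with the delta rule — mini-batch gradient descent on the
#' squared error of the logistic outputs against one-of-26 letter targets
#' — on the network's deterministic mean-field layer-2 activations of the
#' same set used during the unsupervised phase. The generative layers are
#' never modified.
#'
#' @param net A fitted [train_dbn()] network, or `NULL` when `set` is
#'   already an activation matrix.
#' @param set A labelled `stimulus_set` (labels are taken from its
#'   metadata), or a numeric activation/input matrix.
#' @param labels Character vector of letters `A`-`Z`, required when `set`
#'   is a bare matrix.
#' @param config A [readout_config()].
#' @return An object of class `delta_readout`: weights (800 x 26), biases,
#'   the per-epoch training error trace and the epochs actually run.
#' @export
train_readout <- function(net, set, labels = NULL,
                          config = readout_config()) {
  if (inherits(set, "stimulus_set")) {
    labels <- set$meta$letter
    h <- predict(net, set, layer = "h2")
  } else {
    stopifnot(is.matrix(set))
    h <- if (!is.null(net) && ncol(set) == nrow(net$layer1$w)) {
      predict(net, set, "h2")
    } else {
      set                                     # already representation-space
    }
  }
  if (is.null(labels) || length(labels) != nrow(h)) {
    stop("labels must be supplied, one per input row")
  }
  if (!all(labels %in% LETTERS)) {
    stop("labels outside A-Z: ",
         paste(unique(setdiff(labels, LETTERS)), collapse = ", "))
  }
  targets <- outer(labels, LETTERS, `==`) * 1      # one-of-26 coding
  n <- nrow(h); k <- ncol(targets)
  set.seed(config$seed)
  w <- matrix(0, ncol(h), k)
  b <- numeric(k)

  n_batches <- min(config$batches_per_epoch, n)
  trace <- numeric(0)
  best <- Inf; stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    batches <- .partition_batches(sample.int(n), n_batches)
    for (idx in batches) {
      hi <- h[idx, , drop = FALSE]
      ti <- targets[idx, , drop = FALSE]
      y <- .sigmoid(sweep(hi %*% w, 2, b, `+`))
      delta <- (y - ti) * y * (1 - y)              # d(mse)/d(net input)
      w <- w - config$learning_rate * crossprod(hi, delta) / nrow(hi)
      b <- b - config$learning_rate * colMeans(delta)
    }
    y_all <- .sigmoid(sweep(h %*% w, 2, b, `+`))
    err <- mean((y_all - targets)^2)
    trace[epoch] <- err
    if (err < best * (1 - config$tol)) {
      best <- err; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(list(w = w, b = b, config = config, trace = trace,
                 epochs_run = length(trace)),
            class = "delta_readout")
}

#' @export
print.delta_readout <- function(x, ...) {
  cat(sprintf("<delta_readout> %d -> %d units, %d epochs, final mse %.5f\n",
              nrow(x$w), ncol(x$w), x$epochs_run,
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Predict letters (or output activations) from a read-out
#'
#' The behavioural response is the letter of the maximally active output
#' unit; ties break deterministically toward the alphabetically first
#' letter.
#'
#' @param object A `delta_readout`.
#' @param h Layer-2 activation matrix (rows = stimuli).
#' @param type `"letter"` (default) or `"activation"`.
#' @param ... Unused.
#' @return Character vector of letters, or the activation matrix.
#' @export
predict.delta_readout <- function(object, h, type = c("letter", "activation"),
                                  ...) {
  type <- match.arg(type)
  y <- .sigmoid(sweep(h %*% object$w, 2, object$b, `+`))
  if (type == "activation") return(y)
  LETTERS[apply(y, 1, which.max)]        # which.max: first (lowest) index ties
}

#' Evaluate classification performance per letter
#'
#' Presents every test stimulus, takes the read-out's argmax response and
#' scores the fraction of correct classifications for each of the 26
#' letters, plus the overall mean over items.
#'
#' @param net A fitted `dbn`.
#' @param classifier A `delta_readout`.
#' @param test_set A `stimulus_set` covering all 26 letters.
#' @param network_id,condition Optional provenance strings stored in the
#'   records.
#' @return A list of class `performance` with `per_letter` (data frame
#'   network_id, condition, letter, accuracy, n_test_items) and `overall`
#'   (mean accuracy over all test items).
#' @export
evaluate_readout <- function(net, classifier, test_set,
                             network_id = "net1", condition = NA_character_) {
  stopifnot(inherits(test_set, "stimulus_set"))
  truth <- test_set$meta$letter
  missing <- setdiff(LETTERS, truth)
  if (length(missing)) {
    stop("test set lacks letters: ", paste(missing, collapse = ", "))
  }
  h <- predict(net, test_set, layer = "h2")
  pred <- predict(classifier, h)
  correct <- pred == truth
  n_items <- as.vector(table(factor(truth, LETTERS)))
  acc <- as.vector(tapply(correct, factor(truth, LETTERS), mean))
  structure(
    list(per_letter = data.frame(network_id = network_id,
                                 condition = condition, letter = LETTERS,
                                 accuracy = acc, n_test_items = n_items,
                                 stringsAsFactors = FALSE),
         overall = mean(correct)),
    class = "performance"
  )
}

#' @export
print.performance <- function(x, ...) {
  cat(sprintf("<performance> overall accuracy %.3f over %d items\n",
              x$overall, sum(x$per_letter$n_test_items)))
  invisible(x)
}
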