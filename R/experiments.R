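# ---- study orchestration ----------------------------------------------------

#' Configuration of a simulation study
#'
#' Bundles the design of a full experiment. Study 1 trains one network
#' per training condition and analyses the internal dynamics of all 26
#' letters; Study 2 trains `replicas_per_condition` networks per
#' condition (20 by default) and, to keep the computation tractable,
#' records the dynamics of one sampled probe image for each of the
#' letters A and M only.
#'
#' Every random stage derives deterministically from `master_seed`:
#' network i (numbered across conditions) trains with seed
#' `master_seed + i`, its read-out with `master_seed + i + 1000`, and
#' Study 2's probe-image sampling uses `master_seed` itself.
#'
#' @param study 1 or 2.
#' @param master_seed Integer master seed.
#' @param replicas_per_condition Networks per training condition
#'   (forced to 1 for Study 1; default 20 for Study 2).
#' @param letters Letters whose dynamics are recorded (Study 1: all;
#'   Study 2: `c("A", "M")`).
#' @param train A [train_config()] template (its seed is overridden per
#'   network).
#' @param readout A [readout_config()] template.
#' @param window Cycles per micro-stage (default 20).
#' @param registry Font registry.
#' @return A list of class `study_config`.
#' @export
study_config <- function(study = 1L, master_seed = 1L,
                         replicas_per_condition = NULL, letters = NULL,
                         train = train_config(), readout = readout_config(),
                         window = 20L, registry = font_registry()) {
  study <- as.integer(study)
  stopifnot(study %in% c(1L, 2L))
  if (study == 1L) {
    replicas_per_condition <- 1L
    if (is.null(letters)) letters <- LETTERS
  } else {
    if (is.null(replicas_per_condition)) replicas_per_condition <- 20L
    if (is.null(letters)) letters <- c("A", "M")
  }
  structure(list(study = study, master_seed = as.integer(master_seed),
                 replicas_per_condition = as.integer(replicas_per_condition),
                 letters = letters, train = train, readout = readout,
                 window = as.integer(window), registry = registry),
            class = "study_config")
}

# per-letter perimetric complexity: mean over all unique training
# renderings of the letter (27 high-entropy + 2 low-entropy versions)
.letter_peco <- function(registry = font_registry()) {
  he <- registry$font_id[registry$role == "train_he"]
  le <- registry$font_id[registry$role == "train_le"]
  vapply(LETTERS, function(l) {
    imgs <- c(
      lapply(he, function(f) lapply(.STYLES, function(s)
        render_glyph(l, f, s, registry))),
      lapply(le, function(f) list(render_glyph(l, f, "normal", registry)))
    )
    mean(vapply(unlist(imgs, recursive = FALSE), perimetric_complexity,
                numeric(1)))
  }, numeric(1))
}

# train one network + read-out on its condition's set, with optional recorder;
# `probe_set` = NULL disables recording, "train" probes with the training set
.run_network <- function(i, condition, train_set, test_set, config,
                         probe_set = "train") {
  net_id <- sprintf("net%02d_%s", i, condition)
  tcfg <- config$train
  tcfg$seed <- config$master_seed + i
  recorder <- NULL
  if (!is.null(probe_set)) {
    if (identical(probe_set, "train")) probe_set <- train_set
    recorder <- icd_recorder(probe_set, letters = config$letters,
                             window = config$window, network_id = net_id)
  }
  net <- train_dbn(train_set, tcfg, recorder)
  rcfg <- config$readout
  rcfg$seed <- config$master_seed + i + 1000L
  ro <- train_readout(net, train_set, config = rcfg)
  perf <- evaluate_readout(net, ro, test_set, network_id = net_id,
                           condition = condition)
  list(id = net_id, condition = condition, net = net, readout = ro,
       perf = perf, recorder = recorder)
}

# recorded micro-stage matrices -> spectra + indicator rows
.indicator_rows <- function(run, window) {
  ms <- run$recorder$microstages()
  spectra <- lapply(ms, pca_eigenspectrum)
  rows <- do.call(rbind, lapply(spectra, function(s) {
    di <- dimensionality_indicators(s)
    data.frame(network_id = run$id, condition = run$condition,
               letter = di$letter, wght_pd = di$wght_pd,
               wght_sd = di$wght_sd, n_eigen_gt1 = di$n_eigen_gt1,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(spectra = spectra, rows = rows)
}

.assemble_study <- function(config, runs, predictors) {
  ind <- lapply(runs, .indicator_rows, window = config$window)
  indicators <- do.call(rbind, lapply(ind, `[[`, "rows"))
  spectra <- unlist(lapply(ind, `[[`, "spectra"), recursive = FALSE)
  performance <- do.call(rbind, lapply(runs, function(r) r$perf$per_letter))
  rownames(performance) <- NULL

  tab <- merge(indicators,
               performance[, c("network_id", "letter", "accuracy")],
               by = c("network_id", "letter"), sort = FALSE)
  if ("peco" %in% predictors) {
    peco <- .letter_peco(config$registry)
    tab$peco <- peco[tab$letter]
  }
  tab <- tab[order(tab$network_id, tab$letter), ]
  rownames(tab) <- NULL

  reg <- standardized_regression(tab, "accuracy", predictors)
  structure(
    list(study = config$study, config = config,
         performance = performance, indicators = indicators, table = tab,
         regression = reg, spectra = spectra,
         kaiser_cutoff = kaiser_median_cutoff(spectra),
         wght_pd_q05 = quantile_profile(spectra, 0.05),
         recon_error = do.call(rbind, lapply(runs, function(r) {
           cbind(network_id = r$id, r$net$recon_error)
         }))),
    class = "psm_study"
  )
}

#' Run Study 1
#'
#' Trains one network under the high-entropy condition and one under the
#' low-entropy condition, recording the second hidden layer's dynamics
#' for every letter during unsupervised learning; evaluates both on the
#' shared low-contrast test set; computes the 52 per-(network, letter)
#' dimensionality indicator rows; and fits the standardized regression of
#' per-letter accuracy on `wght_pd`, `wght_sd` and perimetric complexity.
#'
#' @param config A [study_config()] with `study = 1`.
#' @return An object of class `psm_study` carrying the performance and
#'   indicator tables, the regression, the 52 eigenspectra, the
#'   Kaiser-like median cutoff and 5th-percentile `wght_pd`, and the
#'   reconstruction-error traces.
#' @export
run_study1 <- function(config = study_config(1L)) {
  stopifnot(inherits(config, "study_config"), config$study == 1L)
  he <- build_training_set("TC-HE", config$registry)
  le <- build_training_set("TC-LE", config$registry)
  test <- build_test_set(config$registry)
  runs <- list(
    .run_network(1L, "TC-HE", he, test, config),
    .run_network(2L, "TC-LE", le, test, config)
  )
  res <- .assemble_study(config, runs, c("wght_pd", "wght_sd", "peco"))
  res$entropy <- list(he = entropy_profile(he), le = entropy_profile(le))
  res
}

#' Run Study 2
#'
#' Replicates the Study 1 procedure over `replicas_per_condition`
#' networks per training condition (40 networks at the default 20 + 20),
#' each trained from its own derived seed. To bound the computation, the
#' internal dynamics are recorded only for one probe image of each
#' analysed letter (A and M), sampled once per condition with the master
#' seed from that condition's unique training versions. The regression
#' omits perimetric complexity (only two letters are analysed).
#'
#' @param config A [study_config()] with `study = 2`.
#' @return A `psm_study`; its table has
#'   `2 * replicas_per_condition * length(letters)` rows (80 at defaults).
#' @export
run_study2 <- function(config = study_config(2L)) {
  stopifnot(inherits(config, "study_config"), config$study == 2L)
  he <- build_training_set("TC-HE", config$registry)
  le <- build_training_set("TC-LE", config$registry)
  test <- build_test_set(config$registry)

  # one probe image per letter and condition, sampled once with the
  # master seed from the condition's unique training versions
  set.seed(config$master_seed)
  pick_probe <- function(set) {
    keep <- !duplicated(set$meta)
    meta <- set$meta[keep, , drop = FALSE]
    imgs <- set$images[keep]
    chosen <- lapply(config$letters, function(l) {
      i <- which(meta$letter == l)
      imgs[[i[sample.int(length(i), 1L)]]]
    })
    .new_stimulus_set(paste0(set$condition, "-probe"), chosen)
  }
  probes <- list("TC-HE" = pick_probe(he), "TC-LE" = pick_probe(le))

  r <- config$replicas_per_condition
  runs <- lapply(seq_len(2L * r), function(i) {
    condition <- if (i <= r) "TC-HE" else "TC-LE"
    train_set <- if (condition == "TC-HE") he else le
    .run_network(i, condition, train_set, test, config,
                 probe_set = probes[[condition]])
  })
  .assemble_study(config, runs, c("wght_pd", "wght_sd"))
}

#' Preliminary design checks
#'
#' Reproduces the three checks that validate the study design: (1) a
#' one-tailed Welch t-test that the high-entropy training set does not
#' carry more information (active pixels per image) than the low-entropy
#' set; (2) a comparison of the pixel-space entropy profiles of the two
#' training sets (the high-entropy set should need at least as many
#' principal components to reach 99% of the variance); and (3) a paired
#' t-test on the 26 per-letter accuracies of one network per condition
#' (df = 25), confirming that the conditions differentiate performance.
#'
#' @param config A [study_config()].
#' @param study Optional fitted `psm_study` (e.g. from [run_study1()])
#'   whose performance table supplies check 3; if omitted, two networks
#'   are trained (without dynamics recording) for that check.
#' @return A list of class `psm_checks` with elements
#'   `amount_of_information`, `entropy_comparison` and
#'   `training_condition_effect`.
#' @export
run_preliminary_checks <- function(config = study_config(1L), study = NULL) {
  he <- build_training_set("TC-HE", config$registry)
  le <- build_training_set("TC-LE", config$registry)

  n_active <- function(set) vapply(set$images, active_pixel_count, numeric(1))
  check1 <- welch_t(n_active(le), n_active(he), alternative = "less")

  prof_he <- entropy_profile(he)
  prof_le <- entropy_profile(le)
  check2 <- list(he = prof_he, le = prof_le,
                 k99_he = components_to_reach(prof_he, 0.99),
                 k99_le = components_to_reach(prof_le, 0.99))

  if (is.null(study)) {
    test <- build_test_set(config$registry)
    runs <- list(
      .run_network(1L, "TC-HE", he, test, config, probe_set = NULL),
      .run_network(2L, "TC-LE", le, test, config, probe_set = NULL)
    )
    perf <- do.call(rbind, lapply(runs, function(r) r$perf$per_letter))
  } else {
    perf <- study$performance
  }
  acc_he <- perf$accuracy[perf$condition == "TC-HE"]
  acc_le <- perf$accuracy[perf$condition == "TC-LE"]
  if (length(acc_he) != 26L || length(acc_le) != 26L) {
    # paired over letters: average within letter if several replicas
    acc_he <- tapply(perf$accuracy[perf$condition == "TC-HE"],
                     perf$letter[perf$condition == "TC-HE"], mean)
    acc_le <- tapply(perf$accuracy[perf$condition == "TC-LE"],
                     perf$letter[perf$condition == "TC-LE"], mean)
  }
  check3 <- paired_t(as.numeric(acc_he), as.numeric(acc_le),
                     alternative = "two.sided")

  structure(list(amount_of_information = check1,
                 entropy_comparison = check2,
                 training_condition_effect = check3,
                 mean_accuracy = c(he = mean(acc_he), le = mean(acc_le))),
            class = "psm_checks")
}

#' @export
print.psm_checks <- function(x, ...) {
  cat("Preliminary design checks\n")
  cat("1) amount of information (active pixels, Welch one-tailed):\n   ")
  print(x$amount_of_information)
  cat(sprintf("2) entropy: components to 99%% variance, TC-HE %d vs TC-LE %d\n",
              x$entropy_comparison$k99_he, x$entropy_comparison$k99_le))
  cat(sprintf("3) condition effect (paired t over letters; mean acc %.3f vs %.3f):\n   ",
              x$mean_accuracy["he"], x$mean_accuracy["le"]))
  print(x$training_condition_effect)
  invisible(x)
}

#' @export
print.psm_study <- function(x, ...) {
  cat(sprintf("<psm_study> Study %d: %d networks, %d indicator rows\n",
              x$study, length(unique(x$table$network_id)), nrow(x$table)))
  acc <- tapply(x$performance$accuracy, x$performance$condition, mean)
  cat(sprintf("  mean per-letter accuracy: %s\n",
              paste(sprintf("%s %.3f", names(acc), acc), collapse = ", ")))
  cat(sprintf("  Kaiser-like median cutoff: %d; 5th pct wght_pd: %.1f%%\n",
              x$kaiser_cutoff, 100 * x$wght_pd_q05))
  print(x$regression)
  invisible(x)
}

#' @export
summary.psm_study <- function(object, ...) {
  print(object)
  cat("\nindicator table head:\n")
  print(utils::head(object$table))
  invisible(object)
}

#' Scatter of accuracy against the primary-dimension weight
#' @param x A `psm_study`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psm_study <- function(x, ...) {
  cols <- ifelse(x$table$condition == "TC-HE", "steelblue", "firebrick")
  graphics::plot(x$table$wght_pd, x$table$accuracy, col = cols, pch = 19,
                 xlab = "weight of primary dimensions (wght_pd)",
                 ylab = "per-letter accuracy", ...)
  graphics::legend("bottomleft", legend = c("TC-HE", "TC-LE"),
                   col = c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(x)
}

#' Export study results to a directory
#'
#' Writes the performance, indicator and merged regression tables as CSV,
#' the regression summary as CSV, the reconstruction-error trace as CSV,
#' and a config snapshot (RDS) sufficient to reproduce the run.
#'
#' @param study A `psm_study`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "psm_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(study$indicators, file.path(dir, "indicators.csv"),
                   row.names = FALSE)
  utils::write.csv(study$table, file.path(dir, "regression_table.csv"),
                   row.names = FALSE)
  co <- study$regression$coefficients
  co$n <- study$regression$n
  co$adj_r2 <- study$regression$adj_r2
  utils::write.csv(co, file.path(dir, "regression_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$recon_error, file.path(dir, "recon_error.csv"),
                   row.names = FALSE)
  saveRDS(study$config, file.path(dir, "config.rds"))
  invisible(dir)
}
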