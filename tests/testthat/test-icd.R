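# micro-stage condensation of activation trajectories

test_that("micro-stage SD reduces cycles by the window factor", {
  set.seed(41)
  rec <- matrix(stats::runif(6 * 60), 6, 60)
  ms <- microstage_sd(rec, window = 20L)
  expect_equal(dim(ms), c(6L, 3L))
  expect_true(all(ms >= 0))
  expect_error(microstage_sd(rec, window = 7L), "not divisible")
})

test_that("window SD equals the two-pass formula on a designed window", {
  rec <- matrix(c(rep(0, 10), rep(1, 10)), 1, 20)
  ms <- microstage_sd(rec, window = 20L)
  expect_equal(ms[1, 1], sqrt(5 / 19), tolerance = 1e-12)  # 20*0.25/19
  expect_equal(ms[1, 1], stats::sd(rec[1, ]), tolerance = 1e-12)
})

test_that("constant recordings give an all-zero micro-stage matrix", {
  ms <- microstage_sd(matrix(0.37, 5, 40), window = 10L)
  expect_true(all(ms == 0))
})

test_that("micro-stage SD is shift invariant and scale equivariant", {
  set.seed(42)
  rec <- matrix(stats::runif(4 * 40), 4, 40)
  base <- microstage_sd(rec, 10L)
  expect_equal(unclass(microstage_sd(rec + 3.7, 10L)), unclass(base),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(microstage_sd(rec * -2.5, 10L)),
               unclass(base) * 2.5, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("streamed micro-stages equal the offline reduction of kept cycles", {
  le <- build_training_set("TC-LE", replicate_le = FALSE)
  rec <- icd_recorder(le, letters = c("D", "Q"), window = 5L,
                      keep_cycles = TRUE, sample_states = FALSE,
                      version_collapse = "mean_activation", network_id = "x")
  n_probe <- nrow(rec$probes)                  # 2 letters x 2 versions
  expect_equal(n_probe, 4L)
  set.seed(43)
  for (i in 1:20) rec$record(matrix(stats::runif(n_probe * 7), n_probe, 7))
  ms_stream <- rec$microstages()
  cyc <- rec$cycles()
  expect_equal(dim(cyc[["D"]]), c(7L, 20L))
  for (l in c("D", "Q")) {
    expect_equal(unclass(ms_stream[[l]]),
                 unclass(microstage_sd(cyc[[l]], 5L)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("version-wise SD collapse equals the per-version offline oracle", {
  le <- build_training_set("TC-LE", replicate_le = FALSE)
  rec <- icd_recorder(le, letters = c("D", "Q"), window = 5L,
                      sample_states = FALSE, version_collapse = "mean_sd")
  set.seed(47)
  traj <- lapply(1:20, function(i) matrix(stats::runif(4 * 7), 4, 7))
  for (a in traj) rec$record(a)
  ms <- rec$microstages()
  # oracle: windowed SD for each version separately, then averaged
  meta <- le$meta[!duplicated(le$meta), ]
  meta <- meta[meta$letter %in% c("D", "Q"), ]
  for (l in c("D", "Q")) {
    rows <- which(meta$letter == l)
    per_version <- lapply(rows, function(v) {
      m <- t(vapply(traj, function(a) a[v, ], numeric(7)))  # cycles x units
      unclass(microstage_sd(t(m), 5L))
    })
    oracle <- Reduce(`+`, per_version) / length(per_version)
    expect_equal(unclass(ms[[l]]), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("letter probes average all of the letter's versions", {
  le <- build_training_set("TC-LE", replicate_le = FALSE)
  rec <- icd_recorder(le, letters = "A", window = 2L, keep_cycles = TRUE,
                      sample_states = FALSE)
  # activations with a known per-version pattern: the two A versions differ
  expect_equal(nrow(rec$probes), 2L)
  a <- rbind(c(0.2, 0.4, 0.6), c(0.8, 0.6, 0.4))
  rec$record(a); rec$record(a)
  cyc <- rec$cycles()[["A"]]
  expect_equal(cyc[, 1], c(0.5, 0.5, 0.5))
})

test_that("sampled-state recording is a seeded Bernoulli draw per probe", {
  le <- build_training_set("TC-LE", replicate_le = FALSE)
  rec <- icd_recorder(le, letters = "A", window = 2L, keep_cycles = TRUE,
                      sample_states = TRUE)
  p <- matrix(c(0, 1, 0.5, 1, 0, 0.5), 2, 3, byrow = TRUE)
  set.seed(91); rec$record(p); rec$record(p)
  cyc1 <- rec$cycles()[["A"]]
  # deterministic p values survive sampling; all states are 0/1 averages
  expect_true(all(cyc1 %in% c(0, 0.5, 1)))
  expect_equal(cyc1[1, ], c(0.5, 0.5))   # mean of a sure 0 and a sure 1
  rec2 <- icd_recorder(le, letters = "A", window = 2L, keep_cycles = TRUE,
                       sample_states = TRUE)
  set.seed(91); rec2$record(p); rec2$record(p)
  expect_identical(cyc1, rec2$cycles()[["A"]])  # same seed, same draws
})

test_that("a probe letter absent from the set is a configuration error", {
  le <- build_training_set("TC-LE", replicate_le = FALSE)
  keep <- le$meta$letter != "M"
  crippled <- harmonium:::.new_stimulus_set("TC-LE", le$images[keep])
  expect_error(icd_recorder(crippled, letters = c("A", "M")), "M")
})
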