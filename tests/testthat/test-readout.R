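# delta-rule read-out and evaluation

test_that("zero learning rate leaves the classifier at its origin", {
  set.seed(21)
  h <- matrix(stats::runif(40), 10, 4)
  labels <- rep(c("A", "B"), 5)
  ro <- train_readout(NULL, h, labels,
                      readout_config(epochs = 5L, learning_rate = 0,
                                     batches_per_epoch = 2L))
  expect_true(all(ro$w == 0))
  expect_true(all(ro$b == 0))
})

test_that("a separable two-class toy is learned perfectly", {
  set.seed(22)
  n <- 30
  h <- rbind(cbind(stats::runif(n, .7, .9), stats::runif(n, .1, .3)),
             cbind(stats::runif(n, .1, .3), stats::runif(n, .7, .9)))
  labels <- rep(c("A", "B"), each = n)
  ro <- train_readout(NULL, h, labels,
                      readout_config(epochs = 200L, learning_rate = 0.5,
                                     batches_per_epoch = 10L, seed = 2L))
  expect_equal(mean(predict(ro, h) == labels), 1)
})

test_that("the same seed gives an identical classifier", {
  set.seed(23)
  h <- matrix(stats::runif(200), 20, 10)
  labels <- rep(LETTERS[1:4], 5)
  cfg <- readout_config(epochs = 30L, batches_per_epoch = 5L, seed = 77L)
  a <- train_readout(NULL, h, labels, cfg)
  b <- train_readout(NULL, h, labels, cfg)
  expect_identical(a$w, b$w)
  expect_identical(a$b, b$b)
})

test_that("labels outside A-Z are rejected", {
  h <- matrix(0.5, 4, 3)
  expect_error(train_readout(NULL, h, c("A", "B", "a", "1"),
                             readout_config(epochs = 1L)),
               "outside A-Z")
})

test_that("argmax response breaks ties toward the first letter", {
  ro <- structure(list(w = matrix(0, 4, 26), b = numeric(26)),
                  class = "delta_readout")
  h <- matrix(stats::runif(8), 2, 4)
  expect_equal(predict(ro, h), c("A", "A"))
})

test_that("evaluation scores per-letter accuracies with 12 test items each", {
  set.seed(25)
  x <- build_training_set("TC-LE", replicate_le = FALSE)
  net <- train_dbn(x, tiny_train(seed = 30L, epochs = 3L, batches = 8L),
                   sizes = c(20L, 12L))
  ro <- train_readout(net, x, config = tiny_readout(seed = 31L))
  test <- build_test_set()
  perf <- evaluate_readout(net, ro, test, network_id = "t", condition = "TC-LE")
  expect_equal(nrow(perf$per_letter), 26L)
  expect_equal(perf$per_letter$letter, LETTERS)
  expect_true(all(perf$per_letter$n_test_items == 12L))
  # accuracies are rational with denominator 12
  expect_true(all(abs(perf$per_letter$accuracy * 12 -
                        round(perf$per_letter$accuracy * 12)) < 1e-12))
  # overall equals the mean of per-letter accuracies (equal item counts)
  expect_equal(perf$overall, mean(perf$per_letter$accuracy))
})

test_that("an all-zero read-out answers A everywhere: accuracy exactly 1/26", {
  set.seed(26)
  x <- build_training_set("TC-LE", replicate_le = FALSE)
  net <- train_dbn(x, tiny_train(seed = 32L, epochs = 1L, batches = 4L),
                   sizes = c(10L, 8L))
  ro <- structure(list(w = matrix(0, 8, 26), b = numeric(26)),
                  class = "delta_readout")
  perf <- evaluate_readout(net, ro, build_test_set())
  expect_equal(perf$overall, 1 / 26)
  expect_equal(perf$per_letter$accuracy, c(1, rep(0, 25)))
})

test_that("random read-outs score at chance level on the test set", {
  set.seed(27)
  x <- build_training_set("TC-LE", replicate_le = FALSE)
  net <- train_dbn(x, tiny_train(seed = 33L, epochs = 1L, batches = 4L),
                   sizes = c(10L, 8L))
  test <- build_test_set()
  accs <- vapply(1:5, function(i) {
    ro <- structure(list(w = matrix(stats::rnorm(8 * 26, sd = 4), 8, 26),
                         b = stats::rnorm(26, sd = 4)),
                    class = "delta_readout")
    evaluate_readout(net, ro, test)$overall
  }, numeric(1))
  expect_gt(mean(accs), 1 / 26 - 0.025)
  expect_lt(mean(accs), 1 / 26 + 0.035)
})

test_that("a test set missing a letter is an evaluation error", {
  set.seed(28)
  x <- build_training_set("TC-LE", replicate_le = FALSE)
  net <- train_dbn(x, tiny_train(seed = 34L, epochs = 1L, batches = 4L),
                   sizes = c(10L, 8L))
  ro <- structure(list(w = matrix(0, 8, 26), b = numeric(26)),
                  class = "delta_readout")
  test <- build_test_set()
  keep <- test$meta$letter != "Z"
  partial <- harmonium:::.new_stimulus_set("TEST", test$images[keep])
  expect_error(evaluate_readout(net, ro, partial), "Z")
})
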