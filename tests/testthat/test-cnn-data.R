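aug_epochs <- function(n_trials = 2, fs = 1024, n_ch = 32) {
  set.seed(101)
  len <- 5 * fs
  arr <- array(rnorm(n_ch * len * n_trials), dim = c(n_ch, len, n_trials),
               dimnames = list(mi_channel_order32()[seq_len(n_ch)]))
  structure(list(data = arr, fs = fs,
                 labels = mi_channel_order32()[seq_len(n_ch)],
                 classes = rep(c("left", "right"), length.out = n_trials),
                 trial_order = seq_len(n_trials),
                 window = c(0, 5), baseline = c(0, 1)),
            class = "eeg_epochs")
}

test_that("channel rearrangement reorders exactly and is invertible", {
  ep <- aug_epochs()
  shuffled <- ep
  perm <- sample(32)
  shuffled$data <- ep$data[perm, , , drop = FALSE]
  shuffled$labels <- ep$labels[perm]
  back <- rearrange_channels(shuffled, mi_channel_order32())
  expect_identical(back$data, ep$data)
  expect_identical(back$labels, mi_channel_order32())
  # already ordered input is untouched
  expect_identical(rearrange_channels(ep)$data, ep$data)
  # position 8 of the fixed order is C3
  expect_equal(mi_channel_order32()[8], "C3")
  expect_identical(back$data[8, , ], shuffled$data[match("C3", shuffled$labels), , ])
  missing <- shuffled
  missing$data <- missing$data[-1, , , drop = FALSE]
  missing$labels <- missing$labels[-1]
  expect_error(rearrange_channels(missing), shuffled$labels[1])
})

test_that("standardization gives global mean 0 / sd 1 and is affine-invariant", {
  set.seed(2)
  x <- matrix(rnorm(32 * 512, mean = 4, sd = 3), 32)
  z <- standardize_sample(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(stats::sd(z) - 1), 1e-6)
  expect_equal(standardize_sample(z), z, tolerance = 1e-6)
  expect_equal(standardize_sample(2.5 * x - 7), z, tolerance = 1e-10)
  expect_error(standardize_sample(matrix(1, 4, 4)), "constant")
})

test_that("sliding-window augmentation yields 12 decimated samples per trial", {
  ep <- aug_epochs(n_trials = 2)
  s <- augment_sliding(ep)
  expect_equal(dim(s$x), c(32, 512, 24))
  expect_equal(nrow(s$meta), 24)
  expect_equal(as.integer(table(s$meta$trial)), rep(12L, 2))
  # phase-0 sample of the first window is columns 1, 5, 9, ... standardized
  raw <- ep$data[, seq(1, 2048, by = 4), 1]
  expect_equal(s$x[, , 1], unname(standardize_sample(raw)), tolerance = 1e-12)
  # phase-2 sample starts at the third point
  raw2 <- ep$data[, 2 + seq(1, 2048, by = 4), 1]
  expect_equal(s$x[, , 3], unname(standardize_sample(raw2)), tolerance = 1e-12)
  # second window starts 1 s in
  raw3 <- ep$data[, 1024 + seq(1, 2048, by = 4), 1]
  expect_equal(s$x[, , 5], unname(standardize_sample(raw3)), tolerance = 1e-12)
  # all samples standardized
  mus <- apply(s$x, 3, mean)
  sds <- apply(s$x, 3, stats::sd)
  expect_lt(max(abs(mus)), 1e-6)
  expect_lt(max(abs(sds - 1)), 1e-6)
  # short epochs are rejected
  short <- ep
  short$data <- short$data[, 1:3000, , drop = FALSE]
  expect_error(augment_sliding(short), "too short")
})

test_that("train/test split is trial-grouped, sized, and deterministic", {
  ep <- aug_epochs(n_trials = 10)
  s <- augment_sliding(ep)
  sp <- split_train_test(s, ratio = 0.8, seed = 4)
  expect_equal(dim(sp$train$x)[3], 96)
  expect_equal(dim(sp$test$x)[3], 24)
  expect_length(intersect(unique(sp$train$meta$trial),
                          unique(sp$test$meta$trial)), 0)
  sp2 <- split_train_test(s, ratio = 0.8, seed = 4)
  expect_identical(sp$train$meta, sp2$train$meta)
  sp3 <- split_train_test(s, ratio = 0.8, seed = 5)
  expect_false(identical(sp$train$meta$trial, sp3$train$meta$trial))
  expect_error(split_train_test(s, ratio = 1.2), "ratio")
})
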