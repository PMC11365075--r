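# Conditional adversarial translator: objective values against hand
# computation, architecture contracts, determinism, training sanity on a
# memorizable singleton, and checkpoint round-trips.

test_that("the adversarial objective matches hand-evaluated cases", {
  half <- matrix(0.5, 3, 3)
  expect_equal(cgan_objective(half, half), 2 * log(0.5))

  expect_equal(cgan_objective(matrix(0.9), matrix(0.2)), log(0.9) + log(0.8))

  # perfect-critic limit approaches the supremum 0 and stays finite at the
  # clamped extremes
  expect_gt(cgan_objective(matrix(1), matrix(0)), 2 * log(1 - 1e-6))
  expect_true(is.finite(cgan_objective(matrix(1), matrix(1))))
  expect_true(is.finite(cgan_objective(matrix(0), matrix(0))))
  expect_lte(cgan_objective(matrix(0.7, 2, 2), matrix(0.4, 2, 2)), 0)

  expect_error(cgan_objective(matrix(0.5, 2, 2), matrix(0.5, 3, 3)), "shape")
  expect_error(cgan_objective(matrix(1.5), matrix(0.5)), "probabilities")
})

test_that("the L1 loss is the mean absolute pixel difference", {
  a <- matrix(0.4, 5, 5)
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(matrix(0.2, 3, 3), matrix(0.5, 3, 3)), 0.3)
  tgt <- matrix(c(0, 1, 1, 0), 2, 2)
  gen <- matrix(c(0.25, 0.5, 0.75, 0.5), 2, 2)
  expect_equal(l1_loss(tgt, gen), 0.375)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("generator contract: shape, range, depth, seeding", {
  spec <- generator_spec(64L, base_channels = 4L)
  expect_equal(spec$depth, 6L)
  g1 <- build_generator(spec, seed = 5)
  g2 <- build_generator(spec, seed = 5)
  set.seed(1)
  x <- matrix(runif(64 * 64), 64, 64)
  o1 <- g1(x)
  expect_equal(dim(o1), c(64L, 64L))
  expect_gte(min(o1), 0); expect_lte(max(o1), 1)
  expect_identical(o1, g2(x))                     # seeded init
  g3 <- build_generator(spec, seed = 6)
  expect_false(identical(o1, g3(x)))
  expect_error(g1(matrix(0.5, 32, 32)), "64x64")  # shape contract
  expect_error(generator_spec(48L), "power of two")
  expect_error(generator_spec(64L, dropout_rate = 1), "dropout_rate")

  # stochastic translation is reproducible under a fixed dropout seed
  s1 <- g1(x, stochastic = TRUE, dropout_seed = 9)
  s2 <- g1(x, stochastic = TRUE, dropout_seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, g1(x, stochastic = TRUE, dropout_seed = 10)))
})

test_that("critic contract: patch grid strictly inside (0,1), deterministic", {
  d <- build_discriminator(discriminator_spec(base_channels = 4L), 64L, seed = 2)
  set.seed(3)
  x <- matrix(runif(64 * 64), 64, 64); y <- matrix(runif(64 * 64), 64, 64)
  p <- d(x, y)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(dim(p) < 64) && length(p) > 1)   # strided shrinkage
  expect_identical(p, d(x, y))
  expect_error(d(x, matrix(0.5, 32, 32)), "same shape")
})

test_that("zero-epoch training returns an inference-capable untrained model", {
  pr <- generate_phantom(tiny_params(), seed = 1)
  m <- train_pix2pix(list(pr), generator_spec(32L, base_channels = 4L),
                     discriminator_spec(base_channels = 4L),
                     train_config(epochs = 0L, seed = 1L))
  expect_equal(nrow(m$history), 0)
  msk <- segment(m, pr$image)
  expect_true(all(msk %in% c(0, 1)))
  expect_equal(dim(msk), dim(pr$image))
  expect_error(train_pix2pix(list(), generator_spec(32L),
                             config = train_config(epochs = 1L)),
               "at least one")
})

test_that("a single structured pair is memorized within a bounded budget", {
  pr <- generate_phantom(tiny_params(), seed = 3)
  m <- train_pix2pix(list(pr), generator_spec(32L, base_channels = 8L),
                     discriminator_spec(base_channels = 8L),
                     train_config(epochs = 300L, seed = 1L,
                                  learning_rate = 1e-3))
  h <- m$history
  expect_lt(h$g_l1[300], h$g_l1[1])
  expect_lt(h$g_l1[300], 0.05)
  expect_equal(h$g_total, h$g_adv + 100 * h$g_l1)   # exact identity per epoch
  expect_lt(l1_loss(pr$mask + 0, translate(m, pr$image)), 0.05)
  expect_gt(score_masks(segment(m, pr$image), pr$mask)$f_measure, 0.9)
})

test_that("training is reproducible and translate is deterministic", {
  pairs <- lapply(1:3, function(s) generate_phantom(tiny_params(), seed = s))
  cfg <- train_config(epochs = 2L, seed = 7L)
  m1 <- train_pix2pix(pairs, generator_spec(32L, base_channels = 4L),
                      discriminator_spec(base_channels = 4L), cfg)
  m2 <- train_pix2pix(pairs, generator_spec(32L, base_channels = 4L),
                      discriminator_spec(base_channels = 4L), cfg)
  expect_identical(m1$history, m2$history)
  x <- pairs[[1]]$image
  expect_identical(translate(m1, x), translate(m2, x))
  expect_identical(translate(m1, x), translate(m1, x))
  expect_identical(translate(m1, x, stochastic = TRUE, dropout_seed = 4),
                   translate(m1, x, stochastic = TRUE, dropout_seed = 4))
  # translate-then-binarize composes into a valid mask
  msk <- binarize(translate(m1, x), 0.5)
  expect_true(all(msk %in% c(0, 1)))
})

test_that("checkpoints round-trip to bit-identical inference", {
  pairs <- lapply(1:2, function(s) generate_phantom(tiny_params(), seed = s))
  m <- train_pix2pix(pairs, generator_spec(32L, base_channels = 4L),
                     discriminator_spec(base_channels = 4L),
                     train_config(epochs = 2L, seed = 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- pairs[[2]]$image
  expect_identical(translate(m, x), translate(m2, x))
  expect_identical(segment(m, x), segment(m2, x))
  expect_identical(m$history, m2$history)
})
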