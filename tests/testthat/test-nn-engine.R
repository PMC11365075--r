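# Finite-difference validation of the analytic gradients driving training.
# Each check perturbs one parameter of a live network and compares the loss
# slope with the backpropagated gradient.

ns <- asNamespace("segtrans")

fd_check <- function(L, pname, idx, loss, analytic, eps = 1e-6) {
  orig <- L[[pname]]
  L[[pname]][idx] <- orig[idx] + eps; Lp <- loss()
  L[[pname]][idx] <- orig[idx] - eps; Lm <- loss()
  L[[pname]][idx] <- orig[idx]
  expect_grad_match(analytic, (Lp - Lm) / (2 * eps))
}

test_that("generator gradients match finite differences", {
  gs <- generator_spec(16L, base_channels = 2L, dropout_stages = 0L)
  G <- ns$new_generator(gs, seed = 3)
  set.seed(42)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16) + 0
  loss <- function() l1_loss(y, ns$gen_forward(G, x, train = TRUE))
  out <- ns$gen_forward(G, x, train = TRUE)
  ns$gen_backward(G, sign(out - y) / length(y))
  fd_check(G$enc[[1]], "Wm", 5, loss, G$enc[[1]]$gWm[5])
  fd_check(G$enc[[3]], "Wm", 17, loss, G$enc[[3]]$gWm[17])
  fd_check(G$enc[[1]], "b", 1, loss, G$enc[[1]]$gb[1])
  fd_check(G$enc_norm[[2]], "gamma", 1, loss, G$enc_norm[[2]]$ggamma[1])
  fd_check(G$dec[[2]], "V", 3, loss, G$dec[[2]]$gV[3])
  fd_check(G$dec_norm[[3]], "beta", 2, loss, G$dec_norm[[3]]$gbeta[2])
})

test_that("critic parameter and input gradients match finite differences", {
  D <- ns$new_discriminator(discriminator_spec(patch_depth = 2L,
                                               base_channels = 4L),
                            16L, seed = 2)
  set.seed(7)
  x <- matrix(runif(256), 16, 16); y <- matrix(runif(256), 16, 16)
  loss <- function() -mean(log(ns$disc_forward(D, x, y, train = TRUE)))
  p <- ns$disc_forward(D, x, y, train = TRUE)
  din <- ns$disc_backward(D, -1 / p / length(p))
  fd_check(D$layers[[1]], "Wm", 3, loss, D$layers[[1]]$gWm[3])
  fd_check(D$layers[[4]], "gamma", 2, loss, D$layers[[4]]$ggamma[2])
  fd_check(D$layers[[9]], "Wm", 1, loss, D$layers[[9]]$gWm[1])

  eps <- 1e-6
  yp <- y; yp[10, 10] <- y[10, 10] + eps
  ym <- y; ym[10, 10] <- y[10, 10] - eps
  num <- (-mean(log(ns$disc_forward(D, x, yp))) +
          mean(log(ns$disc_forward(D, x, ym)))) / (2 * eps)
  expect_grad_match(din[10, 10, 2], num)
})

test_that("U-Net gradients match finite differences", {
  U <- ns$new_unet(unet_spec(16L, base_channels = 2L, depth = 2L), seed = 5)
  set.seed(11)
  x <- matrix(runif(256), 16, 16)
  m <- matrix(rbinom(256, 1, 0.3), 16, 16) + 0
  sig <- function(z) 1 / (1 + exp(-z))
  loss <- function() {
    pr <- sig(ns$unet_forward(U, x, train = TRUE))
    -mean(m * log(pr) + (1 - m) * log(1 - pr))
  }
  pr <- sig(ns$unet_forward(U, x, train = TRUE))
  ns$unet_backward(U, (pr - m) / length(m))
  fd_check(U$enc[[1]][[1]], "Wm", 2, loss, U$enc[[1]][[1]]$gWm[2])
  fd_check(U$bott[[1]], "Wm", 8, loss, U$bott[[1]]$gWm[8])
  fd_check(U$up[[2]], "V", 4, loss, U$up[[2]]$gV[4])
  fd_check(U$dec[[1]][[1]], "Wm", 6, loss, U$dec[[1]][[1]]$gWm[6])
  fd_check(U$head, "Wm", 1, loss, U$head$gWm[1])
  fd_check(U$head, "b", 1, loss, U$head$gb[1])
})

test_that("max pooling routes gradients to the argmax with first-tie rule", {
  L <- ns$nn_maxpool(4L, 4L, 1L)
  x <- array(0, c(4, 4, 1)); x[1, 1, 1] <- 1; x[2, 1, 1] <- 1  # tie in cell 1
  y <- ns$maxpool_fwd(L, x, train = TRUE)
  expect_equal(dim(y), c(2, 2, 1))
  expect_equal(y[1, 1, 1], 1)
  dy <- array(1, c(2, 2, 1))
  dx <- ns$maxpool_bwd(L, dy)
  expect_equal(dx[1, 1, 1], 1)   # first candidate wins the tie
  expect_equal(dx[2, 1, 1], 0)
  expect_equal(sum(dx), 4)
})

test_that("convolution geometry is consistent with its transpose", {
  set.seed(1)
  cv <- ns$nn_conv(3L, 5L, 4L, 2L, 1L, 8L, 8L)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- ns$conv_fwd(cv, x)
  expect_equal(dim(y), c(4, 4, 5))
  tv <- ns$nn_convt(5L, 3L, 4L, 2L, 1L, 4L, 4L)
  z <- ns$convt_fwd(tv, y)
  expect_equal(dim(z), c(8, 8, 3))
  # adjoint identity: <conv(x), u> == <x, convT'(u)> for matching weights
  u <- array(runif(length(y)), dim(y))
  tv$V <- cv$Wm   # convT applies the transpose of this weight matrix
  tv$b <- numeric(3L)
  lhs <- sum(ns$conv_fwd(cv, x) * u) - sum(cv$b * apply(u, 3, sum))
  rhs <- sum(x * ns$convt_fwd(tv, u))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})
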