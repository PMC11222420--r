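# Dice metric, soft Dice, Loss_DS and its aggregation.

random_mask <- function(shape, p = 0.3) {
  array(as.integer(runif(prod(shape)) < p), shape)
}

test_that("dice_coefficient matches its definition and is symmetric", {
  g <- random_mask(c(8, 8, 4))
  expect_equal(dice_coefficient(g, g), 1.0)
  s <- array(0L, dim(g))
  s[1, 1, 1] <- 1L; g2 <- array(0L, dim(g)); g2[2, 2, 2] <- 1L
  expect_equal(dice_coefficient(s, g2), 0.0)
  # |S|=4, |G|=4, |S∩G|=2 -> 0.5
  s3 <- array(0L, c(4, 4)); s3[1, 1:4] <- 1L
  g3 <- array(0L, c(4, 4)); g3[1, 3:4] <- 1L; g3[2, 1:2] <- 1L
  expect_equal(dice_coefficient(s3, g3), 0.5)
  # both empty -> 1 by convention
  expect_equal(dice_coefficient(array(0L, c(3, 3)), array(0L, c(3, 3))), 1.0)
  set.seed(10)
  for (i in 1:50) {
    a <- random_mask(c(6, 6, 3)); b <- random_mask(c(6, 6, 3))
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
  }
  expect_error(dice_coefficient(array(0, c(2, 2)), array(0, c(3, 2))), "shape")
})

test_that("soft_dice reduces to hard Dice for binary maps and handles emptiness", {
  set.seed(2)
  g <- random_mask(c(10, 10))
  expect_equal(soft_dice(g, g), 1.0, tolerance = 1e-6)
  # p constant 0.5 on half-foreground ground truth -> 0.5
  g2 <- matrix(0L, 8, 8); g2[, 1:4] <- 1L
  p <- matrix(0.5, 8, 8)
  expect_equal(soft_dice(p, g2), 0.5, tolerance = 1e-6)
  expect_equal(soft_dice(matrix(0, 4, 4), matrix(0L, 4, 4)), 1.0)
  # agreement with hard Dice on random binary pairs at eps -> 0
  for (i in 1:20) {
    a <- random_mask(c(7, 7)); b <- random_mask(c(7, 7))
    expect_equal(soft_dice(a, b, eps = 1e-12), dice_coefficient(a, b),
                 tolerance = 1e-9)
  }
})

test_that("loss_ds is zero at the target and ln2 + 0.5 at uniform 0.5", {
  g <- matrix(0L, 8, 8); g[, 1:4] <- 1L
  perfect <- pmin(pmax(g, 1e-9), 1 - 1e-9)
  expect_lt(loss_ds(perfect, g), 1e-6)
  # independent numeric evaluation of the uniform-0.5 case
  p <- matrix(0.5, 8, 8)
  expected <- -mean(g * log(0.5) + (1 - g) * log(0.5)) +
    1 - (2 * sum(p * g)) / (sum(p) + sum(g))
  expect_equal(expected, log(2) + 0.5, tolerance = 1e-9)
  expect_equal(loss_ds(p, g), log(2) + 0.5, tolerance = 1e-6)
  expect_error(loss_ds(matrix(1.2, 2, 2), matrix(1L, 2, 2)), "\\[0, 1\\]")
})

test_that("loss_ds is minimised by the target over random probability maps", {
  set.seed(3)
  g <- random_mask(c(8, 8))
  ref <- loss_ds(pmin(pmax(g, 1e-9), 1 - 1e-9), g)
  for (i in 1:100) {
    x <- matrix(runif(64), 8, 8)
    expect_gte(loss_ds(x, g), ref)
  }
})

test_that("analytic gradient of loss_ds matches numeric differentiation", {
  set.seed(4)
  g <- random_mask(c(8, 8))
  x <- matrix(runif(64, 0.05, 0.95), 8, 8)
  ga <- loss_ds_grad(x, g)
  h <- 1e-6
  for (ii in sample(64, 12)) {
    xp <- x; xp[ii] <- xp[ii] + h
    xm <- x; xm[ii] <- xm[ii] - h
    gn <- (loss_ds(xp, g) - loss_ds(xm, g)) / (2 * h)
    expect_equal(ga[ii], gn, tolerance = 1e-4)
  }
})

fake_forward_output <- function(side_per_class, H, W) {
  nc <- length(side_per_class)
  final <- array(0, c(H, W, nc, 1))
  for (ci in seq_len(nc)) {
    last <- side_per_class[[ci]][[length(side_per_class[[ci]])]]
    final[, , ci, ] <- last[, , 1, ]
  }
  list(final_probs = final, side_outputs = side_per_class)
}

test_that("deep_supervision_loss aggregates equally and symmetrically", {
  H <- 16
  # all-ones targets are exactly representable at every level
  ones <- function(n) array(1, c(n, n, 1, 1))
  side <- list(list(ones(4), ones(8), ones(16)),
               list(ones(4), ones(8), ones(16)))
  out <- fake_forward_output(side, H, H)
  y <- array(1L, c(H, H, 2, 1))
  res <- deep_supervision_loss(out, y)
  expect_lt(res$total, 1e-5)
  expect_equal(res$total, mean(res$breakdown$loss_ds))
  expect_true(all(res$breakdown$loss_ds >= 0))
  expect_true(all(abs(res$breakdown$loss_ds -
                        (res$breakdown$bce + 1 - res$breakdown$soft_dice)) < 1e-12))

  # random side outputs: permuting class order leaves the total unchanged
  set.seed(5)
  rnd <- function(n) array(runif(n * n), c(n, n, 1, 1))
  side2 <- list(list(rnd(4), rnd(8), rnd(16)), list(rnd(4), rnd(8), rnd(16)))
  y2 <- array(0L, c(H, H, 2, 1)); y2[1:8, , 1, ] <- 1L; y2[, 1:5, 2, ] <- 1L
  out2 <- fake_forward_output(side2, H, H)
  r1 <- deep_supervision_loss(out2, y2)
  out2p <- fake_forward_output(side2[c(2, 1)], H, H)
  r2 <- deep_supervision_loss(out2p, y2[, , c(2, 1), , drop = FALSE])
  expect_equal(r1$total, r2$total, tolerance = 1e-12)

  # N_c = 1, single level: total equals loss_ds of the pair
  p1 <- rnd(16)
  out1 <- list(final_probs = p1, side_outputs = list(list(p1)))
  y1 <- array(as.integer(p1 > 0.5), c(16, 16, 1, 1))
  r <- deep_supervision_loss(out1, y1)
  expect_equal(r$total, loss_ds(p1, y1), tolerance = 1e-12)

  # class-count mismatch errors
  expect_error(deep_supervision_loss(out2, y2[, , 1, , drop = FALSE]),
               "classes")
})

test_that("deep-supervision gradients flow through the bilinear upscale", {
  set.seed(6)
  n <- 8
  p <- array(runif(n * n, 0.1, 0.9), c(n, n, 1, 1))
  out <- list(final_probs = NULL, side_outputs = list(list(p)))
  out$final_probs <- array(p, c(n, n, 1, 1))
  y <- array(0L, c(2 * n, 2 * n, 1, 1)); y[4:10, 5:12, 1, 1] <- 1L
  # side output at half resolution, upscaled internally
  dim(out$final_probs) <- c(n, n, 1, 1)
  res <- deep_supervision_loss(list(final_probs = array(0.5, c(2 * n, 2 * n, 1, 1)),
                                    side_outputs = list(list(p))),
                               y, with_grad = TRUE)
  ga <- res$grads[[1]][[1]]
  h <- 1e-6
  for (ii in sample(n * n, 8)) {
    pp <- p; pp[ii] <- pp[ii] + h
    pm <- p; pm[ii] <- pm[ii] - h
    f <- function(q) deep_supervision_loss(
      list(final_probs = array(0.5, c(2 * n, 2 * n, 1, 1)),
           side_outputs = list(list(q))), y)$total
    gn <- (f(pp) - f(pm)) / (2 * h)
    expect_equal(ga[ii], gn, tolerance = 1e-4)
  }
})
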