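test_that("softmax_rows maps onto the simplex with shift invariance", {
  expect_equal(softmax_rows(matrix(0, 1, 3)), matrix(1 / 3, 1, 3))
  a <- matrix(c(0.3, -1.2, 2, 0.5), 2, 2)
  expect_equal(softmax_rows(a + 5), softmax_rows(a))
  set.seed(1)
  s <- softmax_rows(matrix(rnorm(40, sd = 50), 8, 5))
  expect_equal(rowSums(s), rep(1, 8))
  expect_true(all(s > 0))
})

test_that("loss matches hand cases and a naive double-loop oracle", {
  m <- make_manual_model(zero_bias = TRUE)
  # perfect fit, no specific association -> loss 0
  m$sigma_specific[["b1:rna"]][] <- 0
  rec <- m$alpha[["b1:rna"]] *
    m$cell_factors$b1 %*% m$sigma_shared %*% t(m$feature_factors$rna)
  m$data$matrices$b1$rna <- rec
  expect_equal(trifactor_loss(m), 0, tolerance = 1e-12)

  # perfect fit with identity specific association -> lambda * d
  m2 <- m
  m2$sigma_specific[["b1:rna"]] <- diag(m2$d)
  rec2 <- m2$alpha[["b1:rna"]] * m2$cell_factors$b1 %*%
    (m2$sigma_shared + diag(m2$d)) %*% t(m2$feature_factors$rna)
  m2$data$matrices$b1$rna <- rec2
  expect_equal(trifactor_loss(m2), 0.001 * m2$d, tolerance = 1e-12)

  # random toy vs naive summation oracle
  m3 <- make_manual_model(n = 4, p = 3, d = 2, seed = 7)
  expect_equal(trifactor_loss(m3), naive_loss(m3), tolerance = 1e-10)
  # shape mismatch detected
  bad <- m3$data
  bad$matrices$b1$rna <- matrix(0, 5, 3)
  expect_error(trifactor_loss(m3, bad), "mismatch")
})

test_that("closed-form updates match their definitions and oracles", {
  # residual with constant rows and zero feature bias -> b_cell = the constant
  m <- make_manual_model(n = 6, p = 5, d = 3, seed = 20, zero_bias = TRUE)
  P <- m$cell_factors$b1 %*%
    (m$sigma_shared + m$sigma_specific[["b1:rna"]]) %*% t(m$feature_factors$rna)
  cc <- c(1, -2, 0.5, 3, -1, 2)
  m$data$matrices$b1$rna <- m$alpha[["b1:rna"]] * P + cc
  up <- closed_form_updates(m, batch = "b1", modality = "rna")
  expect_equal(unname(up$b_cell), cc, tolerance = 1e-12)

  # X = 2 * reconstruction, zero biases -> alpha = 2
  m$data$matrices$b1$rna <- 2 * P
  up2 <- closed_form_updates(m, batch = "b1", modality = "rna")
  expect_equal(up2$alpha, 2, tolerance = 1e-12)

  # random 5x4 toy: alpha equals the no-intercept least-squares slope of
  # vec(X - b) on vec(reconstruction)
  m4 <- make_manual_model(n = 5, p = 4, d = 3, seed = 31)
  X <- m4$data$matrices$b1$rna
  P4 <- m4$cell_factors$b1 %*%
    (m4$sigma_shared + m4$sigma_specific[["b1:rna"]]) %*%
    t(m4$feature_factors$rna)
  Xb <- X - outer(m4$cell_bias[["b1:rna"]], rep(1, 4)) -
    outer(rep(1, 5), m4$feature_bias[["b1:rna"]])
  slope <- unname(coef(lm(as.vector(Xb) ~ 0 + as.vector(P4))))
  up4 <- closed_form_updates(m4, batch = "b1", modality = "rna")
  expect_equal(up4$alpha, slope, tolerance = 1e-8)
  # b_cell / b_feat are the coordinate minimizers given the others
  expect_equal(up4$b_cell,
               rowMeans(X - m4$alpha[["b1:rna"]] * P4 -
                          outer(rep(1, 5), m4$feature_bias[["b1:rna"]])),
               tolerance = 1e-12)
  expect_equal(up4$b_feat,
               colMeans(X - m4$alpha[["b1:rna"]] * P4 -
                          outer(m4$cell_bias[["b1:rna"]], rep(1, 4))),
               tolerance = 1e-12)

  # zero reconstruction leaves alpha unchanged with a warning
  m5 <- m4
  m5$sigma_shared[] <- 0; m5$sigma_specific[["b1:rna"]][] <- 0
  expect_warning(up5 <- closed_form_updates(m5, batch = "b1",
                                            modality = "rna"), "alpha")
  expect_equal(up5$alpha, m5$alpha[["b1:rna"]])
})

test_that("sequential closed-form updates never increase the loss", {
  for (seed in c(3, 14, 27)) {
    m <- make_manual_model(n = 7, p = 6, d = 3, seed = seed)
    before <- trifactor_loss(m)
    up <- closed_form_updates(m, batch = "b1", modality = "rna",
                              sequential = TRUE)
    m$cell_bias[["b1:rna"]] <- up$b_cell
    m$feature_bias[["b1:rna"]] <- up$b_feat
    m$alpha[["b1:rna"]] <- up$alpha
    expect_lte(trifactor_loss(m), before + 1e-10)
  }
})

test_that("fit recovers planted rank-d structure and is seed-deterministic", {
  pl <- make_planted(n = 60, p = 30, d = 4, seed = 2)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X)))
  fit <- tri_factor(data, d = 4, n_iters = 600, batch_frac = 1,
                    learning_rate = 0.05, checkpoint_every = 100, seed = 5,
                    normalize = FALSE)
  lt <- fit$loss_trace
  expect_lt(lt$loss[nrow(lt)], 0.05 * lt$loss[1])
  expect_gt(cor(as.vector(predict(fit)), as.vector(pl$X)), 0.99)

  fit2 <- tri_factor(data, d = 4, n_iters = 600, batch_frac = 1,
                     learning_rate = 0.05, checkpoint_every = 100, seed = 5,
                     normalize = FALSE)
  expect_identical(fit$cell_factors, fit2$cell_factors)
  expect_identical(fit$feature_factors, fit2$feature_factors)
  expect_identical(fit$sigma_shared, fit2$sigma_shared)
})

test_that("simplex and non-negativity invariants hold at every checkpoint", {
  pl <- make_planted(n = 40, p = 20, d = 3, seed = 4)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X)))
  fit <- tri_factor(data, d = 3, n_iters = 300, batch_frac = 0.5,
                    learning_rate = 0.05, checkpoint_every = 50, seed = 1,
                    normalize = FALSE)
  inv <- fit$invariant_trace
  expect_true(all(inv$max_rowsum_dev < 1e-6))
  expect_true(all(inv$min_factor > 0))
  expect_true(all(inv$min_sigma >= 0))
})

test_that("checkpointed loss decreases monotonically in the seed median", {
  pl <- make_planted(n = 40, p = 20, d = 3, seed = 6)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X)))
  traces <- sapply(1:5, function(s) {
    tri_factor(data, d = 3, n_iters = 250, batch_frac = 0.5,
               learning_rate = 0.05, checkpoint_every = 50, seed = s,
               normalize = FALSE)$loss_trace$loss
  })
  med <- apply(traces, 1, median)
  expect_true(all(diff(med) <= 1e-8 + 0.01 * med[-length(med)]))
})

test_that("matched cells of duplicated batches get matching factors", {
  pl <- make_planted(n = 50, p = 25, d = 3, seed = 8)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X),
                              b2 = list(rna = pl$X)))
  fit <- tri_factor(data, d = 3, n_iters = 800, batch_frac = 1,
                    learning_rate = 0.05, checkpoint_every = 200, seed = 3,
                    normalize = FALSE)
  C1 <- fit$cell_factors$b1; C2 <- fit$cell_factors$b2
  matched <- mean(sqrt(rowSums((C1 - C2)^2)))
  baseline <- mean(as.matrix(dist(C1)))
  expect_lt(matched, 0.25 * baseline)
})

test_that("diverging settings abort with diagnostics", {
  pl <- make_planted(n = 20, p = 10, d = 2, seed = 9)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X * 1e200)))
  expect_error(
    tri_factor(data, d = 2, n_iters = 200, batch_frac = 1,
               learning_rate = 10, checkpoint_every = 50, seed = 1,
               normalize = FALSE),
    "non-finite|learning")
})

test_that("model checkpoints round-trip through plain-text files", {
  pl <- make_planted(n = 20, p = 10, d = 2, seed = 15)
  data <- mosaic_dataset(list(b1 = list(rna = pl$X)))
  fit <- tri_factor(data, d = 2, n_iters = 100, batch_frac = 1,
                    learning_rate = 0.05, checkpoint_every = 50, seed = 1,
                    normalize = FALSE)
  dir <- withr::local_tempdir()
  write_model(fit, dir)
  back <- read_model(dir)
  expect_equal(back$cell_factors$b1, unname(fit$cell_factors$b1),
               tolerance = 1e-12)
  expect_equal(back$sigma_shared, fit$sigma_shared, tolerance = 1e-12)
  expect_equal(back$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(back$loss_trace$loss, fit$loss_trace$loss, tolerance = 1e-12)
  # the reloaded parameters reproduce the fitted loss on the same data
  expect_equal(trifactor_loss(back, data = data), trifactor_loss(fit),
               tolerance = 1e-6)
})
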