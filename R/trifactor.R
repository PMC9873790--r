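#' Row-wise softmax
#'
#' Maps every row of a raw parameter matrix onto the interior of the
#' probability simplex; numerically stabilized by subtracting the row
#' maximum, so the result is invariant to adding a constant within a row.
#'
#' @param raw numeric matrix with finite entries.
#' @return matrix of the same shape with positive rows summing to 1.
#' @export
softmax_rows <- function(raw) {
  raw <- as.matrix(raw)
  mx <- apply(raw, 1, max)
  e <- exp(raw - mx)
  e / rowSums(e)
}

# reconstruction alpha * C (S + S_spec) Cf' + b_cell + b_feat'
recon_slot <- function(C, Cf, S, S_spec, alpha, b_cell, b_feat) {
  P <- C %*% (S + S_spec) %*% t(Cf)
  alpha * P + outer(b_cell, rep(1, ncol(P))) + outer(rep(1, nrow(P)), b_feat)
}

slot_key <- function(batch, modality) paste(batch, modality, sep = ":")

# ---- internal optimizer state ---------------------------------------------

# lazy Adam: moments are kept full-size but only the touched rows move
adam_make <- function(dim) list(m = array(0, dim), v = array(0, dim), t = 0)

adam_step <- function(st, grad, rows = NULL, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  if (is.null(rows)) {
    st$m <- b1 * st$m + (1 - b1) * grad
    st$v <- b2 * st$v + (1 - b2) * grad^2
    mhat <- st$m / (1 - b1^st$t)
    vhat <- st$v / (1 - b2^st$t)
    st$delta <- lr * mhat / (sqrt(vhat) + eps)
  } else {
    st$m[rows, ] <- b1 * st$m[rows, , drop = FALSE] + (1 - b1) * grad
    st$v[rows, ] <- b2 * st$v[rows, , drop = FALSE] + (1 - b2) * grad^2
    mhat <- st$m[rows, , drop = FALSE] / (1 - b1^st$t)
    vhat <- st$v[rows, , drop = FALSE] / (1 - b2^st$t)
    st$delta <- lr * mhat / (sqrt(vhat) + eps)
  }
  st
}

# backpropagate a gradient through the row softmax
softmax_backprop <- function(C, grad_C) {
  C * (grad_C - rowSums(grad_C * C))
}

# ---- engine ----------------------------------------------------------------

# Joint alternating mini-batch optimization of all tri-factorization terms.
# `slots` is a data.frame(batch, modality); `mats` a list keyed batch:modality
# of dense matrices. When `fixed_cells` is given (retraining), cell factors
# are used as-is (no softmax) and never updated.
tf_engine <- function(slots, mats, d, lambda_reg, n_iters, batch_frac,
                      learning_rate, checkpoint_every, seed,
                      fixed_cells = NULL, init_sd = 0.1) {
  set.seed(seed)
  batch_ids <- unique(slots$batch)
  modality_ids <- unique(slots$modality)
  keys <- slot_key(slots$batch, slots$modality)
  n_cells <- vapply(batch_ids, function(b)
    nrow(mats[[keys[match(b, slots$batch)]]]), integer(1))
  n_feats <- vapply(modality_ids, function(m)
    ncol(mats[[keys[match(m, slots$modality)]]]), integer(1))
  names(n_cells) <- batch_ids; names(n_feats) <- modality_ids

  freeze <- !is.null(fixed_cells)
  A <- if (freeze) NULL else
    lapply(stats::setNames(batch_ids, batch_ids), function(b)
      matrix(stats::rnorm(n_cells[b] * d, sd = init_sd), n_cells[b], d))
  Fm <- lapply(stats::setNames(modality_ids, modality_ids), function(m)
    matrix(stats::rnorm(n_feats[m] * d, sd = init_sd), n_feats[m], d))
  # identity start: a zero Sigma is a degenerate saddle (the reconstruction
  # vanishes, leaving the trace-ratio scale update ill-posed)
  S <- diag(d)
  S_spec <- lapply(stats::setNames(keys, keys), function(k) matrix(0, d, d))
  b_cell <- lapply(stats::setNames(keys, keys), function(k)
    numeric(nrow(mats[[k]])))
  b_feat <- lapply(stats::setNames(keys, keys), function(k)
    numeric(ncol(mats[[k]])))
  alpha <- stats::setNames(rep(1, length(keys)), keys)

  opt <- list()
  if (!freeze) for (b in batch_ids)
    opt[[paste0("A.", b)]] <- adam_make(dim(A[[b]]))
  for (m in modality_ids) opt[[paste0("F.", m)]] <- adam_make(dim(Fm[[m]]))
  opt[["S"]] <- adam_make(dim(S))
  for (k in keys) opt[[paste0("Ss.", k)]] <- adam_make(dim(S))

  cell_factor <- function(b, rows = NULL) {
    if (freeze) {
      if (is.null(rows)) fixed_cells[[b]] else
        fixed_cells[[b]][rows, , drop = FALSE]
    } else {
      if (is.null(rows)) softmax_rows(A[[b]]) else
        softmax_rows(A[[b]][rows, , drop = FALSE])
    }
  }

  full_loss <- function() {
    tot <- 0
    for (i in seq_len(nrow(slots))) {
      k <- keys[i]
      rec <- recon_slot(cell_factor(slots$batch[i]), softmax_rows(Fm[[slots$modality[i]]]),
                        S, S_spec[[k]], alpha[k], b_cell[[k]], b_feat[[k]])
      tot <- tot + sum((mats[[k]] - rec)^2) + lambda_reg * sum(S_spec[[k]]^2)
    }
    tot
  }

  # sequential closed-form refresh of b_cell, b_feat, alpha for one slot,
  # restricted to the given rows/cols (NULL = full matrix)
  refresh_scales <- function(i, rows = NULL, cols = NULL) {
    k <- keys[i]
    X <- mats[[k]]
    if (!is.null(rows)) X <- X[rows, , drop = FALSE]
    if (!is.null(cols)) X <- X[, cols, drop = FALSE]
    C <- cell_factor(slots$batch[i], rows)
    Fr <- Fm[[slots$modality[i]]]
    if (!is.null(cols)) Fr <- Fr[cols, , drop = FALSE]
    Cf <- softmax_rows(Fr)
    P <- C %*% (S + S_spec[[k]]) %*% t(Cf)
    ri <- if (is.null(rows)) seq_len(nrow(mats[[k]])) else rows
    ci <- if (is.null(cols)) seq_len(ncol(mats[[k]])) else cols
    bf <- b_feat[[k]][ci]
    b_cell[[k]][ri] <<- rowMeans(X - alpha[k] * P -
                                   outer(rep(1, nrow(X)), bf))
    bc <- b_cell[[k]][ri]
    b_feat[[k]][ci] <<- colMeans(X - alpha[k] * P -
                                   outer(bc, rep(1, ncol(X))))
    bf <- b_feat[[k]][ci]
    # the scalar alpha is refreshed from the full matrix only (mini-batch
    # trace ratios are far too noisy and destabilize training)
    if (is.null(rows) && is.null(cols)) {
      num <- sum((X - outer(bc, rep(1, ncol(X))) -
                    outer(rep(1, nrow(X)), bf)) * P)
      den <- sum(P * P)
      if (den > 0) alpha[k] <<- num / den
    }
  }

  trace_iter <- integer(0); trace_loss <- numeric(0)
  inv_trace <- NULL
  checkpoint <- function(it) {
    for (i in seq_len(nrow(slots))) refresh_scales(i)
    l <- full_loss()
    if (!is.finite(l))
      stopf(paste0("non-finite loss at iteration %d ",
                   "(learning_rate = %g); lower the learning rate"),
            it, learning_rate)
    trace_iter <<- c(trace_iter, it); trace_loss <<- c(trace_loss, l)
    Cs <- lapply(batch_ids, cell_factor)
    Cf <- lapply(Fm, softmax_rows)
    inv_trace <<- rbind(inv_trace, data.frame(
      iter = it, loss = l,
      max_rowsum_dev = max(c(
        if (!freeze) vapply(Cs, function(x) max(abs(rowSums(x) - 1)), 0) else 0,
        vapply(Cf, function(x) max(abs(rowSums(x) - 1)), 0))),
      min_factor = min(c(if (!freeze) min(vapply(Cs, min, 0)) else 0,
                         vapply(Cf, min, 0))),
      min_sigma = min(c(min(S), vapply(S_spec, min, 0)))))
  }
  checkpoint(0L)

  for (it in seq_len(n_iters)) {
    rows <- lapply(stats::setNames(batch_ids, batch_ids), function(b)
      sort(sample.int(n_cells[b], max(1L, round(batch_frac * n_cells[b])))))
    cols <- lapply(stats::setNames(modality_ids, modality_ids), function(m)
      sort(sample.int(n_feats[m], max(1L, round(batch_frac * n_feats[m])))))

    sub_parts <- function(i) {
      k <- keys[i]; b <- slots$batch[i]; m <- slots$modality[i]
      ri <- rows[[b]]; ci <- cols[[m]]
      C <- cell_factor(b, ri)
      Cf <- softmax_rows(Fm[[m]][ci, , drop = FALSE])
      M <- S + S_spec[[k]]
      P <- C %*% M %*% t(Cf)
      R <- mats[[k]][ri, ci, drop = FALSE] - alpha[k] * P -
        outer(b_cell[[k]][ri], rep(1, length(ci))) -
        outer(rep(1, length(ri)), b_feat[[k]][ci])
      list(k = k, ri = ri, ci = ci, C = C, Cf = Cf, M = M, R = R)
    }

    # cell factors
    if (!freeze) for (b in batch_ids) {
      idx <- which(slots$batch == b)
      g <- NULL
      for (i in idx) {
        p <- sub_parts(i)
        gc_ <- -2 * alpha[p$k] * (p$R %*% p$Cf %*% t(p$M))
        g <- if (is.null(g)) gc_ else g + gc_
      }
      Cb <- cell_factor(b, rows[[b]])
      graw <- softmax_backprop(Cb, g)
      nm <- paste0("A.", b)
      opt[[nm]] <- adam_step(opt[[nm]], graw, rows[[b]], learning_rate)
      A[[b]][rows[[b]], ] <- A[[b]][rows[[b]], , drop = FALSE] - opt[[nm]]$delta
    }

    # feature factors
    for (m in modality_ids) {
      idx <- which(slots$modality == m)
      g <- NULL
      for (i in idx) {
        p <- sub_parts(i)
        gf <- -2 * alpha[p$k] * (t(p$R) %*% p$C %*% p$M)
        g <- if (is.null(g)) gf else g + gf
      }
      Cfm <- softmax_rows(Fm[[m]][cols[[m]], , drop = FALSE])
      graw <- softmax_backprop(Cfm, g)
      nm <- paste0("F.", m)
      opt[[nm]] <- adam_step(opt[[nm]], graw, cols[[m]], learning_rate)
      Fm[[m]][cols[[m]], ] <- Fm[[m]][cols[[m]], , drop = FALSE] - opt[[nm]]$delta
    }

    # shared association matrix, then the matrix-specific ones; both are
    # projected onto the non-negative orthant after every update
    gS <- matrix(0, d, d)
    for (i in seq_len(nrow(slots))) {
      p <- sub_parts(i)
      gS <- gS - 2 * alpha[p$k] * (t(p$C) %*% p$R %*% p$Cf)
    }
    opt[["S"]] <- adam_step(opt[["S"]], gS, NULL, learning_rate)
    S <- pmax(S - opt[["S"]]$delta, 0)

    for (i in seq_len(nrow(slots))) {
      p <- sub_parts(i)
      g <- -2 * alpha[p$k] * (t(p$C) %*% p$R %*% p$Cf) +
        2 * lambda_reg * S_spec[[p$k]]
      nm <- paste0("Ss.", p$k)
      opt[[nm]] <- adam_step(opt[[nm]], g, NULL, learning_rate)
      S_spec[[p$k]] <- pmax(S_spec[[p$k]] - opt[[nm]]$delta, 0)
    }

    # bias and scale refresh on the current mini-batch (full refresh happens
    # at checkpoints)
    for (i in seq_len(nrow(slots)))
      refresh_scales(i, rows[[slots$batch[i]]], cols[[slots$modality[i]]])

    if (it %% checkpoint_every == 0L || it == n_iters) checkpoint(it)
  }

  list(cell_factors = lapply(stats::setNames(batch_ids, batch_ids), cell_factor),
       feature_factors = lapply(Fm, softmax_rows),
       sigma_shared = S, sigma_specific = S_spec,
       cell_bias = b_cell, feature_bias = b_feat, alpha = alpha,
       loss_trace = data.frame(iter = trace_iter, loss = trace_loss),
       invariant_trace = inv_trace)
}

# ---- user-facing fit -------------------------------------------------------

#' Fit the joint tri-factorization model
#'
#' Decomposes every observed matrix `X[b,m]` of a connected mosaic dataset as
#' `alpha[b,m] * C_b (Sigma + Sigma[b,m]) C_m' + b_cell + b_feat'`, where the
#' rows of the per-batch cell factors `C_b` and per-modality feature factors
#' `C_m` live on the probability simplex (enforced by a row softmax
#' reparameterization) and the shared and matrix-specific association
#' matrices are non-negative (enforced by projection after every update).
#' Training is mini-batch alternating gradient descent with adaptive
#' (Adam-style) steps: each iteration resamples `batch_frac` of the rows and
#' columns of every matrix, updates all cell factors, then all feature
#' factors, then the shared and the matrix-specific association matrices,
#' and finally refreshes biases and scales by their closed-form minimizers.
#'
#' @param data a `mosaic_dataset`; its entity graph must be connected.
#' @param d latent dimension.
#' @param lambda_reg regularization weight on matrix-specific associations.
#' @param n_iters number of mini-batch iterations.
#' @param batch_frac mini-batch fraction of rows and columns.
#' @param learning_rate Adam step size.
#' @param checkpoint_every interval (iterations) at which the full-data loss
#'   is evaluated, biases/scales fully refreshed, and simplex/non-negativity
#'   invariants recorded.
#' @param seed RNG seed; fits are bit-reproducible for a fixed seed.
#' @param normalize apply the per-modality default normalization
#'   (quantile for gene expression, binarize for accessibility and
#'   pseudo-gene-activity, quantile+log for protein) before fitting.
#' @param config optional `run_config`; when given, its entries override the
#'   matching arguments.
#' @return an object of class `tri_factor`.
#' @seealso [neighbor_graph()], [retrain_factors()], [trifactor_loss()]
#' @export
tri_factor <- function(data, d = 30, lambda_reg = 0.001, n_iters = 4000,
                       batch_frac = 0.1, learning_rate = 0.01,
                       checkpoint_every = 100, seed = 0, normalize = TRUE,
                       config = NULL) {
  stopifnot(inherits(data, "mosaic_dataset"))
  if (!is.null(config)) {
    d <- config$d; lambda_reg <- config$lambda_reg
    n_iters <- config$n_iters; batch_frac <- config$batch_frac
    learning_rate <- config$learning_rate
    checkpoint_every <- config$checkpoint_every; seed <- config$seed
  }
  check_connected_filled(data)
  if (normalize) data <- normalize_mosaic(data)
  slots <- mosaic_slots(data)
  mats <- list()
  for (i in seq_len(nrow(slots)))
    mats[[slot_key(slots$batch[i], slots$modality[i])]] <-
      as_dense(mosaic_matrix(data, slots$batch[i], slots$modality[i]))
  res <- tf_engine(slots, mats, d = d, lambda_reg = lambda_reg,
                   n_iters = n_iters, batch_frac = batch_frac,
                   learning_rate = learning_rate,
                   checkpoint_every = checkpoint_every, seed = seed)
  structure(c(res, list(
    d = d, lambda_reg = lambda_reg, seed = seed,
    n_iters = n_iters, batch_frac = batch_frac,
    learning_rate = learning_rate,
    slots = slots, data = data, call = match.call())),
    class = "tri_factor")
}

# all matrices must be in place (no unfilled pseudo slots) and connected
check_connected_filled <- function(data) {
  if (!is.null(data$pseudo_slots) && nrow(data$pseudo_slots) > 0L)
    stopf("dataset has unfilled pseudo slots; run fill_pseudo() first")
  check_connected(data)
}

#' Joint tri-factorization loss
#'
#' Sum over all present matrices of the squared Frobenius reconstruction
#' error plus `lambda_reg` times the squared Frobenius norm of every
#' matrix-specific association matrix.
#'
#' @param model a `tri_factor` (or retrained) model.
#' @param data a `mosaic_dataset` with matrices on the scale the model was
#'   fitted to (i.e. already normalized); defaults to the data stored in the
#'   model.
#' @return non-negative scalar.
#' @export
trifactor_loss <- function(model, data = model$data) {
  tot <- 0
  for (i in seq_len(nrow(model$slots))) {
    b <- model$slots$batch[i]; m <- model$slots$modality[i]
    k <- slot_key(b, m)
    X <- as_dense(mosaic_matrix(data, b, m))
    if (!all(dim(X) == c(nrow(model$cell_factors[[b]]),
                         nrow(model$feature_factors[[m]]))))
      stopf("shape mismatch for slot (%s, %s)", b, m)
    rec <- recon_slot(model$cell_factors[[b]], model$feature_factors[[m]],
                      model$sigma_shared, model$sigma_specific[[k]],
                      model$alpha[k], model$cell_bias[[k]],
                      model$feature_bias[[k]])
    tot <- tot + sum((X - rec)^2) +
      model$lambda_reg * sum(model$sigma_specific[[k]]^2)
  }
  tot
}

#' Closed-form bias and scale updates for one matrix
#'
#' With the factors and association matrices fixed, the cell bias, feature
#' bias and scaling parameter of one tri-factorization term each have a
#' closed-form minimizer: the cell bias is the per-cell mean residual over
#' features, the feature bias the per-feature mean residual over cells, and
#' the scale a trace ratio (the no-intercept least-squares slope of the
#' bias-corrected data on the factor reconstruction). By default each value
#' is computed against the current values of the other two; with
#' `sequential = TRUE` they are computed in order, each seeing the previous
#' updates (the form used inside training, which can never increase the
#' loss).
#'
#' @param model a `tri_factor` model.
#' @param data a `mosaic_dataset` on the fitted scale.
#' @param batch,modality the slot to update.
#' @param sequential apply updates in sequence rather than simultaneously.
#' @return list with `b_cell`, `b_feat`, `alpha`.
#' @export
closed_form_updates <- function(model, data = model$data, batch, modality,
                                sequential = FALSE) {
  k <- slot_key(batch, modality)
  X <- as_dense(mosaic_matrix(data, batch, modality))
  C <- model$cell_factors[[batch]]
  Cf <- model$feature_factors[[modality]]
  if (ncol(X) != nrow(Cf) || nrow(X) != nrow(C))
    stopf("shape mismatch for slot (%s, %s)", batch, modality)
  P <- C %*% (model$sigma_shared + model$sigma_specific[[k]]) %*% t(Cf)
  a <- model$alpha[[k]]
  bc0 <- model$cell_bias[[k]]; bf0 <- model$feature_bias[[k]]
  ones_c <- rep(1, ncol(X)); ones_r <- rep(1, nrow(X))
  b_cell <- rowMeans(X - a * P - outer(ones_r, bf0))
  bc_use <- if (sequential) b_cell else bc0
  b_feat <- colMeans(X - a * P - outer(bc_use, ones_c))
  bf_use <- if (sequential) b_feat else bf0
  bc_use2 <- if (sequential) b_cell else bc0
  den <- sum(P * P)
  if (den > 0) {
    alpha <- sum((X - outer(bc_use2, ones_c) - outer(ones_r, bf_use)) * P) / den
  } else {
    warnf("zero reconstruction for slot (%s, %s); alpha left unchanged",
          batch, modality)
    alpha <- a
  }
  list(b_cell = b_cell, b_feat = b_feat, alpha = alpha)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.tri_factor <- function(x, ...) {
  n <- sum(vapply(x$cell_factors, nrow, integer(1)))
  cat(sprintf("tri_factor model: %d cells in %d batch(es), %d modality(ies), d = %d\n",
              n, length(x$cell_factors), length(x$feature_factors), x$d))
  lt <- x$loss_trace
  cat(sprintf("loss: %.4g (initial) -> %.4g (final) over %d iterations\n",
              lt$loss[1], lt$loss[nrow(lt)], x$n_iters))
  invisible(x)
}

#' @export
summary.tri_factor <- function(object, ...) {
  print(object)
  inv <- object$invariant_trace
  cat(sprintf("simplex deviation (max |rowsum - 1|): %.3g; min factor entry: %.3g\n",
              max(inv$max_rowsum_dev), min(inv$min_factor)))
  cat(sprintf("min association entry: %.3g (constraint: >= 0)\n",
              min(inv$min_sigma)))
  cat("per-matrix scale alpha:\n"); print(round(object$alpha, 4))
  invisible(object)
}

#' @export
coef.tri_factor <- function(object, ...) {
  list(cell_factors = object$cell_factors,
       feature_factors = object$feature_factors,
       sigma_shared = object$sigma_shared,
       sigma_specific = object$sigma_specific,
       alpha = object$alpha)
}

#' Model reconstruction of one grid slot
#' @param object a `tri_factor` model.
#' @param batch,modality slot to reconstruct; defaults to the first slot.
#' @param ... unused.
#' @return the reconstructed cell x feature matrix.
#' @export
predict.tri_factor <- function(object, batch = object$slots$batch[1],
                               modality = object$slots$modality[1], ...) {
  k <- slot_key(batch, modality)
  if (!k %in% slot_key(object$slots$batch, object$slots$modality))
    stopf("model has no slot (%s, %s)", batch, modality)
  recon_slot(object$cell_factors[[batch]], object$feature_factors[[modality]],
             object$sigma_shared, object$sigma_specific[[k]],
             object$alpha[k], object$cell_bias[[k]], object$feature_bias[[k]])
}

#' @export
fitted.tri_factor <- function(object, ...) {
  out <- list()
  for (i in seq_len(nrow(object$slots)))
    out[[slot_key(object$slots$batch[i], object$slots$modality[i])]] <-
      predict(object, object$slots$batch[i], object$slots$modality[i])
  out
}

#' @export
residuals.tri_factor <- function(object, batch = object$slots$batch[1],
                                 modality = object$slots$modality[1], ...) {
  as_dense(mosaic_matrix(object$data, batch, modality)) -
    predict(object, batch, modality)
}

#' @export
plot.tri_factor <- function(x, ...) {
  plot(x$loss_trace$iter, x$loss_trace$loss, type = "b", pch = 16,
       xlab = "iteration", ylab = "full-data loss",
       main = "tri-factorization training trace", ...)
  invisible(x)
}

#' Save a fitted model as plain-text arrays
#'
#' Writes every factor, association matrix, bias and scale as dense TSV
#' files plus a JSON manifest (shapes, training settings, seed, loss trace)
#' so a fit can be archived or inspected without R.
#'
#' @param model a `tri_factor` (or retrained) model.
#' @param dir output directory, created if absent.
#' @return the manifest path, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (b in names(model$cell_factors))
    wt(model$cell_factors[[b]], paste0("cell_factor_", b))
  for (m in names(model$feature_factors))
    wt(model$feature_factors[[m]], paste0("feature_factor_", m))
  wt(model$sigma_shared, "sigma_shared")
  keys <- slot_key(model$slots$batch, model$slots$modality)
  for (i in seq_along(keys)) {
    safe <- gsub(":", "_", keys[i])
    wt(model$sigma_specific[[keys[i]]], paste0("sigma_specific_", safe))
    wt(model$cell_bias[[keys[i]]], paste0("cell_bias_", safe))
    wt(model$feature_bias[[keys[i]]], paste0("feature_bias_", safe))
  }
  wt(model$loss_trace, "loss_trace")
  manifest <- list(
    d = model$d, lambda_reg = model$lambda_reg, seed = model$seed,
    n_iters = model$n_iters, batch_frac = model$batch_frac,
    learning_rate = model$learning_rate,
    slots = model$slots[, c("batch", "modality")],
    alpha = as.list(model$alpha),
    shapes = list(
      cell_factors = lapply(model$cell_factors, dim),
      feature_factors = lapply(model$feature_factors, dim)))
  path <- file.path(dir, "model.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [write_model()]
#'
#' @param dir checkpoint directory.
#' @return a `tri_factor` object (without the training data; methods that
#'   need `model$data`, such as `residuals`, require re-attaching it).
#' @export
read_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  rd <- function(name)
    as.matrix(utils::read.table(file.path(dir, paste0(name, ".tsv")),
                                sep = "\t", header = FALSE))
  keys <- slot_key(man$slots$batch, man$slots$modality)
  cf <- lapply(stats::setNames(names(man$shapes$cell_factors),
                               names(man$shapes$cell_factors)),
               function(b) unname(rd(paste0("cell_factor_", b))))
  ff <- lapply(stats::setNames(names(man$shapes$feature_factors),
                               names(man$shapes$feature_factors)),
               function(m) unname(rd(paste0("feature_factor_", m))))
  ss <- list(); cb <- list(); fb <- list()
  for (i in seq_along(keys)) {
    safe <- gsub(":", "_", keys[i])
    ss[[keys[i]]] <- unname(rd(paste0("sigma_specific_", safe)))
    cb[[keys[i]]] <- as.numeric(rd(paste0("cell_bias_", safe)))
    fb[[keys[i]]] <- as.numeric(rd(paste0("feature_bias_", safe)))
  }
  lt <- utils::read.table(file.path(dir, "loss_trace.tsv"), sep = "\t",
                          header = FALSE, col.names = c("iter", "loss"))
  structure(list(
    cell_factors = cf, feature_factors = ff,
    sigma_shared = unname(rd("sigma_shared")),
    sigma_specific = ss, cell_bias = cb, feature_bias = fb,
    alpha = unlist(man$alpha)[keys],
    d = man$d, lambda_reg = man$lambda_reg, seed = man$seed,
    n_iters = man$n_iters, batch_frac = man$batch_frac,
    learning_rate = man$learning_rate,
    slots = man$slots, loss_trace = lt), class = "tri_factor")
}

#' Stacked cell embedding of a fitted model
#'
#' Row-binds the per-batch cell factors into one cells x d matrix; the
#' simplex rows are the integrated cell embedding.
#'
#' @param model a `tri_factor` model.
#' @return matrix with attribute `"batch"` (per-row batch label) and
#'   rownames from the dataset's cell ids.
#' @export
cell_embedding <- function(model) {
  emb <- do.call(rbind, model$cell_factors)
  batches <- rep(names(model$cell_factors),
                 vapply(model$cell_factors, nrow, integer(1)))
  rownames(emb) <- unlist(lapply(names(model$cell_factors), function(b)
    model$data$cell_ids[[b]]), use.names = FALSE)
  attr(emb, "batch") <- batches
  emb
}
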