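# fixture builders shared across test files; everything is generated in code

# rank-d data with planted simplex factors and non-negative association
make_planted <- function(n = 60, p = 30, d = 4, seed = 1, scale = 10) {
  set.seed(seed)
  C <- softmax_rows(matrix(rnorm(n * d, sd = 2), n, d))
  Cf <- softmax_rows(matrix(rnorm(p * d, sd = 2), p, d))
  S <- diag(runif(d, 1, 2))
  X <- scale * C %*% S %*% t(Cf)
  list(X = X, C = C, Cf = Cf, S = S)
}

# tiny two-batch, two-modality mosaic of small counts
make_toy_dataset <- function(seed = 1, n1 = 8, n2 = 6, pg = 5, pr = 7) {
  set.seed(seed)
  mk <- function(n, p, pre) {
    m <- matrix(rpois(n * p, 3), n, p)
    m
  }
  mosaic_dataset(list(
    b1 = list(rna = mk(n1, pg), atac = (mk(n1, pr, "r") > 2) + 0),
    b2 = list(rna = mk(n2, pg))))
}

# hand-assembled model object for closed-form / loss oracle tests
make_manual_model <- function(n = 5, p = 4, d = 3, seed = 42,
                              zero_bias = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  data <- mosaic_dataset(list(b1 = list(rna = X)))
  k <- "b1:rna"
  model <- structure(list(
    cell_factors = list(b1 = softmax_rows(matrix(rnorm(n * d), n, d))),
    feature_factors = list(rna = softmax_rows(matrix(rnorm(p * d), p, d))),
    sigma_shared = matrix(runif(d * d), d, d),
    sigma_specific = stats::setNames(list(matrix(runif(d * d, 0, 0.5), d, d)), k),
    cell_bias = stats::setNames(list(if (zero_bias) numeric(n) else rnorm(n)), k),
    feature_bias = stats::setNames(list(if (zero_bias) numeric(p) else rnorm(p)), k),
    alpha = stats::setNames(1.3, k),
    lambda_reg = 0.001, d = d,
    slots = data.frame(batch = "b1", modality = "rna",
                       provenance = "observed"),
    data = data), class = "tri_factor")
  model
}

# naive double-loop loss oracle (independent of the vectorized path)
naive_loss <- function(model, data = model$data) {
  tot <- 0
  for (i in seq_len(nrow(model$slots))) {
    b <- model$slots$batch[i]; m <- model$slots$modality[i]
    k <- paste(b, m, sep = ":")
    X <- as.matrix(mosaic_matrix(data, b, m))
    C <- model$cell_factors[[b]]; Cf <- model$feature_factors[[m]]
    M <- model$sigma_shared + model$sigma_specific[[k]]
    for (r in seq_len(nrow(X))) for (cc in seq_len(ncol(X))) {
      rec <- 0
      for (u in seq_len(ncol(C))) for (v in seq_len(ncol(Cf)))
        rec <- rec + C[r, u] * M[u, v] * Cf[cc, v]
      rec <- model$alpha[[k]] * rec + model$cell_bias[[k]][r] +
        model$feature_bias[[k]][cc]
      tot <- tot + (X[r, cc] - rec)^2
    }
    tot <- tot + model$lambda_reg * sum(model$sigma_specific[[k]]^2)
  }
  tot
}
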