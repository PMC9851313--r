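# Prediction heads and losses: multi-label adverse-effect classifier,
# conic feed-forward synergy regressor with a stop-gradient on its
# adverse-effect input, and the alpha-weighted total loss.

#' Adverse-effect probability scores for a drug pair
#'
#' Linear decoder on the concatenation `[z_i_drug, z_i_chem, z_j_drug,
#' z_j_chem]` followed by an elementwise logistic, giving one occurrence
#' probability per adverse-effect label. The concatenation is
#' order-sensitive; symmetry is handled downstream by averaging both
#' orderings.
#'
#' @param z_i,z_j integrated drug embeddings (matrices, one row per sample,
#'   each row `[z_drug || z_chem]`)
#' @param W_ae decoder weight matrix (2*ncol(z_i) x n_ae)
#' @param b_ae bias (1 x n_ae)
#' @return matrix of probabilities in (0,1), one row per sample
#' @export
predict_ae <- function(z_i, z_j, W_ae, b_ae = NULL) {
  z_i <- rbind(z_i); z_j <- rbind(z_j)
  x <- cbind(z_i, z_j)
  if (ncol(x) != nrow(W_ae)) {
    stop("predict_ae: input width ", ncol(x), " does not match decoder rows ",
         nrow(W_ae))
  }
  lin <- x %*% W_ae
  if (!is.null(b_ae)) lin <- sweep(lin, 2L, as.numeric(b_ae), "+")
  1 / (1 + exp(-lin))
}

#' Binary cross-entropy loss
#'
#' Global mean of the elementwise binary cross-entropy, with predictions
#' clamped to `[eps, 1 - eps]` before the logs.
#'
#' @param preds probabilities in (0,1)
#' @param labels matching 0/1 labels
#' @param eps clamping constant
#' @return scalar loss
#' @export
bce_loss <- function(preds, labels, eps = 1e-7) {
  preds <- as.numeric(preds); labels <- as.numeric(labels)
  stopifnot(length(preds) == length(labels), length(preds) > 0)
  if (!all(labels %in% c(0, 1))) stop("bce_loss: labels must be 0/1")
  x <- pmin(pmax(preds, eps), 1 - eps)
  mean(-(labels * log(x) + (1 - labels) * log(1 - x)))
}

#' Mean squared error loss
#'
#' @param preds,targets equal-length numeric vectors
#' @return scalar mean of squared differences
#' @export
mse_loss <- function(preds, targets) {
  preds <- as.numeric(preds); targets <- as.numeric(targets)
  if (!length(preds)) stop("mse_loss: empty input")
  stopifnot(length(preds) == length(targets))
  mean((preds - targets)^2)
}

#' Combined multi-task loss
#'
#' `alpha * l_mse + (1 - alpha) * l_bce`. With `alpha = 1` this recovers
#' single-task synergy training; the ratio `R = alpha / (1 - alpha)` is the
#' scale on which the weight is usually searched.
#'
#' @param l_mse,l_bce scalar losses
#' @param alpha weight in [0, 1]
#' @return scalar total loss
#' @export
total_loss <- function(l_mse, l_bce, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("total_loss: alpha must lie in [0, 1]")
  }
  alpha * l_mse + (1 - alpha) * l_bce
}

#' Convert a loss-weight ratio R to alpha
#'
#' @param R ratio `alpha / (1 - alpha)`, > 0
#' @return alpha in (0, 1)
#' @export
ratio_to_alpha <- function(R) {
  stopifnot(R > 0)
  R / (1 + R)
}

#' Conic feed-forward widths
#'
#' Each hidden layer has half the units of its predecessor.
#' @param base_width first hidden width
#' @param depth number of hidden layers
#' @return integer vector of widths
#' @export
conic_widths <- function(base_width, depth) {
  w <- base_width / 2^(seq_len(depth) - 1L)
  if (any(w < 1)) stop("conic_widths: width underflow; reduce depth")
  as.integer(w)
}

# conic DNN forward over an autograd input node; dropout only when training
.dnn_nodes <- function(x, dnn, dropout = 0, training = FALSE) {
  h <- x
  for (i in seq_along(dnn$W_hidden)) {
    h <- ag_relu(ag_add(ag_matmul(h, dnn$W_hidden[[i]]), dnn$b_hidden[[i]]))
    if (training && dropout > 0) h <- ag_dropout(h, dropout)
  }
  ag_add(ag_matmul(h, dnn$W_out), dnn$b_out)
}

#' Synergy score prediction for drug-drug-cell-line samples
#'
#' Conic feed-forward regressor on the concatenation of the two integrated
#' drug embeddings, the cell-line embedding and (optionally) the
#' adverse-effect probability vector, which is treated as a constant so no
#' gradient flows back into the adverse-effect head through this input.
#'
#' @param z_i,z_j integrated drug embeddings (rows = samples)
#' @param z_cell cell-line embeddings (rows = samples)
#' @param p_ae adverse-effect probabilities (rows = samples), or NULL to
#'   omit the input block entirely
#' @param dnn conic network parameters from [init_params()], plain matrices
#' @return numeric vector, one synergy prediction per sample
#' @export
predict_te <- function(z_i, z_j, z_cell, p_ae, dnn) {
  x <- cbind(rbind(z_i), rbind(z_j), rbind(z_cell))
  if (!is.null(p_ae)) x <- cbind(x, rbind(p_ae))
  if (ncol(x) != nrow(ag_value(dnn$W_hidden[[1]]))) {
    stop("predict_te: input width ", ncol(x), " does not match network input ",
         nrow(ag_value(dnn$W_hidden[[1]])))
  }
  dnn_plain <- rapply(dnn, ag_value, classes = "ANY", how = "replace")
  h <- x
  for (i in seq_along(dnn_plain$W_hidden)) {
    h <- pmax(sweep(h %*% dnn_plain$W_hidden[[i]], 2L,
                    as.numeric(dnn_plain$b_hidden[[i]]), "+"), 0)
  }
  out <- sweep(h %*% dnn_plain$W_out, 2L, as.numeric(dnn_plain$b_out), "+")
  as.numeric(out)
}
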