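# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is a 2-D double matrix wrapped in an environment node that
# records its parents and a closure computing parent gradients from its own.
# A forward pass builds the tape implicitly; ag_backward() topologically
# sorts the tape and accumulates gradients into the leaves.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L
.ag_counter$grad_enabled <- TRUE

#' Evaluate an expression without recording the gradient tape
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag_counter$grad_enabled
  .ag_counter$grad_enabled <- FALSE
  on.exit(.ag_counter$grad_enabled <- old)
  force(expr)
}

# monotone counter issuing per-backward visit tokens
ag_next_id <- function() {
  .ag_counter$n <- .ag_counter$n + 1L
  .ag_counter$n
}

#' Create an autograd tensor node
#'
#' @param value numeric matrix (vectors are promoted to 1-row matrices)
#' @param parents list of parent nodes this value was computed from
#' @param backfn function(grad) returning a list of gradients, one per parent
#' @param leaf logical; leaf nodes receive accumulated gradients
#' @keywords internal
ag_node <- function(value, parents = list(), backfn = NULL, leaf = FALSE) {
  if (!is.matrix(value)) value <- matrix(as.numeric(value), nrow = 1L)
  e <- new.env(parent = emptyenv())
  e$value <- value
  if (!leaf && !.ag_counter$grad_enabled) {
    parents <- list()
    backfn <- NULL
  }
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$leaf <- leaf
  class(e) <- "ag_tensor"
  e
}

#' @keywords internal
ag_param <- function(value) ag_node(value, leaf = TRUE)

#' @keywords internal
ag_const <- function(value) ag_node(value, leaf = FALSE)

ag_is <- function(x) inherits(x, "ag_tensor")

ag_wrap <- function(x) if (ag_is(x)) x else ag_const(x)

#' @keywords internal
ag_value <- function(x) if (ag_is(x)) x$value else x

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

#' Run backpropagation from a scalar loss node
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(ag_is(loss), length(loss$value) == 1L)
  # iterative post-order DFS for topological order; visited nodes are
  # marked in place with a per-call token (no keyed lookup structures)
  token <- .ag_counter$n + 1L
  .ag_counter$n <- token
  topo <- vector("list", 256L)
  ntopo <- 0L
  stack <- list(list(node = loss, i = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i == 0L && identical(node$visit, token)) {
      stack[[length(stack)]] <- NULL
      next
    }
    node$visit <- token
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      if (!identical(p$visit, token)) {
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  loss$grad <- matrix(1, 1L, 1L)
  for (k in seq(ntopo, 1L)) {
    node <- topo[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) ag_accum(node$parents[[j]], gs[[j]])
    }
  }
  invisible(loss)
}

#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- primitive operations ----------------------------------------------

ag_matmul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  ag_node(a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

# elementwise add; b may be a 1-row bias broadcast over rows of a
ag_add <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  av <- a$value; bv <- b$value
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, as.numeric(bv), "+")
    ag_node(val, list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    ag_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

ag_sub <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  stopifnot(all(dim(a$value) == dim(b$value)))
  ag_node(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

# multiply matrix rows by a column vector of per-row weights
ag_mul_cols <- function(col, mat) {
  col <- ag_wrap(col); mat <- ag_wrap(mat)
  stopifnot(ncol(col$value) == 1L, nrow(col$value) == nrow(mat$value))
  cv <- as.numeric(col$value)
  ag_node(mat$value * cv, list(col, mat), function(g) {
    list(matrix(rowSums(g * mat$value), ncol = 1L), g * cv)
  })
}

# multiply a whole node by a scalar node (1x1)
ag_scale <- function(a, s) {
  a <- ag_wrap(a); s <- ag_wrap(s)
  stopifnot(length(s$value) == 1L)
  sv <- as.numeric(s$value)
  ag_node(a$value * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * a$value), 1L, 1L))
  })
}

ag_scale_const <- function(a, k) {
  a <- ag_wrap(a)
  ag_node(a$value * k, list(a), function(g) list(g * k))
}

ag_sigmoid <- function(a) {
  a <- ag_wrap(a)
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  a <- ag_wrap(a)
  tv <- tanh(a$value)
  ag_node(tv, list(a), function(g) list(g * (1 - tv^2)))
}

ag_relu <- function(a) {
  a <- ag_wrap(a)
  m <- a$value > 0
  ag_node(a$value * m, list(a), function(g) list(g * m))
}

ag_leaky_relu <- function(a, slope = 0.01) {
  a <- ag_wrap(a)
  m <- ifelse(a$value > 0, 1, slope)
  ag_node(a$value * m, list(a), function(g) list(g * m))
}

ag_elu <- function(a, alpha = 1) {
  a <- ag_wrap(a)
  pos <- a$value > 0
  ev <- ifelse(pos, a$value, alpha * (exp(a$value) - 1))
  ag_node(ev, list(a), function(g) list(g * ifelse(pos, 1, ev + alpha)))
}

ag_activation <- function(a, name, slope = 0.01) {
  switch(name,
    relu = ag_relu(a),
    elu = ag_elu(a),
    leaky_relu = ag_leaky_relu(a, slope),
    tanh = ag_tanh(a),
    sigmoid = ag_sigmoid(a),
    identity = a,
    stop("unknown activation: ", name)
  )
}

# softmax over the rows of a single-column matrix
ag_softmax_col <- function(a) {
  a <- ag_wrap(a)
  stopifnot(ncol(a$value) == 1L)
  z <- a$value - max(a$value)
  s <- exp(z) / sum(exp(z))
  ag_node(s, list(a), function(g) {
    list(s * (g - sum(g * s)))
  })
}

# segmented softmax: softmax within each group of rows (single-column input)
ag_softmax_group <- function(a, group) {
  a <- ag_wrap(a)
  stopifnot(ncol(a$value) == 1L, length(group) == nrow(a$value))
  gf <- as.integer(factor(group))
  mx <- tapply(as.numeric(a$value), gf, max)[gf]
  ez <- exp(as.numeric(a$value) - mx)
  denom <- as.numeric(rowsum(ez, gf))[gf]
  s <- matrix(ez / denom, ncol = 1L)
  ag_node(s, list(a), function(g) {
    dot <- as.numeric(rowsum(as.numeric(g) * as.numeric(s), gf))[gf]
    list(s * (as.numeric(g) - dot))
  })
}

# per-group row sums: output has one row per group (groups ordered by first level)
ag_group_sum <- function(a, group, ngroups) {
  a <- ag_wrap(a)
  gf <- factor(group, levels = seq_len(ngroups))
  stopifnot(!anyNA(gf))
  val <- rowsum(a$value, gf)
  ag_node(val, list(a), function(g) {
    list(g[as.integer(gf), , drop = FALSE])
  })
}

ag_cbind <- function(nodes) {
  nodes <- lapply(nodes, ag_wrap)
  widths <- vapply(nodes, function(n) ncol(n$value), 1L)
  val <- do.call(cbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(val, nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ag_rbind <- function(nodes) {
  nodes <- lapply(nodes, ag_wrap)
  hts <- vapply(nodes, function(n) nrow(n$value), 1L)
  val <- do.call(rbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(hts)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(val, nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

# gather rows by index (duplicates allowed; gradients accumulate)
ag_rows <- function(a, idx) {
  a <- ag_wrap(a)
  idx <- as.integer(idx)
  nr <- nrow(a$value)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ag_mean_rows <- function(a) {
  a <- ag_wrap(a)
  n <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1L), list(a), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), nrow = n))
  })
}

ag_mean <- function(a) {
  a <- ag_wrap(a)
  n <- length(a$value)
  ag_node(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / n, nrow(a$value), ncol(a$value)))
  })
}

ag_sum <- function(a) {
  a <- ag_wrap(a)
  ag_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(a$value), ncol(a$value)))
  })
}

# detach: value flows forward, gradient is cut (stop-gradient)
ag_detach <- function(a) {
  ag_const(ag_value(a))
}

# inverted dropout; mask drawn from the current RNG stream
ag_dropout <- function(a, p) {
  if (p <= 0) return(ag_wrap(a))
  a <- ag_wrap(a)
  keep <- matrix(stats::runif(length(a$value)) >= p, nrow(a$value))
  scale <- 1 / (1 - p)
  ag_node(a$value * keep * scale, list(a), function(g) list(g * keep * scale))
}

# mean squared error against a constant target
ag_mse <- function(pred, target) {
  pred <- ag_wrap(pred)
  tv <- ag_value(target)
  n <- length(tv)
  stopifnot(n > 0L, length(pred$value) == n)
  d <- pred$value - tv
  ag_node(matrix(mean(d^2), 1L, 1L), list(pred), function(g) {
    list(as.numeric(g) * 2 * d / n)
  })
}

# binary cross-entropy against constant 0/1 labels, probabilities clamped
ag_bce <- function(pred, labels, eps = 1e-7) {
  pred <- ag_wrap(pred)
  y <- ag_value(labels)
  n <- length(y)
  stopifnot(length(pred$value) == n)
  x <- pmin(pmax(pred$value, eps), 1 - eps)
  inside <- pred$value > eps & pred$value < 1 - eps
  val <- mean(-(y * log(x) + (1 - y) * log(1 - x)))
  ag_node(matrix(val, 1L, 1L), list(pred), function(g) {
    list(as.numeric(g) * inside * ((1 - y) / (1 - x) - y / x) / n)
  })
}

# ---- optimizer ----------------------------------------------------------

#' Adam optimizer state
#'
#' Parameters whose gradient is entirely zero (or absent) in a step are left
#' untouched, so unused heads stay bit-identical to their initialization.
#' @keywords internal
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$m <- lapply(params, function(p) matrix(0, nrow(p$value), ncol(p$value)))
  st$v <- lapply(params, function(p) matrix(0, nrow(p$value), ncol(p$value)))
  st$t <- rep(0L, length(params))
  st
}

#' @keywords internal
adam_step <- function(st) {
  for (j in seq_along(st$params)) {
    p <- st$params[[j]]
    g <- p$grad
    if (is.null(g) || all(g == 0)) next
    if (st$wd > 0) g <- g + st$wd * p$value
    st$t[j] <- st$t[j] + 1L
    st$m[[j]] <- st$beta1 * st$m[[j]] + (1 - st$beta1) * g
    st$v[[j]] <- st$beta2 * st$v[[j]] + (1 - st$beta2) * g^2
    mh <- st$m[[j]] / (1 - st$beta1^st$t[j])
    vh <- st$v[[j]] / (1 - st$beta2^st$t[j])
    p$value <- p$value - st$lr * mh / (sqrt(vh) + st$eps)
  }
  invisible(st)
}
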