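# Drug encoder: per-schema sequence aggregation of meta-path instances
# (BiGRU / GRU / mean), attention-weighted instance aggregation (GAT-style,
# multi-head), and the semantic attention combiner that fuses the four
# meta-path-specific embeddings into one drug embedding.

# one GRU direction over a list of per-position feature nodes (each N x d');
# returns list of states after each processed position, in processing order
.gru_direction <- function(xs, prm, reverse = FALSE) {
  n <- nrow(ag_value(xs[[1]]))
  H <- ncol(ag_value(prm$U_z))
  h <- ag_const(matrix(0, n, H))
  order_p <- if (reverse) rev(seq_along(xs)) else seq_along(xs)
  states <- vector("list", length(xs))
  for (p in order_p) {
    x <- xs[[p]]
    z <- ag_sigmoid(ag_add(ag_add(ag_matmul(x, prm$W_z),
                                  ag_matmul(h, prm$U_z)), prm$b_z))
    r <- ag_sigmoid(ag_add(ag_add(ag_matmul(x, prm$W_r),
                                  ag_matmul(h, prm$U_r)), prm$b_r))
    ht <- ag_tanh(ag_add(ag_add(ag_matmul(x, prm$W_h),
                                ag_matmul(ag_mul(r, h), prm$U_h)), prm$b_h))
    h <- ag_add(ag_mul(ag_one_minus(z), h), ag_mul(z, ht))
    states[[p]] <- h
  }
  states
}

ag_one_minus <- function(a) {
  a <- ag_wrap(a)
  ag_node(1 - a$value, list(a), function(g) list(-g))
}

# sequence aggregation over per-position feature nodes; returns
# list(h_f, h_l) as autograd nodes (N x dim)
.aggregate_nodes <- function(xs, sprm, aggregator) {
  L <- length(xs)
  switch(aggregator,
    bigru = {
      fw <- .gru_direction(xs, sprm$fwd, reverse = FALSE)
      bw <- .gru_direction(xs, sprm$bwd, reverse = TRUE)
      # h_f: final hidden state of each direction; h_l: per-position output
      # at the central-node (last) position
      list(h_f = ag_cbind(list(fw[[L]], bw[[1L]])),
           h_l = ag_cbind(list(fw[[L]], bw[[L]])))
    },
    gru = {
      fw <- .gru_direction(xs, sprm$fwd, reverse = FALSE)
      list(h_f = fw[[L]], h_l = fw[[L]])
    },
    mean = {
      acc <- xs[[1L]]
      if (L > 1L) for (p in 2:L) acc <- ag_add(acc, xs[[p]])
      list(h_f = ag_scale_const(acc, 1 / L), h_l = xs[[L]])
    },
    stop("unknown aggregator: ", aggregator)
  )
}

#' Aggregate a drug's meta-path instances into per-instance representations
#'
#' Runs the schema's sequence aggregator over an instance feature tensor.
#' For the bidirectional GRU, `h_f` concatenates the final hidden states of
#' the forward and backward passes (the whole-instance representation) and
#' `h_l` is the per-position output at the final, central-node position (the
#' central node's contextual representation). The unidirectional GRU uses
#' its final state for both; the mean aggregator uses the position-wise mean
#' (`h_f`) and the central node's own transformed feature (`h_l`).
#'
#' @param tensor 3-D array (instance, position, feature) from [tensorize()]
#' @param sprm schema-specific aggregator parameters (see [init_params()])
#' @param aggregator one of "bigru", "gru", "mean"
#' @return list with numeric matrices `h_f` and `h_l`, one row per instance
#' @export
aggregate_instances <- function(tensor, sprm, aggregator = "bigru") {
  if (dim(tensor)[1] == 0L) {
    stop("aggregate_instances: no instances; substitute the null embedding")
  }
  xs <- lapply(seq_len(dim(tensor)[2]), function(p) {
    ag_const(matrix(tensor[, p, ], nrow = dim(tensor)[1]))
  })
  out <- .aggregate_nodes(xs, sprm, aggregator)
  list(h_f = ag_value(out$h_f), h_l = ag_value(out$h_l))
}

# GAT-style attention over instances, vectorized across central drugs via
# the `group` vector; returns node (n_present_groups x K*d_head) plus the
# attention weights and group ids
.gat_nodes <- function(h_l, h_f, group, sprm, config) {
  present <- sort(unique(group))
  gidx <- match(group, present)
  logit <- ag_leaky_relu(
    ag_matmul(ag_cbind(list(h_l, h_f)), sprm$a_m),
    slope = config$leaky_slope
  )
  alpha <- ag_softmax_group(logit, gidx)
  heads <- lapply(seq_len(config$K), function(k) {
    proj <- ag_matmul(h_f, sprm$W_head[[k]])
    ag_activation(ag_group_sum(ag_mul_cols(alpha, proj), gidx,
                               length(present)),
                  config$act_head)
  })
  list(emb = ag_cbind(heads), alpha = alpha, present = present)
}

#' Extract a meta-path-specific embedding via instance attention
#'
#' Computes one attention logit per instance from the concatenation
#' `[h_l || h_f]`, softmax-normalizes over the central drug's instances (its
#' meta-path-based neighbors), and aggregates per-head projections of `h_f`
#' with those weights; the K head outputs are concatenated.
#'
#' @param agg list with matrices `h_f`, `h_l` from [aggregate_instances()]
#' @param sprm schema parameters holding `a_m` and `W_head`
#' @param config a [hetsyn_config()]
#' @return list with `embedding` (1 x K*d_head) and `alpha` (instance weights)
#' @export
gat_extract <- function(agg, sprm, config = hetsyn_config()) {
  n <- nrow(agg$h_f)
  if (n < 1L) stop("gat_extract: at least one instance required")
  out <- .gat_nodes(ag_const(agg$h_l), ag_const(agg$h_f),
                    rep(1L, n), sprm, config)
  list(embedding = ag_value(out$emb), alpha = as.numeric(ag_value(out$alpha)))
}

# semantic attention combiner over the four schema embeddings; inputs are
# nodes (n_drugs x D) keyed by schema name; returns list(h_t, z, beta)
.combine_nodes <- function(emb_nodes, prm, config) {
  miss <- setdiff(SCHEMA_NAMES, names(emb_nodes))
  if (length(miss)) {
    stop("combine_metapaths: missing schema embedding(s): ",
         paste(miss, collapse = ", "))
  }
  omegas <- lapply(SCHEMA_NAMES, function(s) {
    sc <- ag_matmul(ag_tanh(ag_add(ag_matmul(emb_nodes[[s]], prm$W_att),
                                   prm$b_att)), prm$q_att)
    ag_mean(sc)
  })
  beta <- ag_softmax_col(ag_rbind(omegas))
  h_t <- NULL
  for (m in seq_along(SCHEMA_NAMES)) {
    term <- ag_scale(emb_nodes[[SCHEMA_NAMES[m]]], ag_rows(beta, m))
    h_t <- if (is.null(h_t)) term else ag_add(h_t, term)
  }
  z <- ag_activation(ag_matmul(h_t, prm$W_P), config$act_proj)
  list(h_t = h_t, z = z, beta = beta)
}

#' Fuse the four meta-path-specific embeddings into drug embeddings
#'
#' Type-level semantic attention: each schema receives an importance weight
#' (mean over drug nodes of an attended tanh transform), the weights are
#' softmax-normalized over the four schemas, and every drug's summarized
#' embedding is the weighted sum of its schema embeddings followed by a
#' projection nonlinearity. The schema weights are shared across drugs.
#'
#' @param embeddings named list (DTD/DTTD/DTTTD/DD) of numeric matrices,
#'   each n_drugs x D
#' @param prm combiner parameters (`W_att`, `b_att`, `q_att`, `W_P`)
#' @param config a [hetsyn_config()]
#' @return list with `h_t` (n_drugs x D), `z_drug` (n_drugs x d_z) and
#'   `beta` (length-4 schema weights, sums to 1)
#' @export
combine_metapaths <- function(embeddings, prm, config = hetsyn_config()) {
  nodes <- lapply(embeddings, ag_const)
  out <- .combine_nodes(nodes, prm, config)
  list(h_t = ag_value(out$h_t), z_drug = ag_value(out$z),
       beta = as.numeric(ag_value(out$beta)))
}

#' Morgan (ECFP6) fingerprint of a SMILES string
#'
#' Computes the radius-3 Morgan extended-connectivity fingerprint through
#' OpenBabel (via ChemmineOB) and OR-folds the native 4096-bit vector down
#' to `n_bits`. Deterministic for a given SMILES.
#'
#' @param smiles character vector of SMILES
#' @param n_bits folded fingerprint length (power of two up to 4096)
#' @return binary matrix, one row per molecule, `n_bits` columns
#' @export
compute_ecfp6 <- function(smiles, n_bits = 1024) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("compute_ecfp6 requires the ChemmineOB package; ",
         "supply precomputed fingerprints via chem.tsv instead")
  }
  out <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(smiles)) {
    fp <- tryCatch(
      ChemmineOB::fingerprint_OB(
        ChemmineOB::forEachMol("SMILES", smiles[i], identity), "ECFP6"),
      error = function(e) NULL)
    fp <- as.numeric(fp)
    if (!length(fp) || all(fp == 0)) {
      stop("compute_ecfp6: could not parse SMILES for molecule ", i,
           ": '", smiles[i], "'")
    }
    on_bits <- which(fp != 0) - 1L
    folded <- unique(on_bits %% n_bits) + 1L
    out[i, folded] <- 1L
  }
  out
}
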