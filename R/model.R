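# Model assembly: configuration, parameter initialization, and the
# end-to-end differentiable forward pass over a batch of
# drug-drug-cell-line samples.

#' Model and training configuration
#'
#' @param d_prime shared node feature dimension after the type-specific
#'   transformation
#' @param hidden GRU hidden size per direction
#' @param K number of attention heads in the instance extractor
#' @param d_head per-head output dimension (drug embedding dim = K * d_head)
#' @param d_att attention dimension of the meta-path combiner
#' @param d_z final meta-path embedding dimension
#' @param d_cell cell-line embedding dimension
#' @param n_bits chemical fingerprint length
#' @param aggregator "bigru" (default), "gru" or "mean"
#' @param act_head activation on attention-aggregated head outputs
#' @param act_proj activation on the final embedding projection
#' @param leaky_slope negative slope of the attention-logit LeakyReLU
#' @param dnn_base_width first hidden width of the conic synergy network
#' @param dnn_depth number of conic hidden layers
#' @param dropout dropout probability on conic hidden layers (training only)
#' @param n_ae number of adverse-effect labels
#' @param alpha weight of the synergy MSE in the total loss (1 - alpha on
#'   the adverse-effect BCE); `use_ae_input`/`use_ae_loss` are derived from
#'   it unless set explicitly
#' @param use_ae_input feed the (gradient-stopped) adverse-effect
#'   probabilities to the synergy network
#' @param dd_threshold synergy-score threshold for drug-drug edges (strict)
#' @param dtttd_ratio uniform sampling ratio for restricted DTTTD instances
#' @param score_type synergy score column used as the regression target
#' @param lr,weight_decay,epochs,patience,batch_size optimizer settings;
#'   `batch_size = NULL` trains full-batch
#' @param allow_self_instances include meta-path instances whose start and
#'   end drug coincide
#' @return list of class `hetsyn_config`
#' @export
hetsyn_config <- function(d_prime = 64, hidden = 64, K = 8, d_head = 8,
                          d_att = 32, d_z = K * d_head, d_cell = 32,
                          n_bits = 1024, aggregator = "bigru",
                          act_head = "elu", act_proj = "relu",
                          leaky_slope = 0.01,
                          dnn_base_width = 2048, dnn_depth = 3,
                          dropout = 0.5, n_ae = 20, alpha = 0.5,
                          use_ae_input = NULL, dd_threshold = 0,
                          dtttd_ratio = 0.5, score_type = "loewe",
                          lr = 1e-3, weight_decay = 1e-5, epochs = 100,
                          patience = 20, batch_size = NULL,
                          allow_self_instances = FALSE) {
  aggregator <- match.arg(aggregator, c("bigru", "gru", "mean"))
  if (alpha < 0 || alpha > 1) stop("hetsyn_config: alpha must lie in [0,1]")
  if (is.null(use_ae_input)) use_ae_input <- alpha < 1
  structure(as.list(environment()), class = "hetsyn_config")
}

# dimensionality of h_f / h_l for a given aggregator
.agg_dim <- function(config) {
  switch(config$aggregator,
    bigru = 2L * config$hidden,
    gru = config$hidden,
    mean = config$d_prime
  )
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.gru_param_set <- function(d_in, H) {
  list(W_z = ag_param(.glorot(d_in, H)), U_z = ag_param(.glorot(H, H)),
       b_z = ag_param(matrix(0, 1, H)),
       W_r = ag_param(.glorot(d_in, H)), U_r = ag_param(.glorot(H, H)),
       b_r = ag_param(matrix(0, 1, H)),
       W_h = ag_param(.glorot(d_in, H)), U_h = ag_param(.glorot(H, H)),
       b_h = ag_param(matrix(0, 1, H)))
}

#' Initialize all trainable parameters
#'
#' @param n_drugs,n_targets,n_genes vocabulary sizes
#' @param config a [hetsyn_config()]
#' @param seed integer seed for the (Glorot-uniform) initialization
#' @return list of class `hetsyn_params`
#' @export
init_params <- function(n_drugs, n_targets, n_genes,
                        config = hetsyn_config(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    dp <- config$d_prime
    H <- config$hidden
    Dm <- config$K * config$d_head
    adim <- .agg_dim(config)

    schemas <- lapply(stats::setNames(SCHEMA_NAMES, SCHEMA_NAMES), function(s) {
      sp <- list(
        a_m = ag_param(.glorot(2L * adim, 1L)),
        W_head = lapply(seq_len(config$K),
                        function(k) ag_param(.glorot(adim, config$d_head))),
        null_emb = ag_param(matrix(stats::rnorm(Dm, sd = 0.1), 1, Dm))
      )
      if (config$aggregator %in% c("bigru", "gru")) {
        sp$fwd <- .gru_param_set(dp, H)
      }
      if (config$aggregator == "bigru") sp$bwd <- .gru_param_set(dp, H)
      sp
    })

    dnn_in <- 2L * (config$d_z + config$n_bits) + config$d_cell +
      if (config$use_ae_input) config$n_ae else 0L
    widths <- conic_widths(config$dnn_base_width, config$dnn_depth)
    ins <- c(dnn_in, widths[-length(widths)])
    dnn <- list(
      W_hidden = lapply(seq_along(widths),
                        function(i) ag_param(.glorot(ins[i], widths[i]))),
      b_hidden = lapply(widths, function(w) ag_param(matrix(0, 1, w))),
      W_out = ag_param(.glorot(widths[length(widths)], 1L)),
      b_out = ag_param(matrix(0, 1, 1))
    )

    structure(list(
      type_transform = list(D = ag_param(.glorot(n_drugs, dp)),
                            T = ag_param(.glorot(n_targets, dp))),
      schemas = schemas,
      combiner = list(W_att = ag_param(.glorot(Dm, config$d_att)),
                      b_att = ag_param(matrix(0, 1, config$d_att)),
                      q_att = ag_param(.glorot(config$d_att, 1L)),
                      W_P = ag_param(.glorot(Dm, config$d_z))),
      cell = list(W = ag_param(.glorot(n_genes, config$d_cell)),
                  b = ag_param(matrix(0, 1, config$d_cell))),
      ae = list(W = ag_param(.glorot(2L * (config$d_z + config$n_bits),
                                     config$n_ae)),
                b = ag_param(matrix(0, 1, config$n_ae))),
      dnn = dnn,
      config = config
    ), class = "hetsyn_params")
  })
}

#' Flatten a parameter object into a named list of leaf tensors
#' @keywords internal
param_list <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    if (ag_is(x)) {
      out[[prefix]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      for (i in seq_along(x)) walk(x[[i]], paste(prefix, nms[i], sep = "."))
    }
  }
  walk(params[setdiff(names(params), "config")], "p")
  out
}

#' Encode all drugs of the network (differentiable)
#'
#' Runs the aggregator + attention extractor per schema over the instance
#' index, substitutes the learned per-schema null embedding for drugs
#' without instances, and fuses the four schema embeddings via the
#' semantic-attention combiner.
#'
#' @param params `hetsyn_params`
#' @param inst_index from [build_instance_index()]
#' @param n_drugs number of drugs
#' @return list with autograd nodes `z_drug` (n_drugs x d_z) and `beta`
#' @keywords internal
encode_drugs_node <- function(params, inst_index, n_drugs) {
  config <- params$config
  Dm <- config$K * config$d_head
  emb_nodes <- list()
  for (s in SCHEMA_NAMES) {
    idx <- inst_index[[s]]
    sprm <- params$schemas[[s]]
    if (nrow(idx$nodes) == 0L) {
      # no drug has instances of this schema: every row is the null embedding
      emb_nodes[[s]] <- ag_rows(sprm$null_emb, rep(1L, n_drugs))
      next
    }
    types <- idx$schema$node_types
    xs <- lapply(seq_along(types), function(p) {
      w <- if (types[p] == "D") params$type_transform$D else params$type_transform$T
      ag_rows(w, idx$nodes[, p])
    })
    agg <- .aggregate_nodes(xs, sprm, config$aggregator)
    gat <- .gat_nodes(agg$h_l, agg$h_f, idx$group, sprm, config)
    # scatter present-drug rows into the full drug table, null elsewhere
    stacked <- ag_rbind(list(gat$emb, sprm$null_emb))
    pick <- match(seq_len(n_drugs), gat$present,
                  nomatch = length(gat$present) + 1L)
    emb_nodes[[s]] <- ag_rows(stacked, pick)
  }
  comb <- .combine_nodes(emb_nodes, params$combiner, config)
  list(z_drug = comb$z, beta = comb$beta, schema_emb = emb_nodes)
}

#' Differentiable forward pass over a batch of triples
#'
#' @param params `hetsyn_params`
#' @param inst_index instance index for the current network
#' @param chem constant fingerprint matrix (n_drugs x n_bits)
#' @param expr constant expression matrix (n_cells x n_genes)
#' @param triples data.frame with drug_a, drug_b, cell_line
#' @param ae_labels 0/1 matrix (rows match triples) or NULL
#' @param training logical; enables dropout
#' @return list of autograd nodes: `pred` (synergy), `p_ae`, plus `z_int`
#' @keywords internal
forward_batch <- function(params, inst_index, chem, expr, triples,
                          ae_labels = NULL, training = FALSE) {
  config <- params$config
  n_drugs <- nrow(chem)
  enc <- encode_drugs_node(params, inst_index, n_drugs)
  z_int <- ag_cbind(list(enc$z_drug, ag_const(chem)))
  z_cell_all <- ag_add(ag_matmul(ag_const(expr), params$cell$W),
                       params$cell$b)
  zi <- ag_rows(z_int, triples$drug_a)
  zj <- ag_rows(z_int, triples$drug_b)
  zc <- ag_rows(z_cell_all, triples$cell_line)
  p_ae <- ag_sigmoid(ag_add(ag_matmul(ag_cbind(list(zi, zj)), params$ae$W),
                            params$ae$b))
  blocks <- list(zi, zj, zc)
  if (config$use_ae_input) blocks <- c(blocks, list(ag_detach(p_ae)))
  pred <- .dnn_nodes(ag_cbind(blocks), params$dnn,
                     dropout = config$dropout, training = training)
  list(pred = pred, p_ae = p_ae, z_int = z_int, beta = enc$beta)
}

#' Plain-numeric synergy predictions for triples (no gradient tape kept)
#'
#' @inheritParams forward_batch
#' @return numeric vector of predictions in triple order
#' @keywords internal
predict_triples <- function(params, inst_index, chem, expr, triples) {
  ag_no_grad({
    out <- forward_batch(params, inst_index, chem, expr, triples,
                         training = FALSE)
    as.numeric(ag_value(out$pred))
  })
}
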