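# Shared fixtures: random small networks, a brute-force all-tuples
# meta-path oracle, and a desk-scale model configuration.

# random heterogeneous network built through build_hetnet(); DD edges are
# realized by a synthetic synergy table scoring wanted pairs above 0
random_hetnet <- function(seed, n_drugs = 8, n_targets = 12, p = 0.3) {
  withr::with_seed(seed, {
    dti <- which(matrix(runif(n_drugs * n_targets) < p, n_drugs), arr.ind = TRUE)
    dti <- data.frame(drug = as.integer(dti[, 1]), target = as.integer(dti[, 2]))
    if (!nrow(dti)) dti <- data.frame(drug = 1L, target = 1L)
    pp <- which(upper.tri(matrix(0, n_targets, n_targets)) &
                  matrix(runif(n_targets^2) < p, n_targets), arr.ind = TRUE)
    ppi <- data.frame(target_a = as.integer(pp[, 1]), target_b = as.integer(pp[, 2]))
    dd <- which(upper.tri(matrix(0, n_drugs, n_drugs)) &
                  matrix(runif(n_drugs^2) < p, n_drugs), arr.ind = TRUE)
    synergy <- data.frame(drug_a = as.integer(dd[, 1]),
                          drug_b = as.integer(dd[, 2]),
                          cell_line = 1L, loewe = 1, bliss = 1, hsa = 1, zip = 1)
    if (!nrow(synergy)) {
      synergy <- data.frame(drug_a = 1L, drug_b = 2L, cell_line = 1L,
                            loewe = -1, bliss = -1, hsa = -1, zip = -1)
    }
    build_hetnet(dti, ppi, synergy, n_drugs, n_targets)
  })
}

# brute force: test every node tuple of the schema's length against the
# edge constraints; returns the lexicographically sorted instance matrix
oracle_instances <- function(net, schema_name, allow_self = FALSE) {
  nd <- net$n_drugs; nt <- net$n_targets
  A_dti <- matrix(FALSE, nd, nt)
  if (nrow(net$dti)) A_dti[net$dti] <- TRUE
  A_ppi <- matrix(FALSE, nt, nt)
  if (nrow(net$ppi)) {
    A_ppi[net$ppi] <- TRUE
    A_ppi[net$ppi[, 2:1, drop = FALSE]] <- TRUE
  }
  A_dd <- matrix(FALSE, nd, nd)
  if (nrow(net$dd)) {
    A_dd[net$dd] <- TRUE
    A_dd[net$dd[, 2:1, drop = FALSE]] <- TRUE
  }
  ds <- seq_len(nd); ts <- seq_len(nt)
  g <- switch(schema_name,
    DD = expand.grid(p1 = ds, p2 = ds),
    DTD = expand.grid(p1 = ds, p2 = ts, p3 = ds),
    DTTD = expand.grid(p1 = ds, p2 = ts, p3 = ts, p4 = ds),
    DTTTD = expand.grid(p1 = ds, p2 = ts, p3 = ts, p4 = ts, p5 = ds))
  keep <- switch(schema_name,
    DD = A_dd[cbind(g$p1, g$p2)],
    DTD = A_dti[cbind(g$p1, g$p2)] & A_dti[cbind(g$p3, g$p2)],
    DTTD = A_dti[cbind(g$p1, g$p2)] & A_ppi[cbind(g$p2, g$p3)] &
      A_dti[cbind(g$p4, g$p3)] & g$p2 != g$p3,
    DTTTD = A_dti[cbind(g$p1, g$p2)] & A_ppi[cbind(g$p2, g$p3)] &
      A_ppi[cbind(g$p3, g$p4)] & A_dti[cbind(g$p5, g$p4)] &
      g$p2 != g$p3 & g$p3 != g$p4 & g$p2 != g$p4)
  if (!allow_self) keep <- keep & g[[1]] != g[[ncol(g)]]
  m <- as.matrix(g[keep, , drop = FALSE])
  dimnames(m) <- NULL
  if (!nrow(m)) return(matrix(integer(0), 0, ncol(g)))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# desk-scale model configuration used by training-based tests
small_config <- function(...) {
  defaults <- list(d_prime = 16, hidden = 16, K = 4, d_head = 4, d_att = 16,
                   d_cell = 8, n_bits = 64, dnn_base_width = 128,
                   dnn_depth = 3, dropout = 0.2, n_ae = 8)
  do.call(hetsyn_config, utils::modifyList(defaults, list(...)))
}

# a minimal handmade network: 3 drugs, 3 targets
tiny_net <- function() {
  build_hetnet(
    dti = data.frame(drug = c(1L, 2L, 1L, 3L), target = c(1L, 1L, 2L, 3L)),
    ppi = data.frame(target_a = c(1L, 2L), target_b = c(2L, 3L)),
    synergy = data.frame(drug_a = c(1L, 2L), drug_b = c(2L, 3L),
                         cell_line = 1L, loewe = c(5, -2), bliss = 0,
                         hsa = 0, zip = 0),
    n_drugs = 3, n_targets = 3)
}
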