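# Synthetic datasets with the statistical structure the model assumes: a
# drug-target-protein network, plus adverse-effect labels and synergy
# scores driven by a shared latent pair mechanism, at desk scale.

#' Synthetic-dataset configuration
#'
#' The defaults give a small but non-degenerate dataset: every drug has at
#' least one target, the length-3/4/5 meta-path sets are non-empty, and the
#' planted pair factor couples the adverse-effect labels to the synergy
#' scores — the structure the multi-task hypothesis exploits.
#'
#' @param n_drugs,n_targets,n_cell_lines,n_ae,n_genes counts
#' @param n_bits fingerprint length of the synthetic drug bit vectors
#' @param p_dti,p_ppi independent edge probabilities
#' @param p_pair probability that a drug pair is observed at all
#' @param shared_effect strength of the latent pair factor common to the
#'   adverse-effect labels and the synergy scores (0 decouples them)
#' @param interaction_sd scale of the pair-and-cell-line interaction term
#' @param noise_sd standard deviation of the synergy observation noise
#' @param latent_dim dimension of the per-drug / per-cell-line latents
#' @param seed integer RNG seed
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_drugs = 20, n_targets = 30, n_cell_lines = 5,
                         n_ae = 8, n_genes = 50, n_bits = 64,
                         p_dti = 0.12, p_ppi = 0.08, p_pair = 0.9,
                         shared_effect = 2, interaction_sd = 1,
                         noise_sd = 1, latent_dim = 4, seed = 1L) {
  stopifnot(n_drugs >= 2, n_targets >= 2, n_cell_lines >= 2,
            p_dti > 0, p_dti < 1, p_ppi > 0, p_ppi < 1,
            shared_effect >= 0, noise_sd > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic dataset
#'
#' Draws a heterogeneous network (DTI edges with isolated-drug resampling,
#' PPI edges), per-drug and per-cell-line latent vectors, and a per-pair
#' shared factor combining latent similarity with the pair's shared-target
#' count in the generated network. Adverse-effect labels are Bernoulli with
#' logistic probabilities in that factor; synergy scores are
#' `shared_effect * s_ij` plus a pair-by-cell-line interaction and Gaussian
#' noise. Drug "fingerprints" are random bits correlated with the drug
#' latents; expression rows are logistic transforms of the cell-line
#' latents clipped to [0, 1].
#'
#' @param config a [synth_config()]
#' @return list with the same table layout as [load_tables()] plus `truth`
#'   (latent factors and per-pair shared factors)
#' @export
generate_synth_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  withr::with_seed(as.integer(cf$seed), {
    nd <- cf$n_drugs; nt <- cf$n_targets; ncell <- cf$n_cell_lines
    r <- cf$latent_dim

    # DTI with isolated-drug resampling: every drug keeps >= 1 target
    dti_adj <- matrix(stats::runif(nd * nt) < cf$p_dti, nd, nt)
    for (d in which(rowSums(dti_adj) == 0L)) {
      dti_adj[d, sample.int(nt, 1L)] <- TRUE
    }
    dti <- which(dti_adj, arr.ind = TRUE)
    dti <- data.frame(drug = as.integer(dti[, 1]), target = as.integer(dti[, 2]))

    ppi_adj <- matrix(FALSE, nt, nt)
    up <- which(upper.tri(ppi_adj))
    ppi_adj[up] <- stats::runif(length(up)) < cf$p_ppi
    ppi <- which(ppi_adj, arr.ind = TRUE)
    ppi <- data.frame(target_a = as.integer(ppi[, 1]),
                      target_b = as.integer(ppi[, 2]))
    if (!nrow(ppi)) {
      warning("generate_synth_data: no PPI edges drawn; ",
              "DTTD/DTTTD instance sets will be empty")
      ppi <- data.frame(target_a = integer(0), target_b = integer(0))
    }

    u <- matrix(stats::rnorm(nd * r), nd, r)      # drug latents
    v <- matrix(stats::rnorm(ncell * r), ncell, r) # cell-line latents

    pairs <- t(utils::combn(nd, 2L))
    keep <- stats::runif(nrow(pairs)) < cf$p_pair
    if (sum(keep) < 5L) keep[seq_len(5L)] <- TRUE
    pairs <- pairs[keep, , drop = FALSE]

    shared_targets <- vapply(seq_len(nrow(pairs)), function(i) {
      sum(dti_adj[pairs[i, 1], ] & dti_adj[pairs[i, 2], ])
    }, numeric(1))
    s_raw <- rowSums(u[pairs[, 1], , drop = FALSE] *
                       u[pairs[, 2], , drop = FALSE]) / sqrt(r) +
      0.7 * shared_targets
    s <- as.numeric(scale(s_raw))  # standardized shared pair factor

    w_ae <- stats::runif(cf$n_ae, 1.5, 3)
    b_ae <- stats::rnorm(cf$n_ae, 0, 0.5)
    ae_prob <- 1 / (1 + exp(-(outer(s, w_ae) +
                                matrix(b_ae, nrow(pairs), cf$n_ae,
                                       byrow = TRUE))))
    ae_lab <- matrix(as.integer(stats::runif(length(ae_prob)) < ae_prob),
                     nrow(pairs), cf$n_ae)
    ae <- cbind(data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2]),
                stats::setNames(as.data.frame(ae_lab),
                                paste0("ae_", seq_len(cf$n_ae))))

    # synergy per pair x cell line: shared factor + interaction + noise
    grid <- expand.grid(pair = seq_len(nrow(pairs)),
                        cell = seq_len(ncell))
    inter <- cf$interaction_sd *
      rowSums((u[pairs[grid$pair, 1], , drop = FALSE] +
                 u[pairs[grid$pair, 2], , drop = FALSE]) *
                v[grid$cell, , drop = FALSE]) / sqrt(2 * r)
    base_score <- cf$shared_effect * s[grid$pair] + inter +
      stats::rnorm(nrow(grid), 0, cf$noise_sd)
    # the four score types are noisy rescalings of one underlying effect
    synergy <- data.frame(
      drug_a = pairs[grid$pair, 1], drug_b = pairs[grid$pair, 2],
      cell_line = grid$cell,
      loewe = base_score,
      bliss = 0.6 * base_score + stats::rnorm(nrow(grid), 0, 0.3),
      hsa = 0.5 * base_score + stats::rnorm(nrow(grid), 0, 0.3),
      zip = 0.55 * base_score + stats::rnorm(nrow(grid), 0, 0.3))

    # fingerprints: random hyperplane bits of the drug latents, bit-flip noise
    proj <- matrix(stats::rnorm(r * cf$n_bits), r, cf$n_bits)
    bits <- (u %*% proj + matrix(stats::rnorm(nd * cf$n_bits, 0, 0.8),
                                 nd, cf$n_bits)) > 0
    chem <- matrix(as.integer(bits), nd, cf$n_bits)
    rownames(chem) <- sprintf("DRUG%03d", seq_len(nd))
    colnames(chem) <- paste0("bit_", seq_len(cf$n_bits))

    amap <- matrix(stats::rnorm(r * cf$n_genes), r, cf$n_genes)
    expr <- 1 / (1 + exp(-(v %*% amap +
                             matrix(stats::rnorm(ncell * cf$n_genes, 0, 0.3),
                                    ncell, cf$n_genes))))
    expr <- pmin(pmax(expr, 0), 1)
    rownames(expr) <- sprintf("CELL%03d", seq_len(ncell))
    colnames(expr) <- paste0("gene_", seq_len(cf$n_genes))

    list(
      dti = dti, ppi = ppi, synergy = synergy, ae = ae,
      expression = expr, chem = chem,
      maps = list(drugs = sprintf("DRUG%03d", seq_len(nd)),
                  targets = sprintf("TGT%03d", seq_len(nt)),
                  cell_lines = sprintf("CELL%03d", seq_len(ncell))),
      truth = list(u = u, v = v, s = s, pairs = pairs,
                   shared_targets = shared_targets, config = cf)
    )
  })
}

#' Write a dataset to the on-disk TSV layout
#'
#' Emits the exact tab-delimited dialect consumed by [load_tables()];
#' loading the written directory reproduces the tables.
#'
#' @param dataset from [generate_synth_data()] (or [load_tables()])
#' @param dir output directory (created if needed)
#' @return invisible vector of written file paths
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- dataset$maps
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, f)
  }
  files <- c(
    wr(data.frame(drug = maps$drugs[dataset$dti$drug],
                  target = maps$targets[dataset$dti$target]), "dti.tsv"),
    wr(data.frame(target_a = maps$targets[dataset$ppi$target_a],
                  target_b = maps$targets[dataset$ppi$target_b]), "ppi.tsv"),
    wr(within(dataset$synergy, {
      drug_a <- maps$drugs[drug_a]
      drug_b <- maps$drugs[drug_b]
      cell_line <- maps$cell_lines[cell_line]
    })[, c("drug_a", "drug_b", "cell_line", "loewe", "bliss", "hsa", "zip")],
    "synergy.tsv"),
    wr({
      ae <- dataset$ae
      ae$drug_a <- maps$drugs[ae$drug_a]
      ae$drug_b <- maps$drugs[ae$drug_b]
      ae
    }, "ae.tsv"),
    wr(cbind(data.frame(cell_line = rownames(dataset$expression)),
             as.data.frame(dataset$expression)), "expression.tsv"),
    wr(cbind(data.frame(drug = rownames(dataset$chem)),
             as.data.frame(dataset$chem)), "chem.tsv")
  )
  invisible(files)
}
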