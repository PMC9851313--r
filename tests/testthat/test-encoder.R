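make_params <- function(config, seed = 1, n_drugs = 8, n_targets = 12) {
  init_params(n_drugs, n_targets, n_genes = 10, config, seed = seed)
}

test_that("sequence aggregators honor their dimensional contracts", {
  cfg <- small_config()
  prm <- make_params(cfg)
  net <- random_hetnet(5)
  inst <- enumerate_instances(net, "DTD")
  trf <- list(D = hetsyn:::ag_value(prm$type_transform$D),
              T = hetsyn:::ag_value(prm$type_transform$T))
  tens <- tensorize(inst, trf)
  n <- dim(tens)[1]
  expect_gt(n, 1)

  agg <- aggregate_instances(tens, prm$schemas$DTD, "bigru")
  expect_equal(dim(agg$h_f), c(n, 2 * cfg$hidden))
  expect_equal(dim(agg$h_l), c(n, 2 * cfg$hidden))

  # identical instances give identical rows (fixed-parameter determinism)
  dup <- tens[c(1, 1), , , drop = FALSE]
  agg2 <- aggregate_instances(dup, prm$schemas$DTD, "bigru")
  expect_equal(agg2$h_f[1, ], agg2$h_f[2, ])

  # empty sets must be signalled so the caller substitutes the null embedding
  empty <- tens[integer(0), , , drop = FALSE]
  expect_error(aggregate_instances(empty, prm$schemas$DTD, "bigru"),
               "null embedding")
})

test_that("mean aggregator reduces to position-wise mean and central feature", {
  cfg <- small_config(aggregator = "mean")
  prm <- make_params(cfg)
  v <- rnorm(cfg$d_prime)
  tens <- array(rep(v, each = 3), dim = c(1, 3, cfg$d_prime))
  agg <- aggregate_instances(tens, prm$schemas$DTD, "mean")
  expect_equal(as.numeric(agg$h_f), v)  # mean of identical rows
  expect_equal(as.numeric(agg$h_l), v)  # central node's own feature
})

test_that("instance attention weights are a proper softmax per central drug", {
  cfg <- small_config()
  prm <- make_params(cfg)
  # single instance: weight 1 regardless of parameters
  adim <- 2 * cfg$hidden
  one <- list(h_f = matrix(rnorm(adim), 1), h_l = matrix(rnorm(adim), 1))
  out1 <- gat_extract(one, prm$schemas$DTD, cfg)
  expect_equal(out1$alpha, 1)
  expect_length(out1$embedding, cfg$K * cfg$d_head)
  # equal logits (identical rows) spread weight uniformly
  n <- 6
  same <- list(h_f = matrix(rep(rnorm(adim), each = n), n),
               h_l = matrix(rep(rnorm(adim), each = n), n))
  outn <- gat_extract(same, prm$schemas$DTD, cfg)
  expect_equal(outn$alpha, rep(1 / n, n), tolerance = 1e-12)
  # attention weights always sum to one, for many random parameterizations
  for (seed in 1:50) {
    p2 <- make_params(cfg, seed = seed)
    h <- withr::with_seed(seed, list(h_f = matrix(runif(5 * adim, -10, 10), 5),
                                     h_l = matrix(runif(5 * adim, -10, 10), 5)))
    o <- gat_extract(h, p2$schemas$DTTD, cfg)
    expect_equal(sum(o$alpha), 1, tolerance = 1e-6)
    expect_true(all(is.finite(o$embedding)))
  }
})

test_that("attention aggregation is invariant to instance order", {
  cfg <- small_config()
  prm <- make_params(cfg)
  adim <- 2 * cfg$hidden
  h <- withr::with_seed(3, list(h_f = matrix(rnorm(7 * adim), 7),
                                h_l = matrix(rnorm(7 * adim), 7)))
  perm <- sample(7)
  hp <- list(h_f = h$h_f[perm, ], h_l = h$h_l[perm, ])
  expect_equal(gat_extract(hp, prm$schemas$DD, cfg)$embedding,
               gat_extract(h, prm$schemas$DD, cfg)$embedding,
               tolerance = 1e-12)
})

test_that("meta-path combiner weights are softmax-normalized and convex", {
  cfg <- small_config()
  Dm <- cfg$K * cfg$d_head
  for (seed in 1:50) {
    prm <- make_params(cfg, seed = seed)
    emb <- withr::with_seed(seed + 100, {
      stats::setNames(lapply(1:4, function(i) matrix(runif(6 * Dm, -10, 10), 6)),
                      c("DTD", "DTTD", "DTTTD", "DD"))
    })
    out <- combine_metapaths(emb, prm$combiner, cfg)
    expect_equal(sum(out$beta), 1, tolerance = 1e-6)
    expect_true(all(out$beta > 0))
    expect_true(all(is.finite(out$z_drug)))
  }
  # identical schema embeddings: the convex combination returns them unchanged
  prm <- make_params(cfg)
  common <- matrix(rnorm(6 * Dm), 6)
  emb_same <- stats::setNames(lapply(1:4, function(i) common),
                              c("DTD", "DTTD", "DTTTD", "DD"))
  out <- combine_metapaths(emb_same, prm$combiner, cfg)
  expect_equal(out$h_t, common, tolerance = 1e-10)
  expect_error(combine_metapaths(emb_same[1:3], prm$combiner, cfg), "missing schema")
})

test_that("drugs without instances receive the learned null embedding", {
  # drug 3 is connected to nothing but its own target: no DD/DTD neighbors
  net <- build_hetnet(
    dti = data.frame(drug = c(1L, 2L, 3L), target = c(1L, 1L, 2L)),
    ppi = data.frame(target_a = integer(0), target_b = integer(0)),
    synergy = data.frame(drug_a = 1L, drug_b = 2L, cell_line = 1L,
                         loewe = 1, bliss = 0, hsa = 0, zip = 0),
    n_drugs = 3, n_targets = 2)
  cfg <- small_config()
  prm <- init_params(3, 2, 10, cfg, seed = 1)
  idx <- hetsyn:::build_instance_index(net, 1, 1)
  enc <- hetsyn:::encode_drugs_node(prm, idx, 3)
  emb_dtd <- hetsyn:::ag_value(enc$schema_emb$DTD)
  null_dtd <- hetsyn:::ag_value(prm$schemas$DTD$null_emb)
  expect_equal(emb_dtd[3, ], as.numeric(null_dtd))
  expect_false(isTRUE(all.equal(emb_dtd[1, ], as.numeric(null_dtd))))
})

test_that("Morgan fingerprints are deterministic binary vectors of n_bits", {
  skip_if_not_installed("ChemmineOB")
  fp1 <- compute_ecfp6("CCO", n_bits = 256)
  fp2 <- compute_ecfp6("CCO", n_bits = 256)
  expect_identical(fp1, fp2)
  expect_equal(ncol(fp1), 256)
  expect_true(all(fp1 %in% c(0L, 1L)))
  # independent toolkit route: the obabel CLI reports the same on-bit count
  # for the unfolded radius-3 fingerprint of ethanol
  fp_full <- compute_ecfp6("CCO", n_bits = 4096)
  ob <- tryCatch(system2("obabel", c("-:CCO", "-ofpt", "-xfECFP6", "-xN4096"),
                         stdout = TRUE, stderr = FALSE),
                 error = function(e) NULL)
  if (!is.null(ob)) {
    n_cli <- as.integer(sub(">\\s*(\\d+) bits set.*", "\\1",
                            grep("bits set", ob, value = TRUE)[1]))
    expect_equal(sum(fp_full), n_cli)
  }
  # folding ORs high bits onto low bits: popcount can only shrink
  expect_lte(sum(compute_ecfp6("CCO", 64)), sum(fp_full))
  expect_error(compute_ecfp6("not-a-smiles(", 64), "could not parse")
})
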