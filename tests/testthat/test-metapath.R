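test_that("shared-target example yields exactly one DTD instance", {
  net <- build_hetnet(
    dti = data.frame(drug = c(1L, 2L), target = c(1L, 1L)),
    ppi = data.frame(target_a = integer(0), target_b = integer(0)),
    synergy = data.frame(drug_a = 1L, drug_b = 2L, cell_line = 1L,
                         loewe = -1, bliss = 0, hsa = 0, zip = 0),
    n_drugs = 2, n_targets = 1)
  inst <- enumerate_instances(net, "DTD", end_drug = 2L)
  expect_equal(inst$nodes, matrix(c(1L, 1L, 2L), 1))
  # no shared target between any drugs -> empty for every end drug
  net2 <- build_hetnet(
    dti = data.frame(drug = c(1L, 2L), target = c(1L, 2L)),
    ppi = data.frame(target_a = integer(0), target_b = integer(0)),
    synergy = data.frame(drug_a = 1L, drug_b = 2L, cell_line = 1L,
                         loewe = -1, bliss = 0, hsa = 0, zip = 0),
    n_drugs = 2, n_targets = 2)
  for (d in 1:2) {
    expect_equal(nrow(enumerate_instances(net2, "DTD", end_drug = d)$nodes), 0L)
  }
})

test_that("DD instances are exactly the therapeutic-effect neighbors", {
  net <- tiny_net()  # DD edge only between drugs 1 and 2
  expect_equal(enumerate_instances(net, "DD", end_drug = 2L)$nodes,
               matrix(c(1L, 2L), 1))
  expect_equal(nrow(enumerate_instances(net, "DD", end_drug = 3L)$nodes), 0L)
})

test_that("enumeration matches the brute-force all-tuples oracle", {
  for (seed in 1:25) {
    net <- random_hetnet(seed)
    for (s in c("DTD", "DTTD", "DTTTD", "DD")) {
      got <- enumerate_instances(net, s)$nodes
      expect_identical(got, oracle_instances(net, s),
                       info = paste("seed", seed, "schema", s))
    }
  }
})

test_that("instance counts are symmetric between drug pairs for DTD", {
  net <- random_hetnet(99)
  m <- enumerate_instances(net, "DTD")$nodes
  for (a in 1:3) for (b in 4:6) {
    expect_equal(sum(m[, 1] == a & m[, 3] == b),
                 sum(m[, 1] == b & m[, 3] == a))
  }
})

test_that("bridging-target restriction removes exactly the untargeted middles", {
  net <- random_hetnet(7)
  inst <- enumerate_instances(net, "DTTTD")
  res <- restrict_and_sample_dtttd(inst, net, ratio = 1)
  targeted <- unique(net$dti[, 2])
  expect_true(all(res$nodes[, 3] %in% targeted))
  dropped <- inst$nodes[!(inst$nodes[, 3] %in% targeted), , drop = FALSE]
  expect_equal(nrow(res$nodes) + nrow(dropped), nrow(inst$nodes))
  # ratio 1 is a pure order-preserving filter
  expect_identical(res$nodes,
                   inst$nodes[inst$nodes[, 3] %in% targeted, , drop = FALSE])
})

test_that("subsampling is seeded, reproducible, and keeps ceiling(ratio*n)", {
  net <- random_hetnet(13)
  inst <- enumerate_instances(net, "DTTTD")
  restricted <- restrict_and_sample_dtttd(inst, net, ratio = 1)
  n <- nrow(restricted$nodes)
  expect_gt(n, 3)
  s1 <- restrict_and_sample_dtttd(inst, net, ratio = 0.5, seed = 41)
  s2 <- restrict_and_sample_dtttd(inst, net, ratio = 0.5, seed = 41)
  s3 <- restrict_and_sample_dtttd(inst, net, ratio = 0.5, seed = 42)
  expect_identical(s1$nodes, s2$nodes)
  expect_equal(nrow(s1$nodes), ceiling(n / 2))
  expect_false(identical(s1$nodes, s3$nodes))
  # output is a subset of the restricted instances
  expect_true(all(apply(s1$nodes, 1, paste, collapse = ",") %in%
                    apply(restricted$nodes, 1, paste, collapse = ",")))
  # ceiling keeps a singleton set intact
  one <- restricted; one$nodes <- restricted$nodes[1, , drop = FALSE]
  expect_equal(nrow(restrict_and_sample_dtttd(one, net, 0.5, 1)$nodes), 1L)
})

test_that("wrong-schema input to the DTTTD sampler is rejected", {
  net <- random_hetnet(7)
  expect_error(restrict_and_sample_dtttd(enumerate_instances(net, "DTD"), net),
               "expected DTTTD")
})

test_that("tensorize maps one-hot node identities through type transforms", {
  net <- tiny_net()
  inst <- enumerate_instances(net, "DTD", end_drug = 2L)
  # identity transforms: features are the raw one-hot vectors
  tens <- tensorize(inst, list(D = diag(3), T = diag(3)))
  expect_equal(dim(tens), c(1, 3, 3))
  expect_equal(tens[1, 1, ], c(1, 0, 0))  # start drug 1
  expect_equal(tens[1, 2, ], c(1, 0, 0))  # target 1
  expect_equal(tens[1, 3, ], c(0, 1, 0))  # central drug 2
  # general transform: rows are picked from the type matrices
  withr::with_seed(8, {
    tD <- matrix(rnorm(12), 3, 4); tT <- matrix(rnorm(12), 3, 4)
  })
  tens2 <- tensorize(inst, list(D = tD, T = tT))
  expect_equal(dim(tens2), c(1, 3, 4))
  expect_equal(tens2[1, 2, ], tT[1, ])
  # permuting instances permutes tensor slices identically
  inst_all <- enumerate_instances(random_hetnet(3), "DTD")
  trf <- list(D = matrix(rnorm(8 * 4), 8), T = matrix(rnorm(12 * 4), 12))
  tens_a <- tensorize(inst_all, trf)
  perm <- rev(seq_len(nrow(inst_all$nodes)))
  inst_p <- inst_all; inst_p$nodes <- inst_all$nodes[perm, , drop = FALSE]
  tens_p <- tensorize(inst_p, trf)
  expect_equal(tens_p, tens_a[perm, , , drop = FALSE])
  # mismatched transform dimensions are rejected
  expect_error(tensorize(inst, list(D = diag(3), T = diag(2)[, 1:2])), "dimension")
})

test_that("instance export writes one readable TSV per drug and schema", {
  d <- generate_synth_data(synth_config(seed = 2))
  net <- build_hetnet(d$dti, d$ppi, d$synergy, 20, 30)
  dir <- withr::local_tempdir()
  files <- export_instances(net, d$maps, drugs = 1:2, dir = dir)
  expect_length(files, 8)
  tab <- utils::read.delim(files[1])
  inst <- enumerate_instances(net, "DTD", end_drug = 1L)
  expect_equal(nrow(tab), nrow(inst$nodes))
})
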