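test_that("drug-drug edges follow the strict synergy threshold rule", {
  syn <- data.frame(drug_a = c(1L, 1L, 2L), drug_b = c(2L, 2L, 3L),
                    cell_line = c(1L, 2L, 1L),
                    loewe = c(5, -2, 0), bliss = 0, hsa = 0, zip = 0)
  dti <- data.frame(drug = 1L, target = 1L)
  ppi <- data.frame(target_a = integer(0), target_b = integer(0))
  net <- build_hetnet(dti, ppi, syn, 3, 2, threshold = 0)
  # pair (1,2) has a score above 0, pair (2,3) sits exactly on the boundary
  expect_equal(net$dd, matrix(c(1L, 2L), 1))
})

test_that("edge sets are deduplicated, symmetric and self-loop free", {
  dti <- data.frame(drug = c(1L, 2L, 1L), target = c(1L, 1L, 1L))
  ppi <- data.frame(target_a = c(1L, 2L, 2L, 1L), target_b = c(2L, 1L, 2L, 2L))
  syn <- data.frame(drug_a = c(1L, 2L), drug_b = c(2L, 1L), cell_line = 1:2,
                    loewe = c(3, 4), bliss = 0, hsa = 0, zip = 0)
  net <- build_hetnet(dti, ppi, syn, 2, 2)
  expect_equal(nrow(net$dti), 2L)       # (1,1) duplicated
  expect_equal(net$ppi, matrix(c(1L, 2L), 1))  # dedup across orders, no loop
  expect_equal(nrow(net$dd), 1L)        # both orders collapse to one pair
})

test_that("rebuilding from the same tables is idempotent", {
  d <- generate_synth_data(synth_config(seed = 5))
  n1 <- build_hetnet(d$dti, d$ppi, d$synergy, 20, 30)
  n2 <- build_hetnet(d$dti, d$ppi, d$synergy, 20, 30)
  expect_identical(n1, n2)
})

test_that("unknown identifiers and non-finite scores are rejected", {
  syn <- data.frame(drug_a = 1L, drug_b = 2L, cell_line = 1L,
                    loewe = 1, bliss = 0, hsa = 0, zip = 0)
  expect_error(
    build_hetnet(data.frame(drug = 9L, target = 1L),
                 data.frame(target_a = integer(0), target_b = integer(0)),
                 syn, 3, 2),
    "unknown node")
  syn_bad <- syn; syn_bad$loewe <- NaN
  expect_error(
    build_hetnet(data.frame(drug = 1L, target = 1L),
                 data.frame(target_a = integer(0), target_b = integer(0)),
                 syn_bad, 3, 2),
    "non-finite")
})

test_that("restricting DD sources to training pairs excludes held-out labels", {
  d <- generate_synth_data(synth_config(seed = 11))
  tr <- make_triples(d)
  sp <- split_by_pair(tr, seed = 2)
  net <- build_hetnet(d$dti, d$ppi, d$synergy, 20, 30,
                      dd_source_pairs = data.frame(a = sp$train_pairs[, 1],
                                                   b = sp$train_pairs[, 2]))
  dd_keys <- hetsyn:::pair_key(net$dd[, 1], net$dd[, 2])
  held <- c(hetsyn:::pair_key(sp$val_pairs[, 1], sp$val_pairs[, 2]),
            hetsyn:::pair_key(sp$test_pairs[, 1], sp$test_pairs[, 2]))
  expect_length(intersect(dd_keys, held), 0)
  # removing all held-out triples from the input leaves the graph unchanged
  keep <- sp$train
  syn_tr <- d$synergy[keep, , drop = FALSE]
  net2 <- build_hetnet(d$dti, d$ppi, syn_tr, 20, 30,
                       dd_source_pairs = data.frame(a = sp$train_pairs[, 1],
                                                    b = sp$train_pairs[, 2]))
  expect_identical(net$dd, net2$dd)
})

test_that("fixture round trip: write_fixture then load_tables is the identity", {
  d <- generate_synth_data(synth_config(seed = 3))
  dir <- withr::local_tempdir()
  write_fixture(d, dir)
  l <- load_tables(dir)
  expect_equal(l$dti, d$dti)
  expect_equal(l$ppi, d$ppi)
  expect_equal(l$synergy, d$synergy, tolerance = 1e-12)
  expect_equal(as.matrix(l$ae[, -(1:2)]),
               as.matrix(d$ae[, -(1:2)]), ignore_attr = TRUE)
  expect_equal(l$expression, d$expression, tolerance = 1e-12)
  expect_equal(l$chem, d$chem, ignore_attr = TRUE)
  expect_identical(l$maps$drugs, d$maps$drugs)
  # identifier maps round-trip: index -> name -> index
  idx <- seq_along(l$maps$drugs)
  expect_identical(match(l$maps$drugs[idx], l$maps$drugs), idx)
})

test_that("malformed tables are rejected with row context", {
  d <- generate_synth_data(synth_config(seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(d, dir)
  # duplicate synergy row
  syn <- utils::read.delim(file.path(dir, "synergy.tsv"))
  utils::write.table(rbind(syn, syn[1, ]), file.path(dir, "synergy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_tables(dir), "duplicate synergy row")
  utils::write.table(syn, file.path(dir, "synergy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # AE vector of wrong length (missing value in one row)
  ae <- utils::read.delim(file.path(dir, "ae.tsv"))
  ae[2, ncol(ae)] <- NA
  utils::write.table(ae, file.path(dir, "ae.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_tables(dir), "row 2")
  # missing required column
  utils::write.table(ae[, setdiff(names(ae), "drug_a")],
                     file.path(dir, "ae.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_tables(dir), "missing column")
})

test_that("triples join each pair's adverse-effect labels", {
  d <- generate_synth_data(synth_config(seed = 6))
  tr <- make_triples(d, "loewe")
  expect_equal(nrow(tr), nrow(d$synergy))
  lab <- attr(tr, "ae_labels")
  expect_equal(dim(lab), c(nrow(tr), 8))
  i <- 25L
  row <- d$ae[d$ae$drug_a == tr$drug_a[i] & d$ae$drug_b == tr$drug_b[i] |
                d$ae$drug_a == tr$drug_b[i] & d$ae$drug_b == tr$drug_a[i], ]
  expect_equal(as.numeric(lab[i, ]), as.numeric(row[1, -(1:2)]))
})
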