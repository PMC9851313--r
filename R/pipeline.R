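# Leakage-free evaluation protocol: pair-grouped splitting, symmetric
# sample handling, end-to-end training and repeated evaluation.

#' Split samples by drug pair
#'
#' All drug-drug-cell-line samples sharing an (unordered) drug pair are
#' assigned to the same partition, so no test pair is ever seen during
#' training across a different cell line. Pairs are shuffled with the seed
#' and partitioned by largest-remainder rounding of the ratios.
#'
#' @param triples data.frame from [make_triples()]
#' @param ratios train/validation/test fractions summing to 1
#' @param seed shuffle seed
#' @return list of class `split_spec`: `train_pairs`, `val_pairs`,
#'   `test_pairs` (two-column matrices, a < b) and logical row masks
#'   `train`, `val`, `test` over `triples`
#' @export
split_by_pair <- function(triples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3L)
  keys <- pair_key(triples$drug_a, triples$drug_b)
  pairs <- unique(keys)
  n <- length(pairs)
  if (n < length(ratios) + 2L) {
    stop("split_by_pair: need at least 5 distinct drug pairs, got ", n)
  }
  perm <- withr::with_seed(as.integer(seed), sample(pairs))
  base <- floor(ratios * n)
  rem <- ratios * n - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  counts <- base
  counts[extra] <- counts[extra] + 1L
  idx_end <- cumsum(counts)
  idx_start <- c(1L, head(idx_end, -1L) + 1L)
  sets <- lapply(1:3, function(i) {
    if (counts[i] == 0L) character(0) else perm[idx_start[i]:idx_end[i]]
  })
  stopifnot(!length(intersect(sets[[1]], sets[[2]])),
            !length(intersect(sets[[1]], sets[[3]])),
            !length(intersect(sets[[2]], sets[[3]])))
  as_pairs <- function(k) {
    if (!length(k)) return(matrix(integer(0), 0, 2))
    m <- do.call(rbind, strsplit(k, ":", fixed = TRUE))
    matrix(as.integer(m), ncol = 2)
  }
  structure(list(
    train_pairs = as_pairs(sets[[1]]),
    val_pairs = as_pairs(sets[[2]]),
    test_pairs = as_pairs(sets[[3]]),
    train = keys %in% sets[[1]],
    val = keys %in% sets[[2]],
    test = keys %in% sets[[3]]
  ), class = "split_spec")
}

#' Duplicate training samples in both drug orders
#'
#' Each training triple (i, j, k) is emitted once as (i, j, k) and once as
#' (j, i, k) with identical labels, so the order-sensitive heads see both
#' orderings. Validation and test samples are never duplicated; their
#' predictions are symmetrized by [predict_symmetric()] instead.
#'
#' @param triples training triples (with attribute "ae_labels")
#' @return augmented triples, twice the rows
#' @export
symmetrize_training <- function(triples) {
  lab <- attr(triples, "ae_labels")
  swapped <- triples
  swapped$drug_a <- triples$drug_b
  swapped$drug_b <- triples$drug_a
  out <- rbind(triples, swapped)
  attr(out, "ae_labels") <- rbind(lab, lab)
  out
}

#' Order-symmetric synergy prediction
#'
#' Returns the arithmetic mean of the model outputs for both drug orders of
#' each sample, which makes held-out predictions invariant to argument
#' order.
#'
#' @param model a trained `hetsyn_model`
#' @param triples data.frame with drug_a, drug_b, cell_line
#' @return numeric vector of symmetric predictions
#' @export
predict_symmetric <- function(model, triples) {
  swapped <- triples
  swapped$drug_a <- triples$drug_b
  swapped$drug_b <- triples$drug_a
  # one encoder pass serves both drug orders
  both <- predict_triples(model$params, model$inst_index, model$chem,
                          model$expr, rbind(triples, swapped))
  n <- nrow(triples)
  (both[seq_len(n)] + both[n + seq_len(n)]) / 2
}

#' Train the multi-task model on one split
#'
#' Builds the heterogeneous network from the training-split pairs only (by
#' default, so held-out synergy labels never enter the graph), enumerates
#' meta-path instances once, and minimizes the alpha-weighted total loss
#' over the symmetrized training triples with Adam, early-stopping on
#' validation MSE.
#'
#' @param tables dataset tables ([load_tables()] / [generate_synth_data()])
#' @param config a [hetsyn_config()]
#' @param seed integer seed covering initialization, DTTTD sampling,
#'   batching and dropout
#' @param split optional precomputed [split_by_pair()]; defaults to a 6:2:2
#'   pair-grouped split drawn with `seed`
#' @param dd_all_pairs build drug-drug edges from all pairs instead of the
#'   training pairs only (reintroduces label leakage; off by default)
#' @param verbose print per-epoch losses
#' @return object of class `hetsyn_model`
#' @export
train_model <- function(tables, config = hetsyn_config(), seed = 1L,
                        split = NULL, dd_all_pairs = FALSE,
                        verbose = FALSE) {
  # fingerprint width and AE label count are properties of the data
  n_bits_data <- ncol(tables$chem)
  n_ae_data <- sum(grepl("^ae_", names(tables$ae)))
  if (config$n_bits != n_bits_data || config$n_ae != n_ae_data) {
    message("train_model: using n_bits = ", n_bits_data, " and n_ae = ",
            n_ae_data, " from the data tables")
    config$n_bits <- n_bits_data
    config$n_ae <- n_ae_data
  }
  triples <- make_triples(tables, config$score_type)
  if (is.null(split)) split <- split_by_pair(triples, seed = seed)
  stopifnot(!length(intersect(pair_key(split$train_pairs[, 1], split$train_pairs[, 2]),
                              pair_key(split$test_pairs[, 1], split$test_pairs[, 2]))))
  n_drugs <- nrow(tables$chem)
  n_targets <- max(tables$dti$target, tables$ppi$target_a, tables$ppi$target_b)
  dd_source <- if (dd_all_pairs) NULL else
    data.frame(a = split$train_pairs[, 1], b = split$train_pairs[, 2])
  net <- build_hetnet(tables$dti, tables$ppi, tables$synergy,
                      n_drugs = n_drugs, n_targets = n_targets,
                      threshold = config$dd_threshold,
                      score_type = config$score_type,
                      dd_source_pairs = dd_source)
  inst_index <- build_instance_index(net, dtttd_ratio = config$dtttd_ratio,
                                     seed = seed,
                                     allow_self = config$allow_self_instances)
  params <- init_params(n_drugs, n_targets, ncol(tables$expression),
                        config, seed = seed)
  plist <- param_list(params)
  opt <- adam_new(plist, lr = config$lr, weight_decay = config$weight_decay)

  tr <- triples[split$train, , drop = FALSE]
  attr(tr, "ae_labels") <- attr(triples, "ae_labels")[split$train, , drop = FALSE]
  tr <- symmetrize_training(tr)
  va <- triples[split$val, , drop = FALSE]
  chem <- tables$chem
  expr <- tables$expression
  model <- structure(list(params = params, inst_index = inst_index,
                          net = net, chem = chem, expr = expr,
                          config = config, split = split,
                          maps = tables$maps, seed = seed),
                     class = "hetsyn_model")

  n_tr <- nrow(tr)
  labels <- attr(tr, "ae_labels")
  log <- data.frame(epoch = integer(0), l_bce = numeric(0),
                    l_mse = numeric(0), l_total = numeric(0),
                    val_mse = numeric(0))
  best_val <- Inf
  best_values <- NULL
  wait <- 0L

  withr::with_seed(as.integer(seed) + 1L, {
    for (epoch in seq_len(config$epochs)) {
      if (is.null(config$batch_size) || config$batch_size >= n_tr) {
        batches <- list(seq_len(n_tr))
      } else {
        perm <- sample.int(n_tr)
        batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      }
      ep_mse <- 0; ep_bce <- 0; ep_tot <- 0
      for (b in batches) {
        bt <- tr[b, , drop = FALSE]
        bl <- labels[b, , drop = FALSE]
        ag_zero_grad(plist)
        fw <- forward_batch(params, inst_index, chem, expr, bt,
                            training = TRUE)
        l_mse <- ag_mse(fw$pred, matrix(bt$synergy, ncol = 1))
        if (config$alpha < 1) {
          l_bce <- ag_bce(fw$p_ae, bl)
          l_tot <- ag_add(ag_scale_const(l_mse, config$alpha),
                          ag_scale_const(l_bce, 1 - config$alpha))
          bce_val <- as.numeric(ag_value(l_bce))
        } else {
          l_tot <- l_mse
          bce_val <- bce_loss(ag_value(fw$p_ae), bl)
        }
        if (!is.finite(ag_value(l_tot))) {
          stop("train_model: non-finite loss at epoch ", epoch)
        }
        ag_backward(l_tot)
        adam_step(opt)
        w <- length(b) / n_tr
        ep_mse <- ep_mse + w * as.numeric(ag_value(l_mse))
        ep_bce <- ep_bce + w * bce_val
        ep_tot <- ep_tot + w * total_loss(as.numeric(ag_value(l_mse)),
                                          bce_val, config$alpha)
      }
      val_mse <- if (nrow(va)) {
        mse_loss(predict_symmetric(model, va), va$synergy)
      } else NA_real_
      log[epoch, ] <- list(epoch, ep_bce, ep_mse, ep_tot, val_mse)
      if (verbose) {
        message(sprintf("epoch %3d  mse %.4f  bce %.4f  total %.4f  val %.4f",
                        epoch, ep_mse, ep_bce, ep_tot, val_mse))
      }
      if (is.finite(val_mse) && val_mse < best_val - 1e-9) {
        best_val <- val_mse
        best_values <- lapply(plist, function(p) p$value)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (!is.null(config$patience) && wait >= config$patience &&
            !is.na(val_mse)) break
      }
    }
  })
  if (!is.null(best_values)) {
    for (nm in names(plist)) plist[[nm]]$value <- best_values[[nm]]
  }
  model$log <- log
  model$best_val_mse <- best_val
  model
}

#' @export
print.hetsyn_model <- function(x, ...) {
  cat("Multi-task heterogeneous-network synergy model\n")
  cat("  aggregator:", x$config$aggregator, " alpha:", x$config$alpha, "\n")
  cat("  epochs run:", nrow(x$log), " best val MSE:",
      format(x$best_val_mse, digits = 5), "\n")
  invisible(x)
}

#' Evaluate a trained model on one partition
#'
#' Symmetric predictions are scored with MSE, MAE and the Pearson
#' correlation. A constant prediction vector leaves Pearson undefined; it
#' is reported as NA with a warning.
#'
#' @param model trained `hetsyn_model`
#' @param tables the dataset the model was trained on
#' @param partition "test" (default), "val" or "train"
#' @return list with `mse`, `mae`, `pearson`, `n`
#' @export
evaluate_model <- function(model, tables, partition = "test") {
  partition <- match.arg(partition, c("test", "val", "train"))
  triples <- make_triples(tables, model$config$score_type)
  mask <- model$split[[partition]]
  te <- triples[mask, , drop = FALSE]
  preds <- predict_symmetric(model, te)
  pear <- if (stats::sd(preds) == 0 || stats::sd(te$synergy) == 0) {
    warning("evaluate_model: constant predictions; Pearson undefined")
    NA_real_
  } else {
    stats::cor(preds, te$synergy)
  }
  list(mse = mse_loss(preds, te$synergy),
       mae = mean(abs(preds - te$synergy)),
       pearson = pear, n = nrow(te))
}

#' Repeated-split evaluation
#'
#' Reruns split -> train -> evaluate `n_repeats` times with seeds
#' `base_seed + 1 .. base_seed + n_repeats` and reports per-repeat and
#' averaged test metrics (arithmetic means; undefined Pearson values are
#' excluded from the average with a warning already raised per repeat).
#'
#' @param tables dataset tables
#' @param config a [hetsyn_config()]
#' @param n_repeats number of independent repeats
#' @param base_seed base seed
#' @return list of class `eval_report` with `per_repeat` (data.frame) and
#'   `mean` (named vector), plus the config and seeds
#' @export
run_repeated_eval <- function(tables, config = hetsyn_config(),
                              n_repeats = 5, base_seed = 1L) {
  seeds <- as.integer(base_seed) + seq_len(n_repeats)
  rows <- lapply(seeds, function(s) {
    m <- train_model(tables, config, seed = s)
    ev <- evaluate_model(m, tables, "test")
    data.frame(seed = s, mse = ev$mse, mae = ev$mae, pearson = ev$pearson,
               n_test = ev$n, epochs = nrow(m$log))
  })
  per <- do.call(rbind, rows)
  structure(list(
    per_repeat = per,
    mean = c(mse = mean(per$mse), mae = mean(per$mae),
             pearson = mean(per$pearson, na.rm = TRUE)),
    config = config, seeds = seeds
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Repeated pair-grouped evaluation (", nrow(x$per_repeat),
      " repeats)\n", sep = "")
  print(x$per_repeat, row.names = FALSE)
  cat("means: mse", format(x$mean["mse"], digits = 5),
      " mae", format(x$mean["mae"], digits = 5),
      " pearson", format(x$mean["pearson"], digits = 4), "\n")
  invisible(x)
}

#' Select the loss-weight ratio R on validation data
#'
#' Trains one model per candidate ratio `R = alpha / (1 - alpha)` on the
#' same split and returns the candidate with the lowest validation MSE,
#' along with all candidates' validation and test metrics.
#'
#' @param tables dataset tables
#' @param grid candidate ratios (default: the conventional search range)
#' @param config base configuration; its alpha is overridden per candidate
#' @param seed seed shared across candidates (same split, same init stream)
#' @return list with `best_R`, `best_alpha`, `best_model` and `results`
#' @export
sweep_alpha <- function(tables, grid = c(0.01, 0.05, 0.1, 0.5, 1, 5, 10),
                        config = hetsyn_config(), seed = 1L) {
  triples <- make_triples(tables, config$score_type)
  split <- split_by_pair(triples, seed = seed)
  best <- NULL
  rows <- list()
  for (R in grid) {
    cfg <- config
    cfg$alpha <- ratio_to_alpha(R)
    cfg$use_ae_input <- TRUE
    m <- train_model(tables, cfg, seed = seed, split = split)
    ev_val <- evaluate_model(m, tables, "val")
    ev_te <- evaluate_model(m, tables, "test")
    rows[[length(rows) + 1L]] <- data.frame(
      R = R, alpha = cfg$alpha, val_mse = ev_val$mse,
      test_mse = ev_te$mse, test_mae = ev_te$mae,
      test_pearson = ev_te$pearson)
    if (is.null(best) || ev_val$mse < best$val_mse) {
      best <- list(R = R, alpha = cfg$alpha, model = m,
                   val_mse = ev_val$mse)
    }
  }
  list(best_R = best$R, best_alpha = best$alpha, best_model = best$model,
       results = do.call(rbind, rows))
}
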