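# Heterogeneous therapeutic-effect network: drug and protein-target nodes
# with three binary edge relations (drug-target interactions, protein-protein
# interactions, and drug-drug therapeutic-effect edges obtained by
# thresholding synergy scores).

#' Canonical unordered drug-pair keys
#'
#' @param i,j integer drug indices
#' @return character vector "min:max", invariant to argument order
#' @keywords internal
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = ":")
}

#' Build the heterogeneous therapeutic-effect network
#'
#' Constructs the typed graph over drug and target nodes. DTI and PPI edges
#' are copied from their tables (deduplicated, self-loops dropped). A
#' drug-drug (DD) edge is created for an unordered pair iff at least one of
#' its synergy samples among `dd_source_pairs` has a score strictly greater
#' than `threshold` — positive synergy is treated as evidence of a
#' therapeutic-effect relationship.
#'
#' @param dti data.frame with integer columns `drug`, `target` (1-based)
#' @param ppi data.frame with integer columns `target_a`, `target_b`
#' @param synergy data.frame with columns `drug_a`, `drug_b`, `cell_line`
#'   and a score column named by `score_type`
#' @param n_drugs,n_targets node counts (vocabulary sizes)
#' @param threshold scalar; a DD edge requires score > threshold (strict)
#' @param score_type which synergy score column to binarize
#' @param dd_source_pairs optional two-column matrix/data.frame of drug pairs
#'   allowed to contribute DD edges (e.g. the training-split pairs, so that
#'   held-out synergy labels never enter the graph). NULL means all pairs.
#' @return object of class `hetnet` with fields `n_drugs`, `n_targets`,
#'   `dti` (matrix drug,target), `ppi` (matrix, a < b), `dd` (matrix, a < b)
#' @export
build_hetnet <- function(dti, ppi, synergy, n_drugs, n_targets,
                         threshold = 0, score_type = "loewe",
                         dd_source_pairs = NULL) {
  dti_m <- unique(cbind(as.integer(dti$drug), as.integer(dti$target)))
  bad <- which(dti_m[, 1] < 1L | dti_m[, 1] > n_drugs |
                 dti_m[, 2] < 1L | dti_m[, 2] > n_targets)
  if (length(bad)) {
    stop("build_hetnet: DTI row references unknown node: row ",
         bad[1], " (drug=", dti_m[bad[1], 1], ", target=", dti_m[bad[1], 2], ")")
  }

  pa <- pmin(as.integer(ppi$target_a), as.integer(ppi$target_b))
  pb <- pmax(as.integer(ppi$target_a), as.integer(ppi$target_b))
  keep <- pa != pb
  ppi_m <- unique(cbind(pa[keep], pb[keep]))
  if (nrow(ppi_m) && (min(ppi_m) < 1L || max(ppi_m) > n_targets)) {
    stop("build_hetnet: PPI row references unknown target node")
  }

  scores <- synergy[[score_type]]
  if (is.null(scores)) stop("build_hetnet: no synergy column '", score_type, "'")
  if (any(!is.finite(scores))) {
    stop("build_hetnet: non-finite synergy score at row ",
         which(!is.finite(scores))[1])
  }
  da <- as.integer(synergy$drug_a); db <- as.integer(synergy$drug_b)
  if (any(da < 1L | da > n_drugs | db < 1L | db > n_drugs)) {
    stop("build_hetnet: synergy row references unknown drug node")
  }
  in_scope <- rep(TRUE, nrow(synergy))
  if (!is.null(dd_source_pairs)) {
    allowed <- pair_key(as.integer(dd_source_pairs[[1]]),
                        as.integer(dd_source_pairs[[2]]))
    in_scope <- pair_key(da, db) %in% allowed
  }
  hit <- in_scope & scores > threshold & da != db
  dd_m <- unique(cbind(pmin(da[hit], db[hit]), pmax(da[hit], db[hit])))
  if (!nrow(dd_m)) dd_m <- matrix(integer(0), 0, 2)

  structure(list(
    n_drugs = as.integer(n_drugs),
    n_targets = as.integer(n_targets),
    dti = dti_m,
    ppi = ppi_m,
    dd = dd_m
  ), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("Heterogeneous therapeutic-effect network\n")
  cat("  drugs:   ", x$n_drugs, "\n")
  cat("  targets: ", x$n_targets, "\n")
  cat("  edges:   ", nrow(x$dti), "DTI,", nrow(x$ppi), "PPI,",
      nrow(x$dd), "DD\n")
  invisible(x)
}

#' Load the tabular inputs of a dataset directory
#'
#' Reads the tab-delimited files `dti.tsv`, `ppi.tsv`, `synergy.tsv`,
#' `ae.tsv`, `expression.tsv` and `chem.tsv` (all with header lines),
#' maps string identifiers to dense 1-based integer indices per node type,
#' and returns typed tables plus the name maps.
#'
#' @param dir directory containing the six files
#' @return list with elements `dti`, `ppi`, `synergy`, `ae`, `expression`
#'   (matrix, rows = cell lines), `chem` (matrix, rows = drugs), and
#'   `maps` (character vectors `drugs`, `targets`, `cell_lines`: index -> name)
#' @export
load_tables <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("load_tables: missing file ", path)
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  dti_raw <- rd("dti.tsv")
  ppi_raw <- rd("ppi.tsv")
  syn_raw <- rd("synergy.tsv")
  ae_raw <- rd("ae.tsv")
  expr_raw <- rd("expression.tsv")
  chem_raw <- rd("chem.tsv")

  need <- function(tab, cols, f) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) stop("load_tables: ", f, " missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(dti_raw, c("drug", "target"), "dti.tsv")
  need(ppi_raw, c("target_a", "target_b"), "ppi.tsv")
  need(syn_raw, c("drug_a", "drug_b", "cell_line", "loewe", "bliss", "hsa", "zip"),
       "synergy.tsv")
  need(ae_raw, c("drug_a", "drug_b"), "ae.tsv")
  need(chem_raw, "drug", "chem.tsv")
  need(expr_raw, "cell_line", "expression.tsv")

  drugs <- sort(unique(c(dti_raw$drug, syn_raw$drug_a, syn_raw$drug_b,
                         ae_raw$drug_a, ae_raw$drug_b, chem_raw$drug)))
  targets <- sort(unique(c(dti_raw$target, ppi_raw$target_a, ppi_raw$target_b)))
  cells <- sort(unique(c(syn_raw$cell_line, expr_raw$cell_line)))
  dmap <- stats::setNames(seq_along(drugs), drugs)
  tmap <- stats::setNames(seq_along(targets), targets)
  cmap <- stats::setNames(seq_along(cells), cells)

  dup <- duplicated(paste(pair_key(dmap[syn_raw$drug_a], dmap[syn_raw$drug_b]),
                          cmap[syn_raw$cell_line]))
  if (any(dup)) {
    stop("load_tables: duplicate synergy row for (",
         syn_raw$drug_a[which(dup)[1]], ", ", syn_raw$drug_b[which(dup)[1]],
         ", ", syn_raw$cell_line[which(dup)[1]], ") at row ", which(dup)[1])
  }

  ae_cols <- grep("^ae_", names(ae_raw), value = TRUE)
  if (!length(ae_cols)) stop("load_tables: ae.tsv has no ae_* columns")
  ae_mat <- as.matrix(ae_raw[, ae_cols, drop = FALSE])
  bad_ae <- which(!apply(ae_mat, 1, function(r) all(!is.na(r) & r %in% c(0, 1))))
  if (length(bad_ae)) {
    stop("load_tables: ae.tsv row ", bad_ae[1],
         " has a missing or non-binary label")
  }

  expr_mat <- as.matrix(expr_raw[, setdiff(names(expr_raw), "cell_line"),
                                 drop = FALSE])
  rownames(expr_mat) <- expr_raw$cell_line
  if (!all(names(cmap) %in% rownames(expr_mat))) {
    stop("load_tables: expression.tsv missing cell line(s): ",
         paste(setdiff(names(cmap), rownames(expr_mat)), collapse = ", "))
  }
  expr_mat <- expr_mat[names(cmap), , drop = FALSE]

  chem_mat <- as.matrix(chem_raw[, setdiff(names(chem_raw), "drug"),
                                 drop = FALSE])
  rownames(chem_mat) <- chem_raw$drug
  if (!all(names(dmap) %in% rownames(chem_mat))) {
    stop("load_tables: chem.tsv missing drug(s): ",
         paste(setdiff(names(dmap), rownames(chem_mat)), collapse = ", "))
  }
  chem_mat <- chem_mat[names(dmap), , drop = FALSE]

  list(
    dti = data.frame(drug = unname(dmap[dti_raw$drug]),
                     target = unname(tmap[dti_raw$target])),
    ppi = data.frame(target_a = unname(tmap[ppi_raw$target_a]),
                     target_b = unname(tmap[ppi_raw$target_b])),
    synergy = data.frame(drug_a = unname(dmap[syn_raw$drug_a]),
                         drug_b = unname(dmap[syn_raw$drug_b]),
                         cell_line = unname(cmap[syn_raw$cell_line]),
                         loewe = syn_raw$loewe, bliss = syn_raw$bliss,
                         hsa = syn_raw$hsa, zip = syn_raw$zip),
    ae = cbind(data.frame(drug_a = unname(dmap[ae_raw$drug_a]),
                          drug_b = unname(dmap[ae_raw$drug_b])),
               as.data.frame(ae_mat)),
    expression = expr_mat,
    chem = chem_mat,
    maps = list(drugs = drugs, targets = targets, cell_lines = cells)
  )
}

#' Assemble sample triples from loaded tables
#'
#' Joins each synergy row with its pair's adverse-effect label vector.
#' Pairs without an AE row get all-zero labels.
#'
#' @param tables result of [load_tables()] or [generate_synth_data()]
#' @param score_type one of "loewe", "bliss", "hsa", "zip"
#' @return data.frame with drug_a, drug_b, cell_line, synergy and ae matrix
#'   attached as attribute "ae_labels" (one row per triple)
#' @export
make_triples <- function(tables, score_type = "loewe") {
  syn <- tables$synergy
  ae <- tables$ae
  ae_cols <- grep("^ae_", names(ae), value = TRUE)
  key_tr <- pair_key(syn$drug_a, syn$drug_b)
  key_ae <- pair_key(ae$drug_a, ae$drug_b)
  idx <- match(key_tr, key_ae)
  lab <- matrix(0, nrow(syn), length(ae_cols))
  hit <- !is.na(idx)
  lab[hit, ] <- as.matrix(ae[idx[hit], ae_cols, drop = FALSE])
  out <- data.frame(drug_a = syn$drug_a, drug_b = syn$drug_b,
                    cell_line = syn$cell_line,
                    synergy = syn[[score_type]])
  if (any(!is.finite(out$synergy))) stop("make_triples: non-finite synergy score")
  if (any(out$drug_a == out$drug_b)) stop("make_triples: self-pair triple")
  attr(out, "ae_labels") <- lab
  out
}
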