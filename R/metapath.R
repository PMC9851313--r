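# Meta-path schemas and instance enumeration.
#
# The four wired-in schemas over the heterogeneous network are
#   DTD    drug - target - drug            (shared target)
#   DTTD   drug - target - target - drug   (interacting targets)
#   DTTTD  drug - target - target - target - drug (bridged targets)
#   DD     drug - drug                     (therapeutic-effect edge)
# An instance is a concrete node sequence conforming to a schema, read from
# the start (source) drug to the end (central) drug. Instance sets are kept
# as integer matrices (one row per instance) in deterministic lexicographic
# order so that seeded subsampling is reproducible.

SCHEMA_NAMES <- c("DTD", "DTTD", "DTTTD", "DD")

#' Meta-path schema descriptor
#'
#' @param name one of "DTD", "DTTD", "DTTTD", "DD"
#' @return object of class `metapath_schema` with `name`, `node_types`
#'   (character vector of "D"/"T" per position) and `edge_types`
#' @export
metapath_schema <- function(name) {
  name <- match.arg(name, SCHEMA_NAMES)
  node_types <- strsplit(name, "")[[1]]
  edge_types <- vapply(seq_len(length(node_types) - 1L), function(i) {
    et <- paste0(node_types[i], node_types[i + 1L])
    switch(et, DT = "DTI", TD = "DTI", TT = "PPI", DD = "DD")
  }, character(1))
  structure(list(name = name, node_types = node_types,
                 edge_types = edge_types),
            class = "metapath_schema")
}

# adjacency as edge data.frames in both directions for joins
.edges_by_type <- function(net) {
  dti <- data.frame(d = net$dti[, 1], t = net$dti[, 2])
  ppi <- rbind(data.frame(a = net$ppi[, 1], b = net$ppi[, 2]),
               data.frame(a = net$ppi[, 2], b = net$ppi[, 1]))
  dd <- rbind(data.frame(a = net$dd[, 1], b = net$dd[, 2]),
              data.frame(a = net$dd[, 2], b = net$dd[, 1]))
  list(dti = dti, ppi = ppi, dd = dd)
}

#' Enumerate meta-path instances
#'
#' Returns every node sequence conforming to `schema` that ends at
#' `end_drug` (or at any drug if `end_drug` is NULL). Sequences are simple
#' over the target positions (no repeated node within an instance) and the
#' start drug differs from the end drug unless `allow_self = TRUE`. Rows are
#' ordered lexicographically by node indices, so enumeration is
#' deterministic.
#'
#' @param net a [build_hetnet()] network
#' @param schema a [metapath_schema()] or schema name
#' @param end_drug optional 1-based drug index to restrict the central drug
#' @param allow_self include degenerate instances with identical endpoints
#' @return object of class `metapath_instances`: list with `schema`,
#'   `nodes` (integer matrix, one instance per row, columns = positions,
#'   last column is the central drug) — possibly 0 rows
#' @export
enumerate_instances <- function(net, schema, end_drug = NULL,
                                allow_self = FALSE) {
  if (is.character(schema)) schema <- metapath_schema(schema)
  ed <- .edges_by_type(net)
  nm <- schema$name

  paths <- switch(nm,
    DD = {
      m <- ed$dd
      data.frame(p1 = m$a, p2 = m$b)
    },
    DTD = {
      x <- merge(ed$dti, ed$dti, by = "t", suffixes = c("1", "2"))
      data.frame(p1 = x$d1, p2 = x$t, p3 = x$d2)
    },
    DTTD = {
      # D - T1, T1 - T2 (PPI), T2 - D'
      x <- merge(data.frame(p1 = ed$dti$d, p2 = ed$dti$t),
                 data.frame(p2 = ed$ppi$a, p3 = ed$ppi$b), by = "p2")
      x <- merge(x, data.frame(p3 = ed$dti$t, p4 = ed$dti$d), by = "p3")
      x[x$p2 != x$p3, c("p1", "p2", "p3", "p4")]
    },
    DTTTD = {
      x <- merge(data.frame(p1 = ed$dti$d, p2 = ed$dti$t),
                 data.frame(p2 = ed$ppi$a, p3 = ed$ppi$b), by = "p2")
      x <- merge(x, data.frame(p3 = ed$ppi$a, p4 = ed$ppi$b), by = "p3")
      x <- merge(x, data.frame(p4 = ed$dti$t, p5 = ed$dti$d), by = "p4")
      ok <- x$p2 != x$p3 & x$p3 != x$p4 & x$p2 != x$p4
      x[ok, c("p1", "p2", "p3", "p4", "p5")]
    }
  )
  last <- length(schema$node_types)
  if (nrow(paths)) {
    if (!allow_self) paths <- paths[paths[[1]] != paths[[last]], , drop = FALSE]
    if (!is.null(end_drug)) {
      paths <- paths[paths[[last]] == end_drug, , drop = FALSE]
    }
  }
  m <- as.matrix(paths)
  dimnames(m) <- NULL
  if (!nrow(m)) m <- matrix(integer(0), 0, last)
  # lexicographic order over all positions
  if (nrow(m) > 1L) {
    m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  }
  structure(list(schema = schema, nodes = m), class = "metapath_instances")
}

#' @export
print.metapath_instances <- function(x, ...) {
  cat("Meta-path instances (", x$schema$name, "): ", nrow(x$nodes),
      " instance(s)\n", sep = "")
  invisible(x)
}

#' Restrict and subsample DTTTD instances
#'
#' The bridging (middle) target of a DTTTD instance must itself be a drug
#' target somewhere in the network; instances failing this are removed.
#' The remainder is uniformly subsampled without replacement to
#' `ceiling(ratio * n)` instances using `seed`, which caps the otherwise
#' exponential growth of length-5 paths.
#'
#' @param instances `metapath_instances` with schema DTTTD
#' @param net the network the instances came from
#' @param ratio sampling fraction in (0, 1]; 1 keeps all restricted
#'   instances in their original order
#' @param seed integer RNG seed making the draw reproducible
#' @return `metapath_instances` with the restricted, sampled rows
#' @export
restrict_and_sample_dtttd <- function(instances, net, ratio = 0.5,
                                      seed = 1L) {
  stopifnot(inherits(instances, "metapath_instances"))
  if (instances$schema$name != "DTTTD") {
    stop("restrict_and_sample_dtttd: schema is ", instances$schema$name,
         ", expected DTTTD")
  }
  stopifnot(ratio > 0, ratio <= 1)
  m <- instances$nodes
  targeted <- unique(net$dti[, 2])
  m <- m[m[, 3] %in% targeted, , drop = FALSE]
  n <- nrow(m)
  if (ratio < 1 && n > 0L) {
    k <- ceiling(ratio * n)
    keep <- withr::with_seed(as.integer(seed), sort(sample.int(n, k)))
    m <- m[keep, , drop = FALSE]
  }
  structure(list(schema = instances$schema, nodes = m),
            class = "metapath_instances")
}

#' Tensorize an instance set
#'
#' Turns instances into the 3-D feature array consumed by the aggregators:
#' each node contributes its type-specific one-hot vector mapped through the
#' type's transformation matrix to the shared dimension, i.e. the node's row
#' of that matrix.
#'
#' @param instances `metapath_instances`
#' @param transforms list with matrices `D` (n_drugs x d') and
#'   `T` (n_targets x d')
#' @return 3-D array (instance, position, feature)
#' @export
tensorize <- function(instances, transforms) {
  stopifnot(inherits(instances, "metapath_instances"))
  d_prime <- ncol(transforms$D)
  if (ncol(transforms$T) != d_prime) {
    stop("tensorize: transforms must share one output dimension")
  }
  types <- instances$schema$node_types
  m <- instances$nodes
  out <- array(0, dim = c(nrow(m), length(types), d_prime))
  for (p in seq_along(types)) {
    w <- if (types[p] == "D") transforms$D else transforms$T
    if (max(m[, p], 0L) > nrow(w)) {
      stop("tensorize: node index exceeds transform rows at position ", p)
    }
    if (nrow(m)) out[, p, ] <- w[m[, p], , drop = FALSE]
  }
  out
}

#' Export instance sets to TSV
#'
#' Writes one file per (drug, schema) with one instance per row as
#' tab-separated node names, for external inspection of shared
#' mechanism-of-action paths between drugs of a pair.
#'
#' @param net network
#' @param maps name maps from [load_tables()]
#' @param drugs integer drug indices to export
#' @param dir output directory
#' @param dtttd_ratio,seed passed to [restrict_and_sample_dtttd()]
#' @return invisible character vector of written paths
#' @export
export_instances <- function(net, maps, drugs, dir, dtttd_ratio = 0.5,
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (d in drugs) {
    for (s in SCHEMA_NAMES) {
      inst <- enumerate_instances(net, s, end_drug = d)
      if (s == "DTTTD") {
        inst <- restrict_and_sample_dtttd(inst, net, dtttd_ratio, seed)
      }
      m <- inst$nodes
      types <- inst$schema$node_types
      named <- vapply(seq_len(nrow(m)), function(i) {
        paste(vapply(seq_along(types), function(p) {
          if (types[p] == "D") maps$drugs[m[i, p]] else maps$targets[m[i, p]]
        }, character(1)), collapse = "\t")
      }, character(1))
      f <- file.path(dir, paste0(maps$drugs[d], "_", s, ".tsv"))
      writeLines(c(paste(paste0("node_", seq_along(types)), collapse = "\t"),
                   named), f)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Build the per-drug instance index used by the encoder
#'
#' Enumerates all four schemas for every drug, applies the DTTTD
#' restriction/sampling once per run, and returns compact index structures.
#'
#' @param net network
#' @param dtttd_ratio,seed DTTTD subsampling controls
#' @param allow_self passed to [enumerate_instances()]
#' @return list per schema name: list(nodes = integer matrix, group =
#'   central-drug index per row)
#' @keywords internal
build_instance_index <- function(net, dtttd_ratio = 0.5, seed = 1L,
                                 allow_self = FALSE) {
  out <- list()
  for (s in SCHEMA_NAMES) {
    inst <- enumerate_instances(net, s, end_drug = NULL,
                                allow_self = allow_self)
    if (s == "DTTTD") {
      inst <- restrict_and_sample_dtttd(inst, net, dtttd_ratio, seed)
    }
    m <- inst$nodes
    out[[s]] <- list(nodes = m,
                     group = if (nrow(m)) m[, ncol(m)] else integer(0),
                     schema = inst$schema)
  }
  out
}
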