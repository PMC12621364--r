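#' Project methylation profiles onto graph nodes
#'
#' Each cytosine site of each haplotype profile is located inside
#' exactly one node of its own path (the graph should be chopped so
#' nodes are comparable window units).  Per node and haplotype the
#' matrix records whether the node carries a cytosine and whether it is
#' methylated — at least one site whose across-clone mean level reaches
#' `meth_threshold`.
#'
#' @param graph a chopped `sequence_graph`.
#' @param profiles named list path -> `united_profile` (path
#'   coordinates, 1-based positions).
#' @param meth_threshold site methylation threshold in percent
#'   (default 20, inclusive).
#' @return an object of class `node_meth_matrix`: list with `presence`
#'   (`data.table` node/path for every path step) and `cyto`
#'   (`data.table` node/path/n_sites/methylated for cytosine-carrying
#'   node-haplotype pairs).
#' @export
assign_sites_to_nodes <- function(graph, profiles, meth_threshold = 20) {
  presence <- data.table::rbindlist(lapply(names(graph$paths), function(pn) {
    data.table::data.table(node = unique(graph$paths[[pn]]$node), path = pn)
  }))
  cyto <- list()
  for (pn in names(profiles)) {
    prof <- profiles[[pn]]
    idx <- path_index(graph, pn)
    if (nrow(prof) == 0L) next
    pos0 <- prof$pos - 1L
    stop_if(any(pos0 < 0 | pos0 >= idx$path_length),
            sprintf("profile site beyond path length on '%s'", pn))
    step <- findInterval(pos0, idx$start)
    dt <- data.table::data.table(node = idx$node[step],
                                 meth = site_methylated(prof$level_mean,
                                                        meth_threshold))
    cyto[[pn]] <- dt[, list(n_sites = .N, methylated = any(meth)),
                     by = "node"]
    cyto[[pn]]$path <- pn
  }
  cyto <- if (length(cyto)) data.table::rbindlist(cyto, use.names = TRUE)
    else data.table::data.table(node = character(), n_sites = integer(),
                                methylated = logical(), path = character())
  structure(list(presence = presence, cyto = cyto),
            class = "node_meth_matrix")
}

#' Classify graph nodes by haplotype sharing
#'
#' Nodes carrying at least one cytosine (in any haplotype) are
#' classified from their sharing set: the haplotypes whose path contains
#' the node (`mode = "presence"`), or the haplotypes in which the node
#' is methylated (`mode = "methylation"`).  `presence_class` is `core`
#' when the set covers all six haplotypes, `private` when it touches a
#' single cultivar and `dispensable` otherwise; `cultivar_class` is
#' `all` (all haplotypes), `intra` (one cultivar) or `inter` (more than
#' one cultivar but not all haplotypes).  Nodes whose sharing set is
#' empty under the chosen mode are excluded and counted in the
#' `"n_excluded"` attribute.
#'
#' @param matrix a `node_meth_matrix`.
#' @param mode `"presence"` or `"methylation"`.
#' @param all_haplotypes the full haplotype set (defaults to the six
#'   trio haplotypes; pass path names when chromosomes are suffixed).
#' @return `data.table` with `node`, `haps` (sorted `+`-separated
#'   combination), `n_haps`, `n_cultivars`, `presence_class`,
#'   `cultivar_class`.
#' @export
classify_nodes <- function(matrix, mode = c("presence", "methylation"),
                           all_haplotypes = NULL) {
  mode <- match.arg(mode)
  cyto_nodes <- unique(matrix$cyto$node)
  share <- if (mode == "presence") {
    matrix$presence[matrix$presence$node %in% cyto_nodes, ]
  } else {
    m <- matrix$cyto[matrix$cyto$methylated, c("node", "path"), with = FALSE]
    m
  }
  # combinations are named by haplotype (any #chr suffix stripped): a
  # node lives on one chromosome, so haplotype and path are 1:1 for it
  universe <- all_haplotypes %||%
    unique(sub("#.*$", "", matrix$presence$path))
  n_universe <- length(universe)
  share <- data.table::copy(share)
  share$hap <- sub("#.*$", "", share$path)
  node <- hap <- NULL  # data.table NSE
  cls <- share[, list(haps = paste(sort(unique(hap)), collapse = "+"),
                      n_haps = length(unique(hap)),
                      n_cultivars =
                        length(unique(haplotype_cultivar(hap)))),
               by = "node"]
  cls$presence_class <- ifelse(cls$n_haps == n_universe, "core",
                               ifelse(cls$n_cultivars == 1L, "private",
                                      "dispensable"))
  cls$cultivar_class <- ifelse(cls$n_haps == n_universe, "all",
                               ifelse(cls$n_cultivars == 1L, "intra",
                                      "inter"))
  excluded <- setdiff(cyto_nodes, cls$node)
  data.table::setattr(cls, "n_excluded", length(excluded))
  data.table::setattr(cls, "mode", mode)
  cls
}

#' Summarise node classifications
#'
#' Counts nodes per haplotype combination (descending, ties broken by
#' combination name) and per cultivar class.
#'
#' @param classifications output of [classify_nodes()].
#' @return list with `combinations` and `cultivar_class` count tables.
#' @export
node_class_summary <- function(classifications) {
  haps <- cultivar_class <- NULL
  comb <- classifications[, list(count = .N), by = "haps"]
  comb <- comb[order(-comb$count, comb$haps), ]
  cc <- classifications[, list(count = .N), by = "cultivar_class"]
  cc <- cc[order(-cc$count, cc$cultivar_class), ]
  list(combinations = comb, cultivar_class = cc)
}

#' Pairwise methylated-node sharing counts
#'
#' For every pair of haplotypes, the number of classified nodes shared
#' under the chosen mode — the quantity behind the parent-progeny
#' methylation-sharing signal (a progeny haplotype shares more
#' methylated nodes with its source parental haplotype than the two
#' haplotypes of that parent share with each other).
#'
#' @param matrix a `node_meth_matrix`.
#' @param mode `"presence"` or `"methylation"`.
#' @return symmetric named matrix of shared-node counts.
#' @export
pairwise_node_sharing <- function(matrix, mode = c("presence", "methylation")) {
  mode <- match.arg(mode)
  tab <- if (mode == "presence") {
    matrix$presence[matrix$presence$node %in% unique(matrix$cyto$node), ]
  } else {
    matrix$cyto[matrix$cyto$methylated, c("node", "path"), with = FALSE]
  }
  paths <- sort(unique(matrix$presence$path))
  inc <- table(tab$node, factor(tab$path, levels = paths)) > 0
  crossprod(inc * 1L)
}
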