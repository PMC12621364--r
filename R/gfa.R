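#' Read a sequence graph from GFA v1
#'
#' Parses `S` (segment), `L` (link) and `P` (path) records.  `W` (walk)
#' records from GFA 1.1 are accepted and normalised to paths named
#' `sample#haplotype#seqid` (components that are `*` are dropped).
#' Unknown record types are ignored.  Links are optional; edges are
#' completed from consecutive path steps.
#'
#' @param file path to a GFA file.
#' @return a `sequence_graph`.
#' @export
read_gfa <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rectype <- substr(lines, 1L, 1L)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  bad <- function(i, why) {
    stop(sprintf("malformed GFA line %d (%s): %s", i, why,
                 substr(lines[i], 1, 60)), call. = FALSE)
  }

  field <- function(idx, k, why) {
    vapply(idx, function(i) {
      f <- fields[[i]]
      if (length(f) < k) bad(i, why)
      f[[k]]
    }, character(1))
  }

  s_idx <- which(rectype == "S")
  node_names <- field(s_idx, 2L, "S record needs id and sequence")
  nodes <- field(s_idx, 3L, "S record needs id and sequence")
  names(nodes) <- node_names
  stop_if(anyDuplicated(node_names) > 0, "duplicated segment ids in GFA")

  l_idx <- which(rectype == "L")
  edges <- NULL
  if (length(l_idx)) {
    edges <- data.frame(from = field(l_idx, 2L, "L record needs 4 fields"),
                        from_orient = field(l_idx, 3L, "L record needs 4 fields"),
                        to = field(l_idx, 4L, "L record needs 4 fields"),
                        to_orient = field(l_idx, 5L, "L record needs 4 fields"))
  }

  paths <- list()
  for (i in which(rectype == "P")) {
    f <- fields[[i]]
    if (length(f) < 3L) bad(i, "P record needs name and steps")
    steps <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
    if (!all(grepl("[+-]$", steps))) bad(i, "P steps need +/- orientations")
    paths[[f[2L]]] <- steps
  }
  for (i in which(rectype == "W")) {
    f <- fields[[i]]
    if (length(f) < 7L) bad(i, "W record needs 6 fields")
    nm <- paste(setdiff(f[2L:4L], "*"), collapse = "#")
    segs <- regmatches(f[7L], gregexpr("[<>][^<>]+", f[7L]))[[1L]]
    if (length(segs) == 0L) bad(i, "empty walk")
    orient <- ifelse(substr(segs, 1L, 1L) == ">", "+", "-")
    paths[[nm]] <- paste0(substring(segs, 2L), orient)
  }
  for (nm in names(paths)) {
    ids <- sub("[+-]$", "", paths[[nm]])
    missing <- setdiff(ids, node_names)
    stop_if(length(missing) > 0,
            sprintf("path '%s' references unknown node '%s'",
                    nm, missing[1L]))
  }
  if (!is.null(edges)) edges <- unique(edges)
  sequence_graph(nodes, paths, edges = edges)
}

#' Write a sequence graph as GFA v1
#'
#' Emits an `H` header, `S` records in node order, `L` records for every
#' edge and one `P` record per path.  `write_gfa` followed by
#' [read_gfa()] reconstructs an equal graph.
#'
#' @param graph a `sequence_graph`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gfa <- function(graph, file) {
  s <- sprintf("S\t%s\t%s", names(graph$nodes), graph$nodes)
  l <- character()
  if (nrow(graph$edges))
    l <- sprintf("L\t%s\t%s\t%s\t%s\t0M", graph$edges$from,
                 graph$edges$from_orient, graph$edges$to,
                 graph$edges$to_orient)
  p <- vapply(names(graph$paths), function(nm) {
    st <- graph$paths[[nm]]
    sprintf("P\t%s\t%s\t*", nm, paste0(st$node, st$orient, collapse = ","))
  }, character(1))
  writeLines(c("H\tVN:Z:1.0", s, l, p), file)
  invisible(file)
}
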