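#' Sequence graph with named haplotype paths
#'
#' A `sequence_graph` is the coordinate backbone for all cross-haplotype
#' comparison: a set of DNA segments ("nodes"), the adjacencies between
#' them, and one named, oriented walk ("path") per haplotype that spells
#' that haplotype's sequence.
#'
#' @param nodes named character vector; names are node ids, values are
#'   non-empty DNA sequences over the alphabet ACGTN.
#' @param paths named list; each element is a `data.frame` with columns
#'   `node` (node id) and `orient` (`"+"` or `"-"`), or a character
#'   vector of steps such as `c("1+", "2-")`.
#' @param edges optional `data.frame` with columns `from`, `from_orient`,
#'   `to`, `to_orient`.  When `NULL`, edges are inferred from consecutive
#'   path steps.
#' @param validate check invariants (paths reference existing nodes,
#'   consecutive steps have an edge, node alphabet).
#' @return an object of class `sequence_graph` with elements `nodes`,
#'   `edges` and `paths`.
#' @export
sequence_graph <- function(nodes, paths, edges = NULL, validate = TRUE) {
  stop_if(is.null(names(nodes)) || anyDuplicated(names(nodes)) > 0,
          "nodes must be a uniquely named character vector")
  nodes <- toupper(nodes)
  paths <- lapply(paths, normalize_path_steps)
  stop_if(is.null(names(paths)) && length(paths) > 0,
          "paths must be a named list")
  inferred <- infer_edges(paths)
  if (is.null(edges)) {
    edges <- inferred
  } else {
    edges <- unique(rbind(edges[, c("from", "from_orient", "to", "to_orient")],
                          inferred))
  }
  g <- structure(list(nodes = nodes, edges = edges, paths = paths),
                 class = "sequence_graph")
  if (validate) validate_graph(g)
  g
}

normalize_path_steps <- function(p) {
  if (is.character(p)) {
    orient <- substr(p, nchar(p), nchar(p))
    node <- substr(p, 1L, nchar(p) - 1L)
    p <- data.frame(node = node, orient = orient)
  }
  stop_if(!all(c("node", "orient") %in% names(p)),
          "path steps need 'node' and 'orient' columns")
  data.frame(node = as.character(p$node), orient = as.character(p$orient))
}

infer_edges <- function(paths) {
  rows <- lapply(paths, function(p) {
    n <- nrow(p)
    if (n < 2L) return(NULL)
    data.frame(from = p$node[-n], from_orient = p$orient[-n],
               to = p$node[-1L], to_orient = p$orient[-1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(from = character(), from_orient = character(),
                      to = character(), to_orient = character())
  unique(out)
}

validate_graph <- function(g) {
  stop_if(any(nchar(g$nodes) == 0L), "node sequences must be non-empty")
  stop_if(any(grepl("[^ACGTN]", g$nodes)),
          "node sequences must be over the alphabet ACGTN")
  for (nm in names(g$paths)) {
    p <- g$paths[[nm]]
    missing <- setdiff(p$node, names(g$nodes))
    stop_if(length(missing) > 0,
            sprintf("path '%s' references unknown node(s): %s",
                    nm, paste(utils::head(missing, 3), collapse = ", ")))
    stop_if(!all(p$orient %in% c("+", "-")),
            sprintf("path '%s' has invalid orientations", nm))
  }
  invisible(g)
}

#' @export
print.sequence_graph <- function(x, ...) {
  cat(sprintf("sequence_graph: %d nodes (%s bp), %d edges, %d paths\n",
              length(x$nodes), format(sum(nchar(x$nodes)), big.mark = ","),
              nrow(x$edges), length(x$paths)))
  if (length(x$paths))
    cat("paths:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two sequence graphs for equality
#'
#' Graphs are equal when they hold the same nodes, the same edge set
#' (order-independent) and the same paths.
#'
#' @param a,b `sequence_graph` objects.
#' @return logical scalar.
#' @export
graph_equal <- function(a, b) {
  key <- function(e) sort(paste(e$from, e$from_orient, e$to, e$to_orient))
  identical(a$nodes[sort(names(a$nodes))], b$nodes[sort(names(b$nodes))]) &&
    identical(key(a$edges), key(b$edges)) &&
    identical(names(a$paths), names(b$paths)) &&
    all(vapply(names(a$paths), function(nm) {
      identical(a$paths[[nm]]$node, b$paths[[nm]]$node) &&
        identical(a$paths[[nm]]$orient, b$paths[[nm]]$orient)
    }, logical(1)))
}

# per-path positional index: node, orient, len, start (0-based), path length
path_index <- function(graph, path_name) {
  p <- graph$paths[[path_name]]
  stop_if(is.null(p), sprintf("unknown path '%s'", path_name))
  len <- nchar(graph$nodes[p$node])
  names(len) <- NULL
  start <- cumsum(c(0L, len))[seq_along(len)]
  list(node = p$node, orient = p$orient, len = len, start = start,
       path_length = sum(len))
}

#' Spell the sequence of a haplotype path
#'
#' Concatenates node sequences along the path, reverse-complementing
#' nodes traversed in the `-` orientation.
#'
#' @param graph a `sequence_graph`.
#' @param path_name path to spell.
#' @return a single DNA string.
#' @export
path_sequence <- function(graph, path_name) {
  p <- graph$paths[[path_name]]
  stop_if(is.null(p), sprintf("unknown path '%s'", path_name))
  seqs <- graph$nodes[p$node]
  flip <- p$orient == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  paste(seqs, collapse = "")
}

#' Lengths of all paths in a graph
#'
#' @param graph a `sequence_graph`.
#' @return named integer vector of path lengths in bp.
#' @export
path_lengths <- function(graph) {
  vapply(names(graph$paths), function(nm) {
    sum(nchar(graph$nodes[graph$paths[[nm]]$node]))
  }, numeric(1))
}

#' Chop graph nodes to a maximum length
#'
#' Splits every node longer than `max_len` into consecutive pieces of at
#' most `max_len` bp, in 5'-to-3' node order, rewiring all paths so that
#' every path sequence is preserved byte-for-byte.  Chopping to short
#' nodes gives the windowed unit used for node-level methylation
#' comparison across haplotypes.
#'
#' @param graph a `sequence_graph`.
#' @param max_len maximum node length in bp (default 200).
#' @return a new `sequence_graph`; the attribute `"chop_map"` holds a
#'   named list mapping every old node id to its ordered new node ids.
#' @export
chop_nodes <- function(graph, max_len = 200) {
  stop_if(max_len < 1, "max_len must be >= 1")
  lens <- nchar(graph$nodes)
  ids <- names(graph$nodes)
  chop_map <- vector("list", length(ids))
  names(chop_map) <- ids
  new_nodes <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    L <- lens[[i]]
    if (L <= max_len) {
      chop_map[[i]] <- ids[[i]]
      new_nodes[[i]] <- stats::setNames(graph$nodes[[i]], ids[[i]])
    } else {
      starts <- seq(1L, L, by = max_len)
      ends <- pmin(starts + max_len - 1L, L)
      pieces <- substring(graph$nodes[[i]], starts, ends)
      pid <- paste0(ids[[i]], ".", seq_along(pieces))
      chop_map[[i]] <- pid
      new_nodes[[i]] <- stats::setNames(pieces, pid)
    }
  }
  nodes <- unlist(new_nodes)
  paths <- lapply(graph$paths, function(p) {
    reps <- chop_map[p$node]
    # a '-' traversal walks the pieces 3'->5'
    reps <- mapply(function(r, o) if (o == "-") rev(r) else r,
                   reps, p$orient, SIMPLIFY = FALSE)
    n_rep <- lengths(reps)
    data.frame(node = unlist(reps, use.names = FALSE),
               orient = rep(p$orient, n_rep))
  })
  g <- sequence_graph(nodes, paths, validate = FALSE)
  attr(g, "chop_map") <- chop_map
  g
}

#' Project positions between haplotype paths via shared nodes
#'
#' A position on the source path is located inside a node; when that
#' node occurs exactly once on the target path, the position is carried
#' over (within-node offset mirrored if the traversal orientations
#' differ).  Positions inside nodes absent from the target, or inside
#' nodes occurring more than once on the target (ambiguous), project to
#' `NA`.
#'
#' @param graph a `sequence_graph` (typically chopped).
#' @param source,target path names.
#' @param pos integer vector of 0-based positions on the source path.
#' @return integer vector of 0-based target positions (`NA` where
#'   unprojectable).
#' @export
project_positions <- function(graph, source, pos, target) {
  is_ <- path_index(graph, source)
  it <- path_index(graph, target)
  stop_if(any(pos < 0 | pos >= is_$path_length),
          sprintf("position out of range for path '%s'", source))
  step <- findInterval(pos, is_$start)
  node <- is_$node[step]
  offset <- pos - is_$start[step]
  orient_s <- is_$orient[step]
  # single-copy lookup on the target
  tt <- table(it$node)
  single <- names(tt)[tt == 1L]
  tpos <- match(node, it$node)
  ok <- node %in% single & !is.na(tpos)
  out <- rep(NA_integer_, length(pos))
  if (any(ok)) {
    j <- tpos[ok]
    same <- orient_s[ok] == it$orient[j]
    off2 <- ifelse(same, offset[ok], is_$len[step[ok]] - 1L - offset[ok])
    out[ok] <- it$start[j] + off2
  }
  out
}

#' @rdname project_positions
#' @param ... passed on to [project_positions()].
#' @export
project_position <- function(graph, source, pos, target, ...) {
  project_positions(graph, source, pos, target, ...)[1L]
}
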