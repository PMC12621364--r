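#' Simulate the trio genomes and their sequence graph
#'
#' Mutates a random ancestral sequence into the four parental haplotypes
#' (CF1, CF2, SB1, SB2); the progeny haplotypes CSCF and CSSB are exact
#' copies of one CF and one SB haplotype respectively (the choice is
#' recorded in the returned `inheritance` map).  The graph is built
#' directly from the known variant table: shared ancestral segments
#' become nodes traversed by every path and alternate alleles become
#' branch nodes, so every path spells its haplotype sequence exactly and
#' all coordinate relations are known by construction.
#'
#' @param config a [trio_config()].
#' @return a list with elements `truth` (class `trio_truth`: per-path
#'   `sequences`, `anc_maps` (0-based ancestral coordinate of every
#'   haplotype base, `NA` for inserted bases), `variants`,
#'   `inheritance`, `bias_regions`, `chromosomes`, `config`) and `graph`
#'   (the unchopped `sequence_graph`).
#' @export
simulate_trio_genomes <- function(config) {
  stopifnot(inherits(config, "trio_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  inheritance <- c(CSCF = sample(c("CF1", "CF2"), 1L),
                   CSSB = sample(c("SB1", "SB2"), 1L))
  sv_chrom <- if (config$sv_count > 0)
    sample(chroms, config$sv_count, replace = TRUE) else character()

  node_seqs <- list()
  node_n <- 0L
  paths <- list()
  sequences <- list()
  anc_maps <- list()
  var_tabs <- list()
  bias_tabs <- list()

  for (ci in seq_len(n_chr)) {
    chrom <- chroms[ci]
    L <- config$chrom_length
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - config$gc_content) / 2, config$gc_content / 2,
                           config$gc_content / 2, (1 - config$gc_content) / 2))
    ev <- sample_chromosome_events(anc, config,
                                   n_sv = sum(sv_chrom == chrom))
    # progeny columns copy the inherited parental haplotype
    ev$CSCF <- ev[[inheritance[["CSCF"]]]]
    ev$CSSB <- ev[[inheritance[["CSSB"]]]]
    asm <- assemble_haplotypes(anc, ev, node_offset = node_n)
    node_n <- node_n + length(asm$node_seqs)
    node_seqs[[ci]] <- asm$node_seqs
    for (hap in TRIO_HAPLOTYPES) {
      pn <- trio_path_name(hap, chrom, n_chr)
      paths[[pn]] <- asm$paths[[hap]]
      sequences[[pn]] <- asm$sequences[[hap]]
      anc_maps[[pn]] <- asm$anc_maps[[hap]]
    }
    ev$chrom <- chrom
    var_tabs[[ci]] <- ev
    if (nrow(asm$bias_regions)) {
      asm$bias_regions$chrom <- chrom
      bias_tabs[[ci]] <- asm$bias_regions
    }
  }

  variants <- data.table::rbindlist(var_tabs)
  data.table::setcolorder(variants, c("chrom", "start", "ref_len", "ref",
                                      "alt", "type", "length", "planted_ct"))
  bias_regions <- if (length(bias_tabs)) data.table::rbindlist(bias_tabs)
    else data.table::data.table(chrom = character(), start = integer(),
                                end = integer())

  graph <- sequence_graph(unlist(node_seqs), paths)
  truth <- structure(list(sequences = sequences, anc_maps = anc_maps,
                          variants = variants, inheritance = inheritance,
                          bias_regions = bias_regions, chromosomes = chroms,
                          config = config),
                     class = "trio_truth")
  list(truth = truth, graph = graph)
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf(paste0("trio_truth: %d chromosome(s) x %s bp, %d variants; ",
                     "CSCF <- %s, CSSB <- %s\n"),
              length(x$chromosomes), format(x$config$chrom_length,
                                            big.mark = ","),
              nrow(x$variants), x$inheritance[["CSCF"]],
              x$inheritance[["CSSB"]]))
  invisible(x)
}

# Draw SNP/indel/SV events on one chromosome, plus planted C>T events in
# bias regions.  Returns a table sorted by ancestral start with one
# 0/1 alternate-allele indicator column per parental haplotype.
sample_chromosome_events <- function(anc, config, n_sv = 0) {
  L <- length(anc)
  bases <- c("A", "C", "G", "T")
  ev <- list()

  add <- function(start, ref_len, ref, alt, type, planted) {
    ev[[length(ev) + 1L]] <<- data.table::data.table(
      start = as.integer(start), ref_len = as.integer(ref_len),
      ref = ref, alt = alt, type = type,
      length = as.integer(ifelse(type == "SNP", 1L,
                                 abs(nchar(alt) - nchar(ref)))),
      planted_ct = planted)
  }

  # planted C>T events first (they take precedence in spacing conflicts)
  bias <- data.table::data.table(start = integer(), end = integer())
  if (config$bias_region_fraction > 0) {
    size <- config$bias_region_size
    tiles <- seq(1L, L - size + 1L, by = size)
    n_pick <- round(length(tiles) * config$bias_region_fraction)
    if (n_pick > 0) {
      picks <- sort(sample(tiles, n_pick))
      bias <- data.table::data.table(start = picks,
                                     end = picks + size - 1L)
      for (p in picks) {
        idx <- p:(p + size - 1L)
        cand <- idx[anc[idx] %in% c("C", "G")]
        want <- round(length(cand) * config$bias_ct_fraction)
        cand <- thin_min_gap(cand, 3L)
        # evenly-strided placement keeps the planted fraction uniform
        # at sub-region scale instead of fluctuating chunk to chunk
        if (want < length(cand) && want > 0L)
          cand <- cand[unique(round(seq(1L, length(cand),
                                        length.out = want)))]
        for (s in cand) {
          ref <- anc[s]
          add(s, 1L, ref, if (ref == "C") "T" else "A", "SNP", TRUE)
        }
      }
    }
  }

  n_snp <- stats::rbinom(1L, L, config$snp_rate)
  if (n_snp > 0) {
    pos <- sort(sample.int(L, n_snp))
    for (s in pos) {
      ref <- anc[s]
      add(s, 1L, ref, sample(setdiff(bases, ref), 1L), "SNP", FALSE)
    }
  }
  n_ind <- stats::rbinom(1L, L, config$indel_rate)
  if (n_ind > 0) {
    pos <- sort(sample.int(L, n_ind))
    for (s in pos) {
      len <- sample.int(10L, 1L)
      if (stats::runif(1) < 0.5) {           # insertion before base s
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        add(s, 0L, "", ins, "INS", FALSE)
      } else if (s + len - 1L <= L) {        # deletion of [s, s+len)
        add(s, len, paste(anc[s:(s + len - 1L)], collapse = ""), "",
            "DEL", FALSE)
      }
    }
  }
  if (n_sv > 0) {
    for (k in seq_len(n_sv)) {
      len <- sample(50:150, 1L)
      s <- sample.int(max(L - len - 4L, 1L), 1L) + 2L
      if (stats::runif(1) < 0.5) {
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        add(s, 0L, "", ins, "INS", FALSE)
      } else {
        add(s, len, paste(anc[s:(s + len - 1L)], collapse = ""), "",
            "DEL", FALSE)
      }
    }
  }

  if (length(ev) == 0L) {
    out <- data.table::data.table(start = integer(), ref_len = integer(),
                                  ref = character(), alt = character(),
                                  type = character(), length = integer(),
                                  planted_ct = logical())
  } else {
    out <- data.table::rbindlist(ev)
    # keep events clear of chromosome ends so every bubble has anchors
    out <- out[out$start >= 3L & out$start + pmax(out$ref_len, 1L) <= L - 1L, ]
    # planted events win spacing conflicts, then first-come
    out <- out[order(!out$planted_ct, out$start), ]
    out <- enforce_event_spacing(out, min_gap = 2L)
    out <- out[order(out$start), ]
  }

  # alternate-allele assignment across the four parental haplotypes:
  # planted C>T events put the alternate (T/A) on the SB haplotypes;
  # other events draw each parent independently, never monomorphic.
  n <- nrow(out)
  g <- matrix(0L, nrow = n, ncol = 4,
              dimnames = list(NULL, PARENT_HAPLOTYPES))
  if (n > 0) {
    rnd <- which(!out$planted_ct)
    if (length(rnd)) {
      draw <- matrix(stats::rbinom(length(rnd) * 4L, 1L, 0.5), ncol = 4L)
      mono <- rowSums(draw) %in% c(0L, 4L)
      if (any(mono)) {
        flip <- sample.int(4L, sum(mono), replace = TRUE)
        draw[cbind(which(mono), flip)] <- 1L - draw[cbind(which(mono), flip)]
      }
      g[rnd, ] <- draw
    }
    g[out$planted_ct, c("SB1", "SB2")] <- 1L
  }
  for (h in PARENT_HAPLOTYPES) out[[h]] <- g[, h]
  attr(out, "bias_table") <- bias
  out
}

# greedy thinning to a minimum gap between sorted positions
thin_min_gap <- function(pos, gap) {
  if (length(pos) < 2L) return(pos)
  keep <- logical(length(pos))
  last <- -gap
  for (i in seq_along(pos)) {
    if (pos[i] - last >= gap) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  pos[keep]
}

# drop events whose footprint comes within `min_gap` bp of an already
# accepted event; input order encodes priority
enforce_event_spacing <- function(ev, min_gap = 2L) {
  n <- nrow(ev)
  if (n < 2L) return(ev)
  starts <- ev$start
  ends <- ev$start + pmax(ev$ref_len, 1L) - 1L
  acc_s <- numeric(0)
  acc_e <- numeric(0)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (length(acc_s)) {
      ok <- all(starts[i] > acc_e + min_gap | ends[i] < acc_s - min_gap)
    }
    if (ok) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, starts[i])
      acc_e <- c(acc_e, ends[i])
    }
  }
  ev[keep, ]
}

# Turn the ancestral sequence plus the event table into the six
# haplotype sequences, their paths, node sequences and ancestral
# coordinate maps.
assemble_haplotypes <- function(anc, ev, node_offset = 0L) {
  L <- length(anc)
  haps <- TRIO_HAPLOTYPES
  n_ev <- nrow(ev)
  node_seqs <- character(0)
  new_node <- local({
    k <- node_offset
    function(seq) {
      k <<- k + 1L
      id <- as.character(k)
      node_seqs[[id]] <<- seq
      id
    }
  })

  chunks <- stats::setNames(vector("list", length(haps)), haps)
  steps <- stats::setNames(vector("list", length(haps)), haps)
  amaps <- stats::setNames(vector("list", length(haps)), haps)
  for (h in haps) {
    chunks[[h]] <- vector("list", 2L * n_ev + 1L)
    steps[[h]] <- vector("list", 2L * n_ev + 1L)
    amaps[[h]] <- vector("list", 2L * n_ev + 1L)
  }
  cursor <- 1L
  slot <- 0L
  pseudo <- L                    # next free pseudo-ancestral coordinate
  for (i in seq_len(n_ev)) {
    e_start <- ev$start[i]
    e_len <- ev$ref_len[i]
    if (e_start > cursor) {
      id <- new_node(paste(anc[cursor:(e_start - 1L)], collapse = ""))
      slot <- slot + 1L
      seg <- anc[cursor:(e_start - 1L)]
      seg_str <- paste(seg, collapse = "")
      for (h in haps) {
        steps[[h]][[slot]] <- id
        amaps[[h]][[slot]] <- (cursor:(e_start - 1L)) - 1L
        chunks[[h]][[slot]] <- seg_str
      }
    }
    # allele nodes: one node per distinct non-empty allele at this site.
    # Length-preserving alleles keep the real ancestral coordinates;
    # other alleles get pseudo-ancestral coordinates past the chromosome
    # end, shared by every haplotype carrying the same allele, so that
    # homology maps are complete on shared inserted bases.
    alleles <- vapply(haps, function(h)
      if (ev[[h]][i] == 1L) ev$alt[i] else ev$ref[i], character(1))
    uq <- unique(alleles[nzchar(alleles)])
    ids <- stats::setNames(vapply(uq, new_node, character(1)), uq)
    coords <- list()
    for (al in uq) {
      if (nchar(al) == e_len) {
        coords[[al]] <- (e_start:(e_start + e_len - 1L)) - 1L
      } else {
        coords[[al]] <- pseudo + seq_len(nchar(al)) - 1L
        pseudo <- pseudo + nchar(al)
      }
    }
    slot <- slot + 1L
    for (h in haps) {
      al <- alleles[[h]]
      if (nzchar(al)) {
        steps[[h]][[slot]] <- ids[[al]]
        chunks[[h]][[slot]] <- al
        amaps[[h]][[slot]] <- coords[[al]]
      }
    }
    cursor <- e_start + e_len
  }
  if (cursor <= L) {
    id <- new_node(paste(anc[cursor:L], collapse = ""))
    slot <- slot + 1L
    seg_str <- paste(anc[cursor:L], collapse = "")
    for (h in haps) {
      steps[[h]][[slot]] <- id
      amaps[[h]][[slot]] <- (cursor:L) - 1L
      chunks[[h]][[slot]] <- seg_str
    }
  }

  paths <- list()
  sequences <- list()
  anc_maps_out <- list()
  for (h in haps) {
    st <- unlist(steps[[h]][seq_len(slot)], use.names = FALSE)
    paths[[h]] <- data.frame(node = st, orient = rep("+", length(st)))
    sequences[[h]] <- paste(unlist(chunks[[h]][seq_len(slot)],
                                   use.names = FALSE), collapse = "")
    anc_maps_out[[h]] <- unlist(amaps[[h]][seq_len(slot)], use.names = FALSE)
  }
  list(node_seqs = unlist(node_seqs), paths = paths, sequences = sequences,
       anc_maps = anc_maps_out,
       bias_regions = attr(ev, "bias_table") %||%
         data.table::data.table(start = integer(), end = integer()))
}

#' Homologous-base coordinate map between two paths
#'
#' Derived from the generator's ancestral coordinate maps: two bases are
#' homologous when they descend from the same ancestral base (aligned
#' SNP alleles included) or from the same base of a shared insertion
#' allele.  The map is bijective on shared positions.
#'
#' @param truth a `trio_truth`.
#' @param pathA,pathB path names.
#' @return a `data.table` with 0-based columns `posA`, `posB` and the
#'   shared ancestral coordinate `anc`.
#' @export
coordinate_map <- function(truth, pathA, pathB) {
  a <- truth$anc_maps[[pathA]]
  b <- truth$anc_maps[[pathB]]
  stop_if(is.null(a) || is.null(b), "unknown path name")
  da <- data.table::data.table(posA = seq_along(a) - 1L, anc = a)[!is.na(a)]
  db <- data.table::data.table(posB = seq_along(b) - 1L, anc = b)[!is.na(b)]
  out <- merge(da, db, by = "anc", sort = TRUE)
  out[, c("posA", "posB", "anc"), with = FALSE]
}
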