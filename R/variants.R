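#' Extract pairwise variants between two haplotype paths
#'
#' Walks both paths and uses nodes present exactly once on each path as
#' anchors.  The maximal runs of steps between consecutive shared
#' anchors become variant records: the allele of each path is the
#' concatenated sequence of its non-shared steps.  Records where both
#' alleles are identical are discarded.  Variants are typed `SNP`
#' (single differing base), `MNP` (equal length > 1), `INDEL` (length
#' difference; `length` is the difference in bp) or `OTHER` (complex or
#' nested structure, e.g. a shared node inside the bubble).
#'
#' @param graph a `sequence_graph`.
#' @param pathA,pathB path names; `pathB` plays the reference role for
#'   VCF-style output.
#' @param sv_min_length INDELs at least this long are flagged as
#'   structural variants (default 50 bp).
#' @return a `data.table` with columns `posA`, `posB` (0-based start of
#'   the variant on each path), `alleleA`, `alleleB`, `type`, `length`
#'   and `sv`.
#' @export
extract_path_variants <- function(graph, pathA, pathB, sv_min_length = 50) {
  ia <- path_index(graph, pathA)
  ib <- path_index(graph, pathB)
  ta <- table(ia$node)
  tb <- table(ib$node)
  anchors <- intersect(names(ta)[ta == 1L], names(tb)[tb == 1L])
  stop_if(length(anchors) == 0L,
          sprintf("no anchors: paths '%s' and '%s' share no single-copy node",
                  pathA, pathB))
  shared_any <- intersect(ia$node, ib$node)

  # anchor steps in A order whose B positions are increasing
  sa <- which(ia$node %in% anchors)
  pb <- match(ia$node[sa], ib$node)
  keep <- logical(length(sa))
  last <- -1L
  for (k in seq_along(sa)) {
    if (pb[k] > last) {
      keep[k] <- TRUE
      last <- pb[k]
    }
  }
  sa <- sa[keep]
  pb <- pb[keep]
  if (length(sa) < 2L) return(empty_variant_table())

  res <- vector("list", length(sa) - 1L)
  n_out <- 0L
  for (k in seq_len(length(sa) - 1L)) {
    a_lo <- sa[k]; a_hi <- sa[k + 1L]
    b_lo <- pb[k]; b_hi <- pb[k + 1L]
    if (a_hi == a_lo + 1L && b_hi == b_lo + 1L) next
    stepsA <- if (a_hi > a_lo + 1L) seq(a_lo + 1L, a_hi - 1L) else integer()
    stepsB <- if (b_hi > b_lo + 1L) seq(b_lo + 1L, b_hi - 1L) else integer()
    alleleA <- spell_steps(graph, ia, stepsA)
    alleleB <- spell_steps(graph, ib, stepsB)
    if (alleleA == alleleB) next
    nested <- any(ia$node[stepsA] %in% shared_any) ||
      any(ib$node[stepsB] %in% shared_any)
    la <- nchar(alleleA); lb <- nchar(alleleB)
    if (nested) {
      type <- "OTHER"; len <- max(la, lb)
    } else if (la == lb) {
      type <- if (la == 1L) "SNP" else "MNP"
      len <- la
    } else {
      type <- "INDEL"; len <- abs(la - lb)
    }
    n_out <- n_out + 1L
    res[[n_out]] <- data.table::data.table(
      posA = ia$start[a_lo] + ia$len[a_lo],
      posB = ib$start[b_lo] + ib$len[b_lo],
      alleleA = alleleA, alleleB = alleleB,
      type = type, length = as.integer(len),
      sv = type == "INDEL" && len >= sv_min_length)
  }
  if (n_out == 0L) return(empty_variant_table())
  data.table::rbindlist(res[seq_len(n_out)])
}

spell_steps <- function(graph, idx, steps) {
  if (length(steps) == 0L) return("")
  seqs <- graph$nodes[idx$node[steps]]
  flip <- idx$orient[steps] == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  paste(seqs, collapse = "")
}

empty_variant_table <- function() {
  data.table::data.table(posA = integer(), posB = integer(),
                         alleleA = character(), alleleB = character(),
                         type = character(), length = integer(),
                         sv = logical())
}

#' Write pairwise path variants as a minimal VCF 4.2
#'
#' `pathB` of the extraction is the reference: `CHROM` is the reference
#' path name, `POS` is 1-based, and empty alleles are left-padded with
#' the preceding reference base in the usual VCF convention.
#'
#' @param variants table from [extract_path_variants()].
#' @param graph the graph the variants came from.
#' @param pathA,pathB the paths used for extraction.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_variants_vcf <- function(variants, graph, pathA, pathB, file) {
  ref_seq <- path_sequence(graph, pathB)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", pathB, nchar(ref_seq)),
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants) == 0L) {
    writeLines(hdr, file)
    return(invisible(file))
  }
  pos1 <- variants$posB + 1L
  ref <- variants$alleleB
  alt <- variants$alleleA
  pad <- !nzchar(ref) | !nzchar(alt)
  if (any(pad)) {
    base <- substr(ref_seq, variants$posB[pad], variants$posB[pad])
    pos1[pad] <- variants$posB[pad]
    ref[pad] <- paste0(base, ref[pad])
    alt[pad] <- paste0(base, alt[pad])
  }
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s",
                  pathB, pos1, ref, alt, variants$type)
  writeLines(c(hdr, rows), file)
  invisible(file)
}
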