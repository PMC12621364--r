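#' Metagene methylation profile
#'
#' Averages methylation levels in 100 bins (by default) over each of
#' three segments — the upstream flank, the gene body and the
#' downstream flank — strand-aware, so bin 1 of the upstream segment is
#' the 5'-most flank position of every gene.  Site levels are averaged
#' per gene and bin first, then across genes; bins without any site
#' stay `NA` rather than zero.  Genes shorter than the bin count are
#' binned with fractional widths, never dropped.
#'
#' @param genes table with `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`; coordinates on the same path as `profile`.
#' @param profile a `united_profile` for that path.
#' @param flank flank length in bp (default 1000).
#' @param bins bins per segment (default 100).
#' @return `data.table` with `segment` (`upstream`/`body`/
#'   `downstream`), `bin`, `context`, `level` (%), `n_genes`.
#' @export
metagene_profile <- function(genes, profile, flank = 1000, bins = 100) {
  genes <- data.table::as.data.table(genes)
  gr_q <- IRanges::IRanges(start = pmax(genes$start - flank, 1L),
                           end = genes$end + flank)
  s <- IRanges::IRanges(start = profile$pos, width = 1L)
  hits <- IRanges::findOverlaps(gr_q, s)
  if (length(hits) == 0L) {
    return(data.table::data.table(segment = character(), bin = integer(),
                                  context = character(), level = numeric(),
                                  n_genes = integer()))
  }
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pos <- profile$pos[si]
  glen <- genes$end - genes$start + 1L
  plus <- genes$strand[gi] == "+"
  d <- ifelse(plus, pos - genes$start[gi], genes$end[gi] - pos)
  L <- glen[gi]
  seg <- ifelse(d < 0, "upstream", ifelse(d >= L, "downstream", "body"))
  bin <- integer(length(d))
  up <- seg == "upstream"
  body <- seg == "body"
  down <- seg == "downstream"
  bin[up] <- as.integer(pmin(floor((d[up] + flank) / flank * bins),
                             bins - 1)) + 1L
  bin[body] <- as.integer(pmin(floor(d[body] / L[body] * bins),
                               bins - 1)) + 1L
  bin[down] <- as.integer(pmin(floor((d[down] - L[down]) / flank * bins),
                               bins - 1)) + 1L
  keep <- d >= -flank & d < L + flank
  dt <- data.table::data.table(gene = gi[keep], segment = seg[keep],
                               bin = bin[keep],
                               context = profile$context[si][keep],
                               level = profile$level_mean[si][keep])
  per_gene <- dt[, list(level = mean(level)),
                 by = c("gene", "segment", "bin", "context")]
  out <- per_gene[, list(level = mean(level), n_genes = .N),
                  by = c("segment", "bin", "context")]
  data.table::setorderv(out, c("context", "segment", "bin"))
  out
}

#' Classify genes by exonic methylation (gbM / teM)
#'
#' A gene shows gene-body methylation (`gbM`) when its mean exonic CG
#' level is at least `gbm_threshold` while CHG and CHH stay below it;
#' it shows TE-like methylation (`teM`) when all three contexts reach
#' `tem_threshold` and the gene is not gbM; all other genes — including
#' genes lacking exonic sites in a required context, which are flagged —
#' are `other`.
#'
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param exons exon table with `gene_id`, `start`, `end` (1-based
#'   inclusive, same path as `profile`).
#' @param profile a `united_profile`.
#' @param gbm_threshold CG threshold in percent (default 20).
#' @param tem_threshold all-context threshold in percent (default 5).
#' @return `data.table` with `gene_id`, mean exonic levels per context,
#'   `class` and `missing_context`.
#' @export
classify_gene_methylation <- function(genes, exons, profile,
                                      gbm_threshold = 20,
                                      tem_threshold = 5) {
  exons <- data.table::as.data.table(exons)
  q <- IRanges::IRanges(start = exons$start, end = exons$end)
  s <- IRanges::IRanges(start = profile$pos, width = 1L)
  hits <- IRanges::findOverlaps(q, s)
  dt <- data.table::data.table(
    gene_id = exons$gene_id[S4Vectors::queryHits(hits)],
    context = profile$context[S4Vectors::subjectHits(hits)],
    level = profile$level_mean[S4Vectors::subjectHits(hits)])
  means <- dt[, list(level = mean(level)), by = c("gene_id", "context")]
  wide <- data.table::dcast(means, gene_id ~ context, value.var = "level")
  for (ctx in c("CG", "CHG", "CHH"))
    if (!ctx %in% names(wide)) wide[[ctx]] <- NA_real_
  out <- merge(data.table::data.table(gene_id = genes$gene_id), wide,
               by = "gene_id", all.x = TRUE)
  out$missing_context <- is.na(out$CG) | is.na(out$CHG) | is.na(out$CHH)
  gbm <- !out$missing_context & out$CG >= gbm_threshold &
    out$CHG < gbm_threshold & out$CHH < gbm_threshold
  tem <- !out$missing_context & !gbm & out$CG >= tem_threshold &
    out$CHG >= tem_threshold & out$CHH >= tem_threshold
  out$class <- ifelse(gbm, "gbM", ifelse(tem, "teM", "other"))
  out
}

# strand-aware promoter intervals (1-based inclusive), clipped at 1
promoter_intervals <- function(genes, promoter = 3000) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(genes$start - promoter, 1L), genes$end + 1L)
  end <- ifelse(plus, genes$start - 1L, genes$end + promoter)
  data.table::data.table(gene_id = genes$gene_id, start = start, end = end)
}

#' Annotate regions against the gene and repeat space
#'
#' Labels each region with a single feature by the fixed priority
#' exon > intron > promoter > repeat > intergenic, and separately flags
#' overlap with repeats (TE flag) so that any other precedence can be
#' recomputed from the raw flags, which are all returned.
#'
#' @param regions table with `start`, `end` (1-based inclusive, same
#'   path as the annotations).
#' @param genes,exons gene/exon tables (1-based inclusive).
#' @param repeats repeat table (1-based inclusive) or `NULL`.
#' @param promoter promoter length upstream of the TSS in bp
#'   (default 3000).
#' @return the regions with logical overlap flags (`in_exon`,
#'   `in_intron`, `in_promoter`, `te_overlap`) and the `feature` label.
#' @export
annotate_regions <- function(regions, genes, exons, repeats = NULL,
                             promoter = 3000) {
  regions <- data.table::as.data.table(regions)
  q <- IRanges::IRanges(start = regions$start, end = regions$end)
  ov <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(rep(FALSE, nrow(regions)))
    IRanges::overlapsAny(q, IRanges::IRanges(start = tab$start,
                                             end = tab$end))
  }
  in_gene <- ov(genes)
  in_exon <- ov(exons)
  regions$in_exon <- in_exon
  regions$in_intron <- in_gene & !in_exon
  regions$in_promoter <- ov(promoter_intervals(genes, promoter))
  regions$te_overlap <- ov(repeats)
  regions$feature <- ifelse(regions$in_exon, "exon",
                     ifelse(regions$in_intron, "intron",
                     ifelse(regions$in_promoter, "promoter",
                     ifelse(regions$te_overlap, "repeat", "intergenic"))))
  regions
}

#' Structural variants in the neighbourhood of DMRs
#'
#' Restricts the variant set to INDELs of at least `sv_min_length` bp
#' and reports, for every DMR-SV pair within `maxgap`, whether the SV
#' overlaps the DMR (`within`) or lies up to `maxgap` bp away
#' (`proximal`).  When the DMR table carries a `te_overlap` flag, a
#' 2x2 Fisher test of TE content against large-deletion impact
#' (deletion SV within the DMR) is run.
#'
#' @param dmrs table with `dmr_id`, `start`, `end` (1-based inclusive)
#'   and optionally `te_overlap`.
#' @param variants [extract_path_variants()] table localised on the
#'   same path via `posB`.
#' @param maxgap maximum separation in bp (default 1000).
#' @param sv_min_length minimum INDEL length (default 50 bp).
#' @return list with `pairs` (`dmr_id`, SV index, `distance`, `class`)
#'   and `test` (Fisher results or `NULL`).
#' @export
sv_proximity <- function(dmrs, variants, maxgap = 1000, sv_min_length = 50) {
  dmrs <- data.table::as.data.table(dmrs)
  svs <- variants[variants$type == "INDEL" &
                    variants$length >= sv_min_length, ]
  pairs <- data.table::data.table(dmr_id = character(), sv = integer(),
                                  sv_pos = integer(), sv_length = integer(),
                                  distance = integer(), class = character())
  if (nrow(svs) > 0L && nrow(dmrs) > 0L) {
    q <- IRanges::IRanges(start = dmrs$start, end = dmrs$end)
    s <- IRanges::IRanges(start = svs$posB + 1L,
                          width = pmax(nchar(svs$alleleB), 1L))
    hits <- IRanges::findOverlaps(q, s, maxgap = maxgap)
    if (length(hits)) {
      d <- IRanges::distance(q[S4Vectors::queryHits(hits)],
                             s[S4Vectors::subjectHits(hits)])
      sj <- S4Vectors::subjectHits(hits)
      pairs <- data.table::data.table(
        dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
        sv = sj, sv_pos = svs$posB[sj], sv_length = svs$length[sj],
        distance = as.integer(d),
        class = ifelse(d == 0L, "within", "proximal"))
    }
  }
  test <- NULL
  if ("te_overlap" %in% names(dmrs) && nrow(dmrs) > 0L) {
    del_within <- unique(pairs$dmr_id[pairs$class == "within" &
                                        !nzchar(svs$alleleA[pairs$sv])])
    impacted <- dmrs$dmr_id %in% del_within
    if (length(unique(dmrs$te_overlap)) > 1L && any(impacted)) {
      ft <- stats::fisher.test(table(factor(dmrs$te_overlap, c(TRUE, FALSE)),
                                     factor(impacted, c(TRUE, FALSE))))
      test <- list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    }
  }
  list(pairs = pairs, test = test)
}

#' Reciprocal allelic gene pairs across haplotypes
#'
#' Projects each gene span onto the other haplotype via the graph and
#' pairs it with the native gene its projection overlaps by at least
#' `min_overlap` of the projected span; pairs are kept only when found
#' in both directions.  Unpaired genes are categorised as
#' `unprojectable` (span does not project), `no_overlap` (projection
#' hits no gene at the required fraction) or `unidirectional`.
#'
#' @param graph a chopped `sequence_graph`.
#' @param genes_a,genes_b gene tables (1-based inclusive) on `path_a`
#'   and `path_b`.
#' @param path_a,path_b the two haplotype paths.
#' @param min_overlap minimum overlap fraction of the projected span
#'   (default 0.5).
#' @return list with `pairs` (`gene_a`, `gene_b`) and `unpaired`
#'   (`gene_id`, `path`, `category`).
#' @export
allelic_pairs <- function(graph, genes_a, genes_b, path_a, path_b,
                          min_overlap = 0.5) {
  match_dir <- function(ga, gb, pa, pb) {
    n <- nrow(ga)
    hit <- rep(NA_character_, n)
    cat <- rep(NA_character_, n)
    p1 <- project_positions(graph, pa, ga$start - 1L, pb)
    p2 <- project_positions(graph, pa, ga$end - 1L, pb)
    lo <- pmin(p1, p2) + 1L
    hi <- pmax(p1, p2) + 1L
    ok <- !is.na(p1) & !is.na(p2)
    cat[!ok] <- "unprojectable"
    if (any(ok)) {
      q <- IRanges::IRanges(start = lo[ok], end = hi[ok])
      s <- IRanges::IRanges(start = gb$start, end = gb$end)
      ovl <- IRanges::findOverlaps(q, s)
      w <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(ovl)], s[S4Vectors::subjectHits(ovl)]))
      frac <- w / IRanges::width(q)[S4Vectors::queryHits(ovl)]
      good <- frac >= min_overlap
      best <- data.table::data.table(
        qi = S4Vectors::queryHits(ovl)[good],
        target = gb$gene_id[S4Vectors::subjectHits(ovl)[good]],
        frac = frac[good])
    data.table::setorderv(best, c("qi", "frac"), order = c(1L, -1L))
      best <- best[!duplicated(best$qi), ]
      oki <- which(ok)
      hit[oki[best$qi]] <- best$target
      cat[ok] <- ifelse(is.na(hit[ok]), "no_overlap", NA_character_)
    }
    list(hit = hit, cat = cat)
  }
  ab <- match_dir(genes_a, genes_b, path_a, path_b)
  ba <- match_dir(genes_b, genes_a, path_b, path_a)
  back <- ba$hit[match(ab$hit, genes_b$gene_id)]
  reciprocal <- !is.na(ab$hit) & !is.na(back) & back == genes_a$gene_id
  pairs <- data.table::data.table(gene_a = genes_a$gene_id[reciprocal],
                                  gene_b = ab$hit[reciprocal])
  unidir_a <- !reciprocal & !is.na(ab$hit)
  cat_a <- ifelse(reciprocal, NA_character_,
                  ifelse(unidir_a, "unidirectional", ab$cat))
  paired_b <- genes_b$gene_id %in% pairs$gene_b
  unidir_b <- !paired_b & !is.na(ba$hit)
  cat_b <- ifelse(paired_b, NA_character_,
                  ifelse(unidir_b, "unidirectional", ba$cat))
  unpaired <- rbind(
    data.table::data.table(gene_id = genes_a$gene_id, path = path_a,
                           category = cat_a)[!is.na(cat_a)],
    data.table::data.table(gene_id = genes_b$gene_id, path = path_b,
                           category = cat_b)[!is.na(cat_b)])
  list(pairs = pairs, unpaired = unpaired)
}

#' Signed intersection of two significance sets
#'
#' Generic inherited-set logic: identifiers significant in both input
#' sets with the same sign.
#'
#' @param set_a,set_b tables with columns `id` and `sign` (any equal
#'   values count as agreement, e.g. `"up"`/`"down"` or `1`/`-1`).
#' @return table of inherited ids with their shared sign.
#' @export
inherited_sets <- function(set_a, set_b) {
  a <- data.table::as.data.table(set_a)
  b <- data.table::as.data.table(set_b)
  if (length(intersect(a$id, b$id)) == 0L) {
    warning("significance sets share no identifiers")
    return(data.table::data.table(id = character(), sign = character()))
  }
  m <- merge(a, b, by = "id", suffixes = c("_a", "_b"))
  m <- m[m$sign_a == m$sign_b, ]
  data.table::data.table(id = m$id, sign = m$sign_a)
}
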