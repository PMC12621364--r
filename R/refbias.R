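#' Pair homologous chunks between two haplotype paths
#'
#' Tiles the reference path into `size`-bp chunks and projects both
#' endpoints onto the alternative path.  Chunks whose endpoints do not
#' project unambiguously, or whose projected length falls outside the
#' comparable-window bounds, are dropped.
#'
#' @param graph a chopped `sequence_graph`.
#' @param ref_path reference path (methylation is re-expressed on its
#'   coordinates).
#' @param alt_path alternative path supplying the ported calls.
#' @param size chunk size in bp (default 200).
#' @param min_len,max_len accepted projected lengths (default 150-250).
#' @return `data.table` with `chunk_id`, reference `start`/`end` and
#'   projected `alt_start`/`alt_end` (0-based half-open).
#' @export
homologous_chunks <- function(graph, ref_path, alt_path, size = 200,
                              min_len = 150, max_len = 250) {
  w <- make_reference_windows(graph, ref_path, win = size, step = size,
                              min_len = min_len)
  p1 <- project_positions(graph, ref_path, w$start, alt_path)
  p2 <- project_positions(graph, ref_path, w$end - 1L, alt_path)
  lo <- pmin(p1, p2)
  hi <- pmax(p1, p2) + 1L
  ok <- !is.na(p1) & !is.na(p2) & hi - lo >= min_len & hi - lo <= max_len
  data.table::data.table(chunk_id = w$window_id[ok], start = w$start[ok],
                         end = w$end[ok], alt_start = lo[ok],
                         alt_end = hi[ok])
}

# mean level of profile sites inside 0-based half-open intervals,
# optionally restricted to one context; counts are pooled over clones
interval_mean_levels <- function(intervals, prof, context = NULL,
                                 start_col = "start", end_col = "end") {
  n <- nrow(intervals)
  out <- data.table::data.table(n_sites = integer(n), level = rep(NA_real_, n))
  if (n == 0L || is.null(prof) || nrow(prof) == 0L) return(out)
  ctx <- context   # plain local: a bare symbol would resolve to the column
  sites <- if (is.null(ctx)) prof else prof[prof$context == ctx, ]
  if (nrow(sites) == 0L) return(out)
  meth_cols <- grep("^meth_", names(sites), value = TRUE)
  cov_cols <- grep("^cov_", names(sites), value = TRUE)
  m <- rowSums(as.matrix(sites[, meth_cols, with = FALSE]))
  cv <- rowSums(as.matrix(sites[, cov_cols, with = FALSE]))
  q <- IRanges::IRanges(start = intervals[[start_col]] + 1L,
                        end = intervals[[end_col]])
  s <- IRanges::IRanges(start = sites$pos, width = 1L)
  hits <- IRanges::findOverlaps(q, s)
  if (length(hits) == 0L) return(out)
  dd <- data.table::data.table(i = S4Vectors::queryHits(hits),
                               m = m[S4Vectors::subjectHits(hits)],
                               cv = cv[S4Vectors::subjectHits(hits)])
  agg <- dd[, list(n_sites = .N, m = sum(m), cv = sum(cv)), by = "i"]
  out$n_sites[agg$i] <- agg$n_sites
  out$level[agg$i] <- ifelse(agg$cv > 0, 100 * agg$m / agg$cv, NA_real_)
  out
}

#' Port methylation calls through homologous chunks
#'
#' For every homologous chunk, the biased single-reference calls inside
#' the reference interval give the pre-correction level, and the
#' alternative-side sample profile inside the paired interval gives the
#' post-correction ("ported") level.  Per-site ported values on
#' reference coordinates are returned for sites whose own position
#' projects onto the reference.
#'
#' @param graph the chopped `sequence_graph` used for the pairing.
#' @param chunks output of [homologous_chunks()].
#' @param biased_profile `united_profile` of the biased calls (on
#'   reference coordinates), e.g. united output of
#'   [emit_single_reference_calls()] clones.
#' @param alt_profile `united_profile` of the sample on its own
#'   (alternative-path) coordinates.
#' @param alt_path,ref_path the paths of the pairing.
#' @param context optional context restriction.
#' @return list with `regions` (`chunk_id`, `pre`, `post`, `n_pre`,
#'   `n_post`) and `sites` (per-site ported levels on reference
#'   coordinates).
#' @export
port_methylation <- function(graph, chunks, biased_profile, alt_profile,
                             ref_path, alt_path, context = NULL) {
  pre <- interval_mean_levels(chunks, biased_profile, context)
  post <- interval_mean_levels(chunks, alt_profile, context,
                               start_col = "alt_start", end_col = "alt_end")
  regions <- data.table::data.table(chunk_id = chunks$chunk_id,
                                    start = chunks$start, end = chunks$end,
                                    pre = pre$level, post = post$level,
                                    n_pre = pre$n_sites,
                                    n_post = post$n_sites)
  # regions with no sites on either side carry no information
  regions <- regions[!(regions$n_pre == 0L & regions$n_post == 0L), ]

  sites <- data.table::data.table(ref_pos = integer(), strand = character(),
                                  level = numeric())
  ctx <- context
  ap <- if (is.null(ctx)) alt_profile
    else alt_profile[alt_profile$context == ctx, ]
  if (!is.null(ap) && nrow(ap) > 0L) {
    proj <- project_positions(graph, alt_path, ap$pos - 1L, ref_path)
    ok <- !is.na(proj)
    if (any(ok)) {
      meth_cols <- grep("^meth_", names(ap), value = TRUE)
      cov_cols <- grep("^cov_", names(ap), value = TRUE)
      m <- rowSums(as.matrix(ap[ok, meth_cols, with = FALSE]))
      cv <- rowSums(as.matrix(ap[ok, cov_cols, with = FALSE]))
      sites <- data.table::data.table(ref_pos = proj[ok] + 1L,
                                      strand = ap$strand[ok],
                                      level = ifelse(cv > 0, 100 * m / cv,
                                                     NA_real_))
    }
  }
  list(regions = regions, sites = sites)
}

#' Classify regions by correction outcome
#'
#' Partition of ported regions by the pre/post methylation contrast:
#' `corrected` regions reach high methylation (>= `high_level`) only
#' after porting with a delta of at least `delta_min`; `original`
#' regions were high only before; the remainder split into `low_delta`
#' and `high_delta` by the delta alone.  The four groups are exclusive
#' and exhaustive.
#'
#' @param records table with `pre` and `post` mean levels (%).
#' @param high_level high-methylation threshold (default 75).
#' @param delta_min minimum delta (percentage points, default 20).
#' @return the records with `delta` and `group` columns.
#' @export
classify_correction_groups <- function(records, high_level = 75,
                                       delta_min = 20) {
  rec <- data.table::as.data.table(records)
  pre <- ifelse(is.na(rec$pre), 0, rec$pre)
  post <- ifelse(is.na(rec$post), 0, rec$post)
  rec$delta <- abs(post - pre)
  rec$group <- ifelse(
    post >= high_level & pre < high_level & rec$delta >= delta_min,
    "corrected",
    ifelse(pre >= high_level & post < high_level & rec$delta >= delta_min,
           "original",
           ifelse(rec$delta < delta_min, "low_delta", "high_delta")))
  rec
}

#' Substitution-type composition per correction group
#'
#' Localises pairwise path SNPs to the classified regions, counts the
#' twelve directed substitution types per group (reference allele >
#' alternative allele) and tests whether the corrected group is
#' enriched for the bisulfite-confusable substitutions (C>T and G>A)
#' with Fisher's exact test against all other groups.
#'
#' @param records classified regions ([classify_correction_groups()])
#'   with reference `start`/`end` columns.
#' @param variants [extract_path_variants()] table where path A is the
#'   alternative haplotype and path B the reference (`posB` localises
#'   the variant on the reference).
#' @return list with `counts` (group x substitution table), `test`
#'   (`odds_ratio`, `p_value`, or `NA` when a margin is empty) and
#'   `snps` (per-SNP group assignment).
#' @export
substitution_enrichment <- function(records, variants) {
  snps <- variants[variants$type == "SNP", ]
  out_empty <- list(counts = table(character(), character()),
                    test = list(odds_ratio = NA_real_, p_value = NA_real_),
                    snps = data.table::data.table())
  if (nrow(snps) == 0L || nrow(records) == 0L) return(out_empty)
  q <- IRanges::IRanges(start = records$start + 1L, end = records$end)
  s <- IRanges::IRanges(start = snps$posB + 1L, width = 1L)
  hits <- IRanges::findOverlaps(s, q)
  if (length(hits) == 0L) return(out_empty)
  snps <- snps[S4Vectors::queryHits(hits), ]
  snps$group <- records$group[S4Vectors::subjectHits(hits)]
  snps$substitution <- paste0(snps$alleleB, ">", snps$alleleA)
  counts <- table(snps$group, snps$substitution)
  confusable <- snps$substitution %in% c("C>T", "G>A")
  corrected <- snps$group == "corrected"
  test <- list(odds_ratio = NA_real_, p_value = NA_real_)
  if (any(corrected) && any(!corrected)) {
    tab <- table(factor(corrected, c(TRUE, FALSE)),
                 factor(confusable, c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    # sample odds ratio (not the conditional MLE) alongside the exact p
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    test <- list(odds_ratio = unname(or), p_value = ft$p.value)
  }
  list(counts = counts, test = test, snps = snps)
}
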