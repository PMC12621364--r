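#' Thresholds for the differential methylation analysis
#'
#' Defaults follow the calibrated study settings: 200 bp windows,
#' at least 3 cytosines per window, q < 0.01, and context-specific
#' methylation differentials of 20 percentage points for CG and CHG and
#' 10 for CHH.
#'
#' @param q_max significance threshold on the BH-adjusted q-value.
#' @param diff_min named vector of minimum absolute methylation
#'   differentials (percentage points) per context.
#' @param win,step window size and tiling step in bp.
#' @param min_cytosines minimum cytosines per window per haplotype.
#' @param min_len,max_len accepted projected-window lengths in bp.
#' @return a list of class `dma_thresholds`.
#' @export
dma_thresholds <- function(q_max = 0.01,
                           diff_min = c(CG = 20, CHG = 20, CHH = 10),
                           win = 200, step = 200, min_cytosines = 3,
                           min_len = 150, max_len = 250) {
  stop_if(any(diff_min <= 0), "diff_min must be positive")
  structure(list(q_max = q_max, diff_min = diff_min, win = win, step = step,
                 min_cytosines = min_cytosines, min_len = min_len,
                 max_len = max_len), class = "dma_thresholds")
}

#' Tile reference paths into windows
#'
#' Tiles `[0, L)` of each reference path with `win`-bp windows every
#' `step` bp; a shorter terminal window is kept only when it is at
#' least `min_len` bp.
#'
#' @param graph a `sequence_graph`.
#' @param ref_paths character vector of reference path names (the
#'   progeny haplotypes in the standard trio analysis).
#' @param win,step window size and step (bp).
#' @param min_len minimum terminal window length (bp).
#' @return `data.table` with `window_id`, `ref_path`, `start`, `end`
#'   (0-based half-open).
#' @export
make_reference_windows <- function(graph, ref_paths, win = 200, step = 200,
                                   min_len = 150) {
  stop_if(win < 1 || step < 1, "win and step must be >= 1")
  rows <- lapply(ref_paths, function(pn) {
    L <- path_index(graph, pn)$path_length
    starts <- seq.int(0L, max(L - 1L, 0L), by = step)
    ends <- pmin(starts + win, L)
    keep <- ends - starts >= min_len
    data.table::data.table(ref_path = pn, start = starts[keep],
                           end = ends[keep])
  })
  out <- data.table::rbindlist(rows)
  out$window_id <- sprintf("%s:%d-%d", out$ref_path, out$start, out$end)
  out[, c("window_id", "ref_path", "start", "end"), with = FALSE]
}

# count profile sites of one context inside 0-based half-open intervals
count_sites_in_intervals <- function(intervals, prof, context_sel) {
  if (nrow(intervals) == 0L) return(integer(0))
  sites <- prof[prof$context == context_sel, ]
  q <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  s <- IRanges::IRanges(start = sites$pos, width = 1L)
  IRanges::countOverlaps(q, s)
}

#' Project reference windows onto target haplotypes
#'
#' Projects both endpoints of every reference window onto each target
#' path via [project_positions()] and applies the comparability
#' filters: windows are dropped when an endpoint does not project
#' (private or ambiguous node), when a projected length falls outside
#' `[min_len, max_len]`, or when any required haplotype (reference
#' included) has fewer than `min_cytosines` sites of the analysed
#' context inside its interval.
#'
#' @param graph a chopped `sequence_graph`.
#' @param windows output of [make_reference_windows()].
#' @param targets character vector of target path names.
#' @param profiles named list path -> `united_profile`.
#' @param context cytosine context under analysis.
#' @param thresholds a [dma_thresholds()].
#' @return list of class `comparable_windows`: `windows` (retained
#'   reference windows), `intervals` (long table: `window_id`, `path`,
#'   `start`, `end`, `n_cyt`, `is_ref`) and `dropped` (named counts of
#'   drop reasons).
#' @export
project_windows <- function(graph, windows, targets, profiles, context,
                            thresholds = dma_thresholds()) {
  th <- thresholds
  keep <- rep(TRUE, nrow(windows))
  dropped <- c(unprojected = 0L, length = 0L, cytosines = 0L)
  ivs <- list()
  for (rp in unique(windows$ref_path)) {
    wi <- which(windows$ref_path == rp)
    w <- windows[wi, ]
    ref_iv <- data.table::data.table(window_id = w$window_id, path = rp,
                                     start = w$start, end = w$end,
                                     is_ref = TRUE)
    ref_iv$n_cyt <- count_sites_in_intervals(ref_iv, profiles[[rp]], context)
    ivs[[length(ivs) + 1L]] <- ref_iv
    for (tp in setdiff(targets, rp)) {
      p1 <- project_positions(graph, rp, w$start, tp)
      p2 <- project_positions(graph, rp, w$end - 1L, tp)
      lo <- pmin(p1, p2)
      hi <- pmax(p1, p2) + 1L
      ok_proj <- !is.na(p1) & !is.na(p2)
      len <- hi - lo
      ok_len <- ok_proj & len >= th$min_len & len <= th$max_len
      iv <- data.table::data.table(window_id = w$window_id, path = tp,
                                   start = ifelse(ok_len, lo, NA_integer_),
                                   end = ifelse(ok_len, hi, NA_integer_),
                                   is_ref = FALSE)
      n_cyt <- rep(NA_integer_, nrow(iv))
      good <- which(ok_len)
      if (length(good))
        n_cyt[good] <- count_sites_in_intervals(iv[good, ], profiles[[tp]],
                                                context)
      iv$n_cyt <- n_cyt
      ivs[[length(ivs) + 1L]] <- iv
      dropped["unprojected"] <- dropped["unprojected"] + sum(!ok_proj & keep[wi])
      dropped["length"] <- dropped["length"] + sum(ok_proj & !ok_len & keep[wi])
      keep[wi] <- keep[wi] & ok_len
    }
  }
  intervals <- data.table::rbindlist(ivs)
  # cytosine filter across every required haplotype, reference included
  low <- intervals[!is.na(intervals$n_cyt) &
                     intervals$n_cyt < th$min_cytosines, ]
  kept_ids <- windows$window_id[keep]
  cyt_bad <- intersect(unique(low$window_id), kept_ids)
  dropped["cytosines"] <- length(cyt_bad)
  kept_ids <- setdiff(kept_ids, cyt_bad)
  out_w <- windows[windows$window_id %in% kept_ids, ]
  out_i <- intervals[intervals$window_id %in% kept_ids, ]
  structure(list(windows = out_w, intervals = out_i, dropped = dropped,
                 context = context),
            class = "comparable_windows")
}

#' @export
print.comparable_windows <- function(x, ...) {
  cat(sprintf("comparable_windows (%s): %d windows retained; dropped: %s\n",
              x$context, nrow(x$windows),
              paste(names(x$dropped), x$dropped, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# expand a group specification to interval rows: haplotype names are
# matched with any '#chr' suffix stripped; the token "@ref" selects the
# window's own reference interval (allele-specific progeny counts)
group_intervals <- function(cw, group) {
  iv <- cw$intervals
  if (identical(group, "@ref")) return(iv[iv$is_ref == TRUE, ])
  iv[sub("#.*$", "", iv$path) %in% group & !is.na(iv$start), ]
}

#' Aggregate per-clone counts inside comparable windows
#'
#' For each window and clone, methylated and total counts of the
#' analysed context are summed over every cytosine falling inside the
#' group's projected interval(s) — both haplotypes of a cultivar in the
#' standard comparison, a single haplotype in intra-cultivar mode, or
#' the window's own reference interval for allele-specific progeny
#' counts (`group = "@ref"`).
#'
#' @param cw a `comparable_windows` object.
#' @param profiles named list path -> `united_profile`.
#' @param group character vector of haplotype names, or `"@ref"`.
#' @return list with matrices `M` (methylated) and `N` (total), windows
#'   in `cw$windows` order x clones.
#' @export
aggregate_window_counts <- function(cw, profiles, group) {
  iv <- group_intervals(cw, group)
  ids <- cw$windows$window_id
  first_path <- iv$path[1L]
  n_clones <- length(grep("^meth_", names(profiles[[first_path]])))
  M <- matrix(0L, nrow = length(ids), ncol = n_clones,
              dimnames = list(ids, NULL))
  N <- matrix(0L, nrow = length(ids), ncol = n_clones,
              dimnames = list(ids, NULL))
  for (pn in unique(iv$path)) {
    pi <- iv[iv$path == pn, ]
    prof <- profiles[[pn]]
    sites <- prof[prof$context == cw$context, ]
    if (nrow(sites) == 0L || nrow(pi) == 0L) next
    q <- IRanges::IRanges(start = pi$start + 1L, end = pi$end)
    s <- IRanges::IRanges(start = sites$pos, width = 1L)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    dd <- data.table::data.table(
      window_id = pi$window_id[S4Vectors::queryHits(hits)],
      sites[S4Vectors::subjectHits(hits),
            c(paste0("meth_", seq_len(n_clones)),
              paste0("cov_", seq_len(n_clones))), with = FALSE])
    agg <- dd[, lapply(.SD, sum), by = "window_id"]
    ri <- match(agg$window_id, ids)
    for (k in seq_len(n_clones)) {
      M[ri, k] <- M[ri, k] + agg[[paste0("meth_", k)]]
      N[ri, k] <- N[ri, k] + agg[[paste0("cov_", k)]]
    }
  }
  list(M = M, N = N)
}

# x*log(p) with the 0*log(0) == 0 convention
xlogp <- function(x, p) {
  out <- x * log(p)
  out[x == 0] <- 0
  out
}

# vectorised two-group binomial likelihood-ratio test with
# McCullagh-Nelder overdispersion scaling; matrices are windows x clones
dma_test_matrix <- function(MA, NA_, MB, NB) {
  pA <- rowSums(MA) / rowSums(NA_)
  pB <- rowSums(MB) / rowSums(NB)
  p0 <- (rowSums(MA) + rowSums(MB)) / (rowSums(NA_) + rowSums(NB))
  ll <- function(M, N, P) {
    rowSums(xlogp(M, P) + xlogp(N - M, 1 - P))
  }
  D <- 2 * (ll(MA, NA_, pA) + ll(MB, NB, pB) -
              ll(MA, NA_, p0) - ll(MB, NB, p0))
  D <- pmax(D, 0)
  pearson <- function(M, N, P) {
    denom <- N * P * (1 - P)
    r <- (M - N * P)^2 / denom
    r[denom == 0] <- 0
    rowSums(r)
  }
  K <- ncol(MA) + ncol(MB)
  phi <- if (K > 2) (pearson(MA, NA_, pA) + pearson(MB, NB, pB)) / (K - 2)
    else rep(1, nrow(MA))
  Dc <- ifelse(phi > 1, D / phi, D)
  list(meth_diff = 100 * (pA - pB), p_value =
         stats::pchisq(Dc, df = 1, lower.tail = FALSE),
       statistic = D, phi = phi, level_A = 100 * pA, level_B = 100 * pB)
}

#' Two-group window test for differential methylation
#'
#' Pools counts per group into a binomial logistic model with a binary
#' group covariate (the fitted group proportions are the pooled
#' proportions) and computes the likelihood-ratio statistic against the
#' single-proportion null.  Overdispersion is estimated as the Pearson
#' statistic over its residual degrees of freedom and, when above 1,
#' scales the statistic down before the chi-squared (1 df) tail is
#' taken — binomial counts from clone replicates are frequently
#' overdispersed and the correction keeps the test calibrated.
#'
#' @param m_a,n_a methylated and total counts per sample in group A.
#' @param m_b,n_b methylated and total counts per sample in group B.
#' @return list with `meth_diff` (percentage points, A minus B),
#'   `p_value`, `statistic` (uncorrected deviance), `phi`
#'   (overdispersion), `level_A`, `level_B` (pooled levels, %).
#' @export
test_window <- function(m_a, n_a, m_b, n_b) {
  stop_if(length(m_a) < 2 || length(m_b) < 2,
          "need at least two samples per group")
  stop_if(any(n_a < m_a) || any(n_b < m_b), "counts exceed coverage")
  stop_if(sum(n_a) == 0 || sum(n_b) == 0,
          "a group has zero total coverage")
  res <- dma_test_matrix(matrix(m_a, nrow = 1), matrix(n_a, nrow = 1),
                         matrix(m_b, nrow = 1), matrix(n_b, nrow = 1))
  lapply(res, as.vector)
}

#' Run one pairwise comparison over comparable windows
#'
#' @param cw a `comparable_windows` object.
#' @param profiles named list path -> `united_profile`.
#' @param group_a,group_b haplotype groups (see
#'   [aggregate_window_counts()]); group B is the reference of the
#'   comparison (positive differentials mean A is hyper-methylated).
#' @param comparison label stored with the results.
#' @return `data.table` with per-window `meth_diff`, `p_value`,
#'   overdispersion `phi` and pooled levels; windows where any sample
#'   has zero total coverage are skipped and counted in the
#'   `"n_skipped"` attribute.
#' @export
dma_compare <- function(cw, profiles, group_a, group_b,
                        comparison = "AvB") {
  a <- aggregate_window_counts(cw, profiles, group_a)
  b <- aggregate_window_counts(cw, profiles, group_b)
  ok <- rowSums(a$N == 0) == 0 & rowSums(b$N == 0) == 0
  res <- dma_test_matrix(a$M[ok, , drop = FALSE], a$N[ok, , drop = FALSE],
                         b$M[ok, , drop = FALSE], b$N[ok, , drop = FALSE])
  out <- data.table::data.table(
    window_id = cw$windows$window_id[ok],
    ref_path = cw$windows$ref_path[ok],
    comparison = comparison, context = cw$context,
    level_A = res$level_A, level_B = res$level_B,
    meth_diff = res$meth_diff, phi = res$phi, p_value = res$p_value)
  data.table::setattr(out, "n_skipped", sum(!ok))
  out
}

#' Adjust p-values and call differential windows
#'
#' Benjamini-Hochberg adjustment within each comparison x context
#' stratum; a window is `hyper` when `q < q_max` and the differential
#' reaches the context's threshold, `hypo` symmetrically, otherwise
#' `ns`.
#'
#' @param results one or more [dma_compare()] tables (rbind-compatible).
#' @param thresholds a [dma_thresholds()].
#' @return the results with `q_value` and `call` columns.
#' @export
adjust_and_call <- function(results, thresholds = dma_thresholds()) {
  res <- data.table::as.data.table(results)
  p_value <- q_value <- NULL
  res[, q_value := stats::p.adjust(p_value, method = "BH"),
      by = c("comparison", "context")]
  dm <- thresholds$diff_min[res$context]
  res$call <- ifelse(res$q_value < thresholds$q_max & res$meth_diff >= dm,
                     "hyper",
                     ifelse(res$q_value < thresholds$q_max &
                              res$meth_diff <= -dm, "hypo", "ns"))
  res
}

#' Inherited DMR sets (iCF / iSB)
#'
#' A window inherited from CF (`iCF`) is significant with the same sign
#' in both CS-vs-SB and CF-vs-SB; a window inherited from SB (`iSB`) is
#' significant with the same sign in CS-vs-CF and SB-vs-CF.  Hyper and
#' hypo calls are kept separate.
#'
#' @param calls a called results table ([adjust_and_call()]) containing
#'   the comparisons `CSvSB`, `CFvSB`, `CSvCF` and `SBvCF`.
#' @return list with `iCF` and `iSB` tables (`window_id`, `context`,
#'   `call`).
#' @export
inherited_dmr_sets <- function(calls) {
  calls <- data.table::as.data.table(calls)
  need <- c("CSvSB", "CFvSB", "CSvCF", "SBvCF")
  missing <- setdiff(need, unique(calls$comparison))
  stop_if(length(missing) > 0,
          sprintf("missing comparison(s): %s", paste(missing, collapse = ", ")))
  pick <- function(cmp) {
    x <- calls[calls$comparison == cmp & calls$call != "ns",
               c("window_id", "context", "call"), with = FALSE]
    data.table::setnames(x, "call", paste0("call_", cmp))
  }
  set_of <- function(c1, c2) {
    m <- merge(pick(c1), pick(c2), by = c("window_id", "context"))
    m <- m[m[[paste0("call_", c1)]] == m[[paste0("call_", c2)]], ]
    data.table::data.table(window_id = m$window_id, context = m$context,
                           call = m[[paste0("call_", c1)]])
  }
  list(iCF = set_of("CSvSB", "CFvSB"), iSB = set_of("CSvCF", "SBvCF"))
}

#' Pooled methylation level of each window for a haplotype group
#'
#' @param cw a `comparable_windows` object.
#' @param profiles named list path -> `united_profile`.
#' @param group haplotype group or `"@ref"`.
#' @return `data.table` with `window_id` and `level` (%; `NA` when the
#'   group has no coverage in the window).
#' @export
window_levels <- function(cw, profiles, group = "@ref") {
  a <- aggregate_window_counts(cw, profiles, group)
  tot <- rowSums(a$N)
  data.table::data.table(window_id = cw$windows$window_id,
                         level = ifelse(tot > 0,
                                        100 * rowSums(a$M) / tot, NA_real_))
}

#' Concordance of the progeny with intra-cultivar DMRs
#'
#' For windows differentially methylated between the two haplotypes of
#' a parent, checks whether the progeny's methylation level matches at
#' least one parental haplotype: the minimum absolute delta between the
#' CS level and either haplotype level must stay below the context's
#' methylation-differential threshold.
#'
#' @param parent_calls called intra-cultivar results
#'   ([adjust_and_call()] of a hap1-vs-hap2 comparison); `level_A` and
#'   `level_B` are the two parental haplotype levels.
#' @param cs_levels [window_levels()] of the progeny on the same
#'   windows.
#' @param thresholds a [dma_thresholds()].
#' @return list with `fraction` (concordant fraction among evaluable
#'   DMRs), `records` (per-DMR deltas and verdicts) and `n_excluded`
#'   (DMRs without a progeny level).
#' @export
intra_cultivar_concordance <- function(parent_calls, cs_levels,
                                       thresholds = dma_thresholds()) {
  dmrs <- parent_calls[parent_calls$call != "ns", ]
  m <- merge(dmrs, cs_levels, by = "window_id", all.x = TRUE)
  excl <- is.na(m$level)
  m <- m[!excl, ]
  delta1 <- abs(m$level - m$level_A)
  delta2 <- abs(m$level - m$level_B)
  dmin <- pmin(delta1, delta2)
  concordant <- dmin < thresholds$diff_min[m$context]
  records <- data.table::data.table(
    window_id = m$window_id, context = m$context, call = m$call,
    level_cs = m$level, level_hap1 = m$level_A, level_hap2 = m$level_B,
    delta_min = dmin, concordant = concordant)
  list(fraction = if (nrow(records)) mean(concordant) else NA_real_,
       records = records, n_excluded = sum(excl))
}

#' Drop duplicate homologous windows across reference tilings
#'
#' When both progeny haplotypes are tiled, a window from one tiling and
#' a window from the other can describe the same homologous region.  A
#' window is a duplicate when its projected interval on another
#' reference path coincides exactly with one of that path's own
#' windows; the copy anchored on the lexicographically later reference
#' is dropped.  Intended for pooled-progeny analyses — in
#' allele-specific mode the two anchors are distinct tests and both are
#' kept.
#'
#' @param cw a `comparable_windows` object.
#' @return a deduplicated `comparable_windows` object.
#' @export
dedup_windows <- function(cw) {
  refs <- sort(unique(cw$windows$ref_path))
  drop <- character(0)
  for (i in seq_along(refs)[-1]) {
    for (j in seq_len(i - 1L)) {
      # intervals of ref_i-anchored windows projected on ref_j
      late <- cw$windows$window_id[cw$windows$ref_path == refs[i]]
      iv <- cw$intervals[cw$intervals$window_id %in% late &
                           cw$intervals$path == refs[j] &
                           !is.na(cw$intervals$start), ]
      own <- cw$windows[cw$windows$ref_path == refs[j], ]
      dup <- iv$window_id[paste(iv$start, iv$end) %in%
                            paste(own$start, own$end)]
      drop <- union(drop, dup)
    }
  }
  keep <- !cw$windows$window_id %in% drop
  structure(list(windows = cw$windows[keep, ],
                 intervals = cw$intervals[
                   !cw$intervals$window_id %in% drop, ],
                 dropped = c(cw$dropped, duplicate = length(drop)),
                 context = cw$context),
            class = "comparable_windows")
}

#' Write called DMRs as BED
#'
#' 0-based half-open intervals on the reference path; the name is the
#' window id and the score the absolute methylation differential.
#'
#' @param calls a called results table ([adjust_and_call()]); only
#'   rows with `call != "ns"` are written.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dmrs_bed <- function(calls, file) {
  dmrs <- calls[calls$call != "ns", ]
  coords <- do.call(rbind, strsplit(sub("^.*:", "", dmrs$window_id), "-"))
  if (nrow(dmrs) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  writeLines(sprintf("%s\t%s\t%s\t%s\t%.1f\t.", dmrs$ref_path,
                     coords[, 1], coords[, 2], dmrs$window_id,
                     abs(dmrs$meth_diff)), file)
  invisible(file)
}

#' Run the four standard trio comparisons and call DMRs
#'
#' Convenience wrapper computing CS-vs-SB, CF-vs-SB, CS-vs-CF and
#' SB-vs-CF over one set of comparable windows (the second cultivar of
#' each label is the reference).  In `"allele"` mode (default) the
#' progeny group uses only the window's own reference haplotype
#' interval — windows anchored on CSCF measure the CF-derived allele —
#' while the parents always pool their two haplotypes; `"pooled"` mode
#' pools both progeny haplotypes as well.
#'
#' @param cw a `comparable_windows` object.
#' @param profiles named list path -> `united_profile`.
#' @param thresholds a [dma_thresholds()].
#' @param cs_mode `"allele"` or `"pooled"`.
#' @return a called results table ([adjust_and_call()]) covering the
#'   four comparisons.
#' @export
trio_dma <- function(cw, profiles, thresholds = dma_thresholds(),
                     cs_mode = c("allele", "pooled")) {
  cs_mode <- match.arg(cs_mode)
  cs <- if (cs_mode == "allele") "@ref" else c("CSCF", "CSSB")
  cf <- c("CF1", "CF2")
  sb <- c("SB1", "SB2")
  res <- rbind(dma_compare(cw, profiles, cs, sb, "CSvSB"),
               dma_compare(cw, profiles, cf, sb, "CFvSB"),
               dma_compare(cw, profiles, cs, cf, "CSvCF"),
               dma_compare(cw, profiles, sb, cf, "SBvCF"))
  adjust_and_call(res, thresholds)
}

#' Sweep window and calling parameters
#'
#' Re-runs window construction, projection and calling over a grid of
#' window size, step, minimum cytosines and differential threshold,
#' reporting retained-window and DMR counts per cell — the screening
#' used to choose the defaults.
#'
#' @param graph chopped `sequence_graph`.
#' @param profiles named list path -> `united_profile`.
#' @param ref_paths reference paths to tile.
#' @param targets target paths for projection.
#' @param group_a,group_b comparison groups.
#' @param context cytosine context.
#' @param grid `data.frame` with columns `win`, `step`,
#'   `min_cytosines`, `diff_min` (one row per cell).
#' @param q_max significance threshold.
#' @return the grid with `n_windows` and `n_dmrs` columns.
#' @export
sweep_parameters <- function(graph, profiles, ref_paths, targets,
                             group_a, group_b, context, grid,
                             q_max = 0.01) {
  grid <- data.table::as.data.table(grid)
  grid$n_windows <- NA_integer_
  grid$n_dmrs <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    th <- dma_thresholds(q_max = q_max,
                         diff_min = stats::setNames(
                           rep(grid$diff_min[i], 3), c("CG", "CHG", "CHH")),
                         win = grid$win[i], step = grid$step[i],
                         min_cytosines = grid$min_cytosines[i])
    w <- make_reference_windows(graph, ref_paths, win = th$win,
                                step = th$step, min_len = th$min_len)
    cw <- project_windows(graph, w, targets, profiles, context, th)
    grid$n_windows[i] <- nrow(cw$windows)
    if (nrow(cw$windows) == 0L) {
      grid$n_dmrs[i] <- 0L
      next
    }
    res <- adjust_and_call(dma_compare(cw, profiles, group_a, group_b),
                           th)
    grid$n_dmrs[i] <- sum(res$call != "ns")
  }
  grid
}
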