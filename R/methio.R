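#' Cytosine site tables (bismark-style CX layout)
#'
#' A cytosine site table holds one record per (chromosome, position,
#' strand): methylated and unmethylated read counts, the cytosine
#' context (CG/CHG/CHH) and the strand-oriented trinucleotide.  The
#' on-disk layout is the 7-column tab-separated cytosine report written
#' by bismark with `--CX_context --cytosine_report`.
#'
#' @param x a `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (1-based), `strand`, `count_methylated`, `count_unmethylated`,
#'   `context`, `trinucleotide`.
#' @return a keyed `data.table` of class `cx_table`.
#' @export
as_cx_table <- function(x) {
  x <- data.table::as.data.table(x)
  need <- c("chrom", "pos", "strand", "count_methylated",
            "count_unmethylated", "context", "trinucleotide")
  stop_if(!all(need %in% names(x)),
          sprintf("missing columns: %s",
                  paste(setdiff(need, names(x)), collapse = ", ")))
  x <- x[, need, with = FALSE]
  stop_if(any(x$count_methylated < 0) || any(x$count_unmethylated < 0),
          "counts must be non-negative")
  bad <- x$context != context_from_trinucleotide(x$trinucleotide)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "context/trinucleotide mismatch at %s:%d%s: context %s, trinucleotide %s",
      x$chrom[i], x$pos[i], x$strand[i], x$context[i], x$trinucleotide[i]),
      call. = FALSE)
  }
  stop_if(anyDuplicated(x, by = c("chrom", "pos", "strand")) > 0,
          "duplicate (chrom, pos, strand) records")
  data.table::setkeyv(x, c("chrom", "pos", "strand"))
  data.table::setattr(x, "class", c("cx_table", class(x)))
  x
}

#' Read a bismark-style CX cytosine report
#'
#' Expects the 7-column layout (chrom, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide).  The
#' context is recomputed from the trinucleotide and cross-checked; a
#' mismatch is an error naming the offending record.
#'
#' @param file path to an (uncompressed) CX report.
#' @return a `cx_table`.
#' @export
read_cx_report <- function(file) {
  x <- data.table::fread(file, header = FALSE, sep = "\t",
                         col.names = c("chrom", "pos", "strand",
                                       "count_methylated",
                                       "count_unmethylated", "context",
                                       "trinucleotide"),
                         colClasses = list(character = c(1, 3, 6, 7),
                                           integer = c(2, 4, 5)))
  as_cx_table(x)
}

#' Write a cytosine site table as a CX report
#'
#' @param table a `cx_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cx_report <- function(table, file) {
  data.table::fwrite(table, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Drop low-coverage cytosine sites
#'
#' Retains sites whose total read count (methylated + unmethylated) is
#' at least `min_cov`.
#'
#' @param table a `cx_table`.
#' @param min_cov minimum coverage (default 10).
#' @return a filtered `cx_table`.
#' @export
filter_by_coverage <- function(table, min_cov = 10) {
  stop_if(min_cov < 1, "min_cov must be >= 1")
  table[table$count_methylated + table$count_unmethylated >= min_cov, ]
}

#' Is a site methylated?
#'
#' A site counts as methylated when its methylation level reaches the
#' threshold (inclusive), 20% by default.
#'
#' @param level methylation level in percent (0-100).
#' @param threshold inclusive threshold in percent.
#' @return logical vector.
#' @export
site_methylated <- function(level, threshold = 20) {
  stop_if(any(level < 0 | level > 100, na.rm = TRUE),
          "levels must lie in [0,100]")
  level >= threshold
}

#' Scale clone coverages to a common median
#'
#' Multiplies each clone's read counts by the ratio of the across-clone
#' median coverage to its own median coverage (counts are rounded).
#' Off by default in [build_hap_profiles()]: with simulated clones drawn
#' at a common depth it is a no-op in expectation.
#'
#' @param tables named list of `cx_table`s.
#' @return the list with scaled counts.
#' @export
normalize_coverage <- function(tables) {
  med <- vapply(tables, function(t)
    stats::median(t$count_methylated + t$count_unmethylated), numeric(1))
  target <- stats::median(med)
  Map(function(t, m) {
    f <- if (m > 0) target / m else 1
    t <- data.table::copy(t)
    t$count_methylated <- as.integer(round(t$count_methylated * f))
    t$count_unmethylated <- as.integer(round(t$count_unmethylated * f))
    t
  }, tables, med)
}

#' Unite per-clone cytosine tables into a common-site profile
#'
#' Intersects the (chromosome, position, strand) keys of all clones —
#' strands are kept separate (no destranding) — and keeps per-clone
#' counts side by side: downstream differential testing treats clones
#' as biological replicates, so counts are never averaged here.  Each
#' clone `k` contributes columns `meth_k`, `cov_k` and `level_k`
#' (percent); `level_mean` is the across-clone mean level.
#'
#' @param tables named list of `cx_table`s on the same coordinates,
#'   typically already coverage-filtered.
#' @param destrand must be `FALSE` (strand merging is not supported;
#'   the argument documents the convention).
#' @return a keyed `data.table` of class `united_profile`; attribute
#'   `"clones"` holds the clone names.
#' @export
unite_clones <- function(tables, destrand = FALSE) {
  stop_if(!identical(destrand, FALSE), "destrand = TRUE is not supported")
  stop_if(length(tables) < 2L, "need at least two clone tables")
  keys <- c("chrom", "pos", "strand")
  common <- tables[[1L]][, c(keys, "context", "trinucleotide"), with = FALSE]
  for (k in seq.int(2L, length(tables))) {
    common <- common[tables[[k]][, keys, with = FALSE], on = keys,
                     nomatch = NULL]
  }
  if (nrow(common) == 0L)
    warning("no sites shared by all clones; empty profile")
  out <- data.table::copy(common)
  for (k in seq_along(tables)) {
    tk <- tables[[k]][common[, keys, with = FALSE], on = keys]
    m <- tk$count_methylated
    cov <- m + tk$count_unmethylated
    out[[paste0("meth_", k)]] <- m
    out[[paste0("cov_", k)]] <- cov
    out[[paste0("level_", k)]] <- ifelse(cov > 0, 100 * m / cov, NA_real_)
  }
  lv <- as.matrix(out[, paste0("level_", seq_along(tables)), with = FALSE])
  out$level_mean <- rowMeans(lv, na.rm = TRUE)
  data.table::setkeyv(out, keys)
  data.table::setattr(out, "clones",
                      names(tables) %||% paste0("clone", seq_along(tables)))
  data.table::setattr(out, "class", c("united_profile", class(out)))
  out
}

#' Build per-path united profiles for all cultivars
#'
#' Convenience wrapper running the standard per-clone processing:
#' coverage filtering (`min_cov`), then uniting the clones of each
#' cultivar, split by haplotype path.
#'
#' @param tables cultivar -> clone -> `cx_table`, as produced by
#'   [simulate_methylomes()].
#' @param min_cov minimum per-clone coverage (default 10).
#' @param normalize scale clone coverages to a common median before
#'   uniting (default `FALSE`).
#' @return named list: path name -> `united_profile`.
#' @export
build_hap_profiles <- function(tables, min_cov = 10, normalize = FALSE) {
  out <- list()
  for (cv in names(tables)) {
    clones <- lapply(tables[[cv]], filter_by_coverage, min_cov = min_cov)
    if (normalize) clones <- normalize_coverage(clones)
    paths <- unique(unlist(lapply(clones, function(t) unique(t$chrom))))
    for (pn in paths) {
      per_path <- lapply(clones, function(t) t[t$chrom == pn, ])
      out[[pn]] <- unite_clones(per_path)
    }
  }
  out
}
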