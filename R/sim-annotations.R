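#' Simulate gene and repeat annotations with known methylation classes
#'
#' Places non-overlapping multi-exon genes on the ancestral coordinates
#' of each chromosome, alternating random strands, with repeats in the
#' intergenic space and inside a configurable fraction of introns.  A
#' designated number of genes per chromosome is labelled `gbM` and
#' `teM`; [simulate_methylomes()] uses those labels to force the
#' corresponding exonic methylation states, so the labels are recovered
#' by construction and serve as classification ground truth.
#'
#' @param truth a `trio_truth`.
#' @param config the matching [trio_config()]; fields `n_genes`,
#'   `gene_length`, `n_exons`, `intron_length`, `n_repeats`,
#'   `repeat_length`, `intron_te_fraction`, `n_gbm`, `n_tem` drive the
#'   layout.
#' @return a list with `genes` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `class`; 1-based inclusive), `exons` (`gene_id`,
#'   `exon_number`, `chrom`, `start`, `end`) and `repeats`
#'   (`repeat_id`, `chrom`, `start`, `end`, `intronic`).
#' @export
simulate_annotations <- function(truth, config) {
  set.seed(config$seed + 2L)
  L <- config$chrom_length
  glen <- config$gene_length
  n_ex <- config$n_exons
  ilen <- config$intron_length
  stop_if(n_ex < 1, "n_exons must be >= 1")
  exlen <- (glen - (n_ex - 1L) * ilen) %/% n_ex
  stop_if(exlen < 50, "gene_length too short for the requested exon layout")
  stop_if(config$n_gbm + config$n_tem > config$n_genes,
          "n_gbm + n_tem exceeds n_genes")

  genes <- list()
  exons <- list()
  repeats <- list()
  rep_n <- 0L
  for (chrom in truth$chromosomes) {
    gap <- 500L
    pitch <- glen + gap
    usable <- L - 2001L                      # keep clear of chromosome ends
    n_slots <- max((usable - 1000L) %/% pitch, 0L)
    stop_if(n_slots < config$n_genes,
            sprintf("cannot place %d non-overlapping genes on %d bp",
                    config$n_genes, L))
    slot_start <- 1001L + (seq_len(n_slots) - 1L) * pitch
    starts <- sort(sample(slot_start, config$n_genes))
    strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    cls <- rep("none", config$n_genes)
    forced <- sample.int(config$n_genes, config$n_gbm + config$n_tem)
    cls[forced[seq_len(config$n_gbm)]] <- "gbM"
    if (config$n_tem > 0)
      cls[forced[config$n_gbm + seq_len(config$n_tem)]] <- "teM"
    ids <- sprintf("%s_g%03d", chrom, seq_len(config$n_genes))
    genes[[chrom]] <- data.table::data.table(
      gene_id = ids, chrom = chrom, start = starts,
      end = starts + glen - 1L, strand = strands, class = cls)

    ex_start <- lapply(starts, function(s)
      s + (seq_len(n_ex) - 1L) * (exlen + ilen))
    exons[[chrom]] <- data.table::data.table(
      gene_id = rep(ids, each = n_ex),
      exon_number = rep(seq_len(n_ex), config$n_genes),
      chrom = chrom,
      start = unlist(ex_start),
      end = unlist(ex_start) + exlen - 1L)

    # intronic repeats for a fraction of multi-exon genes
    if (n_ex > 1L && config$intron_te_fraction > 0) {
      te_genes <- which(stats::runif(config$n_genes) <
                          config$intron_te_fraction)
      for (gi in te_genes) {
        intron_no <- sample.int(n_ex - 1L, 1L)
        i_start <- starts[gi] + intron_no * exlen + (intron_no - 1L) * ilen
        rlen <- min(config$repeat_length, ilen - 2L)
        if (rlen < 10L) next
        rep_n <- rep_n + 1L
        repeats[[length(repeats) + 1L]] <- data.table::data.table(
          repeat_id = sprintf("rep%04d", rep_n), chrom = chrom,
          start = i_start + 1L, end = i_start + rlen, intronic = TRUE)
      }
    }
    # intergenic repeats between gene slots
    if (config$n_repeats > 0) {
      gaps_start <- c(1L, genes[[chrom]]$end + 100L)
      gaps_end <- c(genes[[chrom]]$start - 100L, L)
      wide <- which(gaps_end - gaps_start >= config$repeat_length + 10L)
      stop_if(length(wide) == 0L, "no intergenic space for repeats")
      pick <- sample(wide, config$n_repeats, replace = TRUE)
      for (w in pick) {
        s <- gaps_start[w] +
          sample.int(gaps_end[w] - gaps_start[w] - config$repeat_length, 1L)
        rep_n <- rep_n + 1L
        repeats[[length(repeats) + 1L]] <- data.table::data.table(
          repeat_id = sprintf("rep%04d", rep_n), chrom = chrom,
          start = s, end = s + config$repeat_length - 1L, intronic = FALSE)
      }
    }
  }
  list(genes = data.table::rbindlist(genes),
       exons = data.table::rbindlist(exons),
       repeats = if (length(repeats)) data.table::rbindlist(repeats)
         else data.table::data.table(repeat_id = character(),
                                     chrom = character(), start = integer(),
                                     end = integer(), intronic = logical()))
}

#' Lift an ancestral interval onto a haplotype path
#'
#' Uses the generator's ancestral coordinate map: the lifted interval
#' spans the haplotype bases descending from ancestral positions inside
#' the query (indels inside the interval shift its length).
#'
#' @param truth a `trio_truth`.
#' @param path path name.
#' @param start,end 1-based inclusive ancestral interval.
#' @return integer `c(start, end)` (1-based inclusive) on the path, or
#'   `NULL` when no base of the interval survives on the path.
#' @export
lift_ancestral_interval <- function(truth, path, start, end) {
  amap <- truth$anc_maps[[path]]
  stop_if(is.null(amap), sprintf("unknown path '%s'", path))
  hit <- which(!is.na(amap) & amap >= start - 1L & amap <= end - 1L)
  if (length(hit) == 0L) return(NULL)
  c(min(hit), max(hit))
}

#' Lift a whole annotation set onto a haplotype path
#'
#' @param truth a `trio_truth`.
#' @param annotations output of [simulate_annotations()].
#' @param path target path name.
#' @return the annotation list with `start`/`end` in path coordinates
#'   and `chrom` set to the path name; features that do not survive on
#'   the path are dropped.
#' @export
lift_annotations <- function(truth, annotations, path) {
  chrom <- path_chromosome(path, truth$config$n_chromosomes)
  lift_tab <- function(tab) {
    tab <- tab[tab$chrom == chrom, ]
    if (nrow(tab) == 0L) return(tab)
    li <- lapply(seq_len(nrow(tab)), function(i)
      lift_ancestral_interval(truth, path, tab$start[i], tab$end[i]))
    keep <- !vapply(li, is.null, logical(1))
    tab <- tab[keep, ]
    li <- li[keep]
    tab$start <- vapply(li, `[`, integer(1), 1L)
    tab$end <- vapply(li, `[`, integer(1), 2L)
    tab$chrom <- path
    tab
  }
  list(genes = lift_tab(annotations$genes),
       exons = lift_tab(annotations$exons),
       repeats = lift_tab(annotations$repeats))
}

#' Write gene annotations as GFF3
#'
#' Emits `gene` and `exon` features with 1-based inclusive coordinates.
#'
#' @param annotations list with `genes` and `exons` tables.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(annotations, file) {
  g <- annotations$genes
  e <- merge(annotations$exons,
             g[, c("gene_id", "strand"), with = FALSE], by = "gene_id")
  lines <- c("##gff-version 3",
             sprintf("%s\tpanmeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id),
             sprintf("%s\tpanmeth\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                     e$chrom, e$start, e$end, e$strand, e$gene_id,
                     e$exon_number, e$gene_id))
  writeLines(lines, file)
  invisible(file)
}

#' Write repeats as BED (0-based half-open)
#'
#' @param repeats table with `chrom`, `start`, `end` (1-based
#'   inclusive), `repeat_id`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_repeats_bed <- function(repeats, file) {
  if (nrow(repeats) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s", repeats$chrom, repeats$start - 1L,
                     repeats$end, repeats$repeat_id), file)
  invisible(file)
}
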