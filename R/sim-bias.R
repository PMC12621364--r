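#' Emulate single-linear-reference methylation calls
#'
#' Re-expresses one sample haplotype's methylome on the coordinates of a
#' single reference haplotype, reproducing the biases of mapping
#' bisulfite reads from a divergent genome onto a linear reference:
#'
#' * sites homologous between sample and reference keep their counts;
#' * reference cytosines where the sample carries the bisulfite-
#'   indistinguishable base (C>T on the site's strand) receive fully
#'   unmethylated read counts (coverage drawn from the configured
#'   Poisson depth);
#' * reference positions absent from the sample (deletions, divergent
#'   alleles) are dropped.
#'
#' @param truth a `trio_truth`.
#' @param methylomes output of [simulate_methylomes()].
#' @param reference_haplotype `"CSCF"` or `"CSSB"`.
#' @param sample_haplotype the haplotype whose clones are re-mapped
#'   (e.g. `"SB1"`).
#' @param seed seed for the fake-coverage draws; defaults to
#'   `config$seed + 3`.
#' @return named list, one biased `cx_table` per clone, indexed on
#'   reference coordinates.
#' @export
emit_single_reference_calls <- function(truth, methylomes,
                                        reference_haplotype,
                                        sample_haplotype,
                                        seed = NULL) {
  stop_if(!reference_haplotype %in% c("CSCF", "CSSB"),
          sprintf("unknown reference haplotype '%s'", reference_haplotype))
  stop_if(!sample_haplotype %in% TRIO_HAPLOTYPES,
          sprintf("unknown sample haplotype '%s'", sample_haplotype))
  config <- truth$config
  set.seed(seed %||% (config$seed + 3L))
  cultivar <- haplotype_cultivar(sample_haplotype)
  clone_tabs <- methylomes$tables[[cultivar]]

  out <- lapply(clone_tabs, function(x) list())
  for (chrom in truth$chromosomes) {
    rp <- trio_path_name(reference_haplotype, chrom, config$n_chromosomes)
    sp <- trio_path_name(sample_haplotype, chrom, config$n_chromosomes)
    ref_sites <- cytosine_sites(truth$sequences[[rp]])
    # cytosine_sites positions are 1-based; coordinate_map is 0-based
    cmap <- coordinate_map(truth, rp, sp)          # posA = ref, posB = sample
    ref_sites$pos0 <- ref_sites$pos - 1L
    ref_sites <- merge(ref_sites, cmap[, c("posA", "posB"), with = FALSE],
                       by.x = "pos0", by.y = "posA", all.x = TRUE, sort = FALSE)
    ref_sites$sample_pos <- ref_sites$posB + 1L
    samp_seq <- truth$sequences[[sp]]
    has_pos <- !is.na(ref_sites$sample_pos)
    samp_base <- rep(NA_character_, nrow(ref_sites))
    samp_base[has_pos] <- substring(samp_seq, ref_sites$sample_pos[has_pos],
                                    ref_sites$sample_pos[has_pos])
    # the bisulfite-confusable substitution on each strand
    confusable <- ifelse(ref_sites$strand == "+", "T", "A")
    cyto_base <- ifelse(ref_sites$strand == "+", "C", "G")
    is_match <- has_pos & samp_base == cyto_base
    is_ct <- has_pos & samp_base == confusable

    for (cl in names(clone_tabs)) {
      tab <- clone_tabs[[cl]][chrom == sp]
      hit <- tab[data.table::data.table(chrom = sp,
                                        pos = ref_sites$sample_pos,
                                        strand = ref_sites$strand),
                 on = c("chrom", "pos", "strand")]
      keep_match <- is_match & !is.na(hit$count_methylated)
      rows <- list()
      if (any(keep_match)) {
        rows$match <- data.table::data.table(
          chrom = rp, pos = ref_sites$pos[keep_match],
          strand = ref_sites$strand[keep_match],
          count_methylated = hit$count_methylated[keep_match],
          count_unmethylated = hit$count_unmethylated[keep_match],
          context = ref_sites$context[keep_match],
          trinucleotide = ref_sites$trinucleotide[keep_match])
      }
      if (any(is_ct)) {
        cov <- stats::rpois(sum(is_ct), config$mean_coverage)
        rows$ct <- data.table::data.table(
          chrom = rp, pos = ref_sites$pos[is_ct],
          strand = ref_sites$strand[is_ct],
          count_methylated = 0L, count_unmethylated = cov,
          context = ref_sites$context[is_ct],
          trinucleotide = ref_sites$trinucleotide[is_ct])
      }
      res <- data.table::rbindlist(rows)
      out[[cl]][[chrom]] <- res
    }
  }
  lapply(out, function(parts) as_cx_table(data.table::rbindlist(parts)))
}
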