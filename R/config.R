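#' Configuration for the synthetic parent-progeny trio
#'
#' Describes the study design emulated by the generator: two diploid
#' parents (CF, SB) and a hybrid progeny (CS) that inherits one whole
#' haplotype from each parent, each cultivar represented by several
#' clones sharing the genotype but carrying slightly divergent
#' methylomes.  All downstream modules are exercised against the ground
#' truth this configuration pins down.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (>= 2000).
#' @param gc_content GC fraction of the ancestral sequence.
#' @param snp_rate per-bp probability of a SNP site.
#' @param indel_rate per-bp probability of a short (1-10 bp) indel.
#' @param sv_count number of large indels (>= 50 bp) across the genome.
#' @param clones_per_cultivar biological replicates per cultivar (>= 2).
#' @param mean_coverage mean per-site read coverage (Poisson).
#' @param epimutation_rate per-site probability that a progeny haplotype
#'   state differs from the inherited parental state.
#' @param clone_noise_sd clone-to-clone methylation-level noise, in
#'   percentage points.
#' @param level_methylated,level_unmethylated methylation level (%) of
#'   the two epigenetic states.
#' @param context_meth_prob named vector: per-context probability that a
#'   site is in the methylated state on a parental haplotype.  These are
#'   free parameters of the generator, not estimates of any real genome.
#' @param shared_states if `TRUE`, homologous sites share one state
#'   across all haplotypes (a global epigenetic null); if `FALSE`
#'   parental haplotypes draw states independently.
#' @param planted_dmr_fraction fraction of `planted_dmr_size` ancestral
#'   tiles carrying a planted inter-cultivar methylation differential.
#' @param planted_dmr_size tile size (bp) for planted differentials.
#' @param planted_dmr_context cytosine context of planted differentials.
#' @param planted_dmr_donor cultivar (`"CF"` or `"SB"`) whose haplotypes
#'   are methylated inside planted tiles; the other parent is
#'   unmethylated there.
#' @param bias_region_fraction fraction of `bias_region_size` ancestral
#'   tiles turned into reference-bias showcases: all haplotypes are
#'   methylated there and a fraction of cytosines carry C>T SNPs on the
#'   SB haplotypes (CF keeps the cytosine).
#' @param bias_region_size tile size (bp) for bias regions.
#' @param bias_ct_fraction fraction of bias-region cytosines converted
#'   to C>T (or G>A) SNP sites.
#' @param n_genes,gene_length,n_exons,intron_length gene annotation
#'   layout (per chromosome).
#' @param n_repeats,repeat_length intergenic repeats per chromosome.
#' @param intron_te_fraction fraction of genes receiving one intronic
#'   repeat.
#' @param n_gbm,n_tem number of genes (per chromosome) forced into the
#'   gbM and teM methylation classes.
#' @param seed integer seed driving every random choice.
#' @return a validated list of class `trio_config`.
#' @export
trio_config <- function(n_chromosomes = 1,
                        chrom_length = 50000,
                        gc_content = 0.4,
                        snp_rate = 0.005,
                        indel_rate = 5e-4,
                        sv_count = 2,
                        clones_per_cultivar = 3,
                        mean_coverage = 30,
                        epimutation_rate = 0.02,
                        clone_noise_sd = 5,
                        level_methylated = 80,
                        level_unmethylated = 2,
                        context_meth_prob = c(CG = 0.5, CHG = 0.4, CHH = 0.1),
                        shared_states = FALSE,
                        planted_dmr_fraction = 0,
                        planted_dmr_size = 200,
                        planted_dmr_context = "CG",
                        planted_dmr_donor = "CF",
                        bias_region_fraction = 0,
                        bias_region_size = 200,
                        bias_ct_fraction = 0.3,
                        n_genes = 10,
                        gene_length = 3000,
                        n_exons = 3,
                        intron_length = 400,
                        n_repeats = 10,
                        repeat_length = 300,
                        intron_te_fraction = 0.3,
                        n_gbm = 0,
                        n_tem = 0,
                        seed = 1) {
  cfg <- as.list(environment())
  rates <- c(gc_content = gc_content, snp_rate = snp_rate,
             indel_rate = indel_rate, epimutation_rate = epimutation_rate,
             planted_dmr_fraction = planted_dmr_fraction,
             bias_region_fraction = bias_region_fraction,
             bias_ct_fraction = bias_ct_fraction,
             intron_te_fraction = intron_te_fraction)
  bad <- rates < 0 | rates > 1
  stop_if(any(bad), sprintf("rates must lie in [0,1]: %s",
                            paste(names(rates)[bad], collapse = ", ")))
  stop_if(any(context_meth_prob < 0 | context_meth_prob > 1),
          "context_meth_prob values must lie in [0,1]")
  stop_if(!all(c("CG", "CHG", "CHH") %in% names(context_meth_prob)),
          "context_meth_prob needs CG, CHG and CHH entries")
  stop_if(chrom_length < 2000, "chrom_length must be >= 2000")
  stop_if(clones_per_cultivar < 2, "clones_per_cultivar must be >= 2")
  stop_if(!planted_dmr_donor %in% c("CF", "SB"),
          "planted_dmr_donor must be 'CF' or 'SB'")
  vr <- snp_rate + indel_rate
  stop_if(vr > 0 && 1 / vr < 2,
          "expected variant spacing below 2 bp; the graph degenerates")
  class(cfg) <- "trio_config"
  cfg
}

# the six haplotype names and their cultivar grouping
TRIO_HAPLOTYPES <- c("CF1", "CF2", "SB1", "SB2", "CSCF", "CSSB")
PARENT_HAPLOTYPES <- c("CF1", "CF2", "SB1", "SB2")

#' Cultivar of a haplotype or path name
#'
#' Path names may carry a `#chrN` suffix in multi-chromosome graphs.
#'
#' @param x character vector of haplotype or path names.
#' @return character vector over `"CF"`, `"SB"`, `"CS"`.
#' @export
haplotype_cultivar <- function(x) {
  hap <- sub("#.*$", "", x)
  out <- rep(NA_character_, length(x))
  out[hap %in% c("CF1", "CF2")] <- "CF"
  out[hap %in% c("SB1", "SB2")] <- "SB"
  out[hap %in% c("CSCF", "CSSB")] <- "CS"
  out
}

#' Path names belonging to a haplotype
#'
#' @param truth a `trio_truth` object.
#' @param hap haplotype name (e.g. `"CF1"`).
#' @return character vector of path names, one per chromosome.
#' @export
haplotype_paths <- function(truth, hap) {
  nm <- names(truth$sequences)
  nm[sub("#.*$", "", nm) == hap]
}

trio_path_name <- function(hap, chrom, n_chromosomes) {
  if (n_chromosomes == 1L) hap else paste0(hap, "#", chrom)
}
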