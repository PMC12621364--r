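#' Enumerate cytosine sites of a DNA sequence
#'
#' Both strands are reported: a `C` on the forward strand is a site on
#' strand `+`; a `G` on the forward strand is a cytosine on the reverse
#' strand and is reported on strand `-` with its trinucleotide read from
#' the reverse complement.  Contexts follow the usual plant convention
#' (CG, CHG, CHH with H = A/C/T); truncated trinucleotides at sequence
#' ends are padded with `N`.
#'
#' @param seq a DNA string.
#' @return `data.table` with columns `pos` (1-based), `strand`,
#'   `trinucleotide`, `context`.
#' @export
cytosine_sites <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  padded <- c("N", "N", ch, "N", "N")
  cpos <- which(ch == "C")
  gpos <- which(ch == "G")
  tri_plus <- paste0(padded[cpos + 2L], padded[cpos + 3L], padded[cpos + 4L])
  comp <- .COMP[padded]
  tri_minus <- paste0(comp[gpos + 2L], comp[gpos + 1L], comp[gpos])
  dt <- data.table::data.table(
    pos = c(cpos, gpos),
    strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
    trinucleotide = c(tri_plus, tri_minus))
  data.table::setorderv(dt, c("pos", "strand"))
  dt$context <- context_from_trinucleotide(dt$trinucleotide)
  dt
}

#' Simulate per-clone methylomes for the trio
#'
#' Every cytosine on every haplotype is assigned one of two epigenetic
#' states (methylated at `level_methylated` %, unmethylated at
#' `level_unmethylated` %).  Parental haplotypes draw states per context
#' (independently per haplotype, or once per ancestral site when
#' `shared_states` is set); progeny haplotypes inherit the state of the
#' copied parental haplotype, flipped with probability
#' `epimutation_rate`.  Optional planted differentials, bias regions and
#' forced gene methylation classes override the drawn states.  Per
#' clone, the observed level adds truncated Gaussian noise, coverage is
#' Poisson and the methylated count binomial.
#'
#' @param truth a `trio_truth` from [simulate_trio_genomes()].
#' @param config the [trio_config()] used to generate `truth`.
#' @param annotations optional annotation set from
#'   [simulate_annotations()]; when given, genes labelled `gbM` have
#'   exonic CG sites forced methylated (CHG/CHH unmethylated) and genes
#'   labelled `teM` have all exonic contexts forced methylated, on every
#'   haplotype.
#' @return a list with `tables` (cultivar -> clone -> cytosine-report
#'   `data.table`), `site_states` (per path/pos/strand truth state and
#'   level) and `planted_dmrs` (ancestral tiles carrying the planted
#'   differential, possibly empty).
#' @export
simulate_methylomes <- function(truth, config, annotations = NULL) {
  set.seed(config$seed + 1L)
  n_chr <- config$n_chromosomes
  probs <- config$context_meth_prob
  mu <- c(config$level_unmethylated, config$level_methylated)

  # choose planted-differential tiles on ancestral coordinates
  planted <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer())
  if (config$planted_dmr_fraction > 0) {
    rows <- lapply(truth$chromosomes, function(chrom) {
      size <- config$planted_dmr_size
      tiles <- seq(1L, config$chrom_length - size + 1L, by = size)
      n_pick <- round(length(tiles) * config$planted_dmr_fraction)
      if (n_pick == 0L) return(NULL)
      picks <- sort(sample(tiles, n_pick))
      data.table::data.table(chrom = chrom, start = picks,
                             end = picks + config$planted_dmr_size - 1L)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) planted <- data.table::rbindlist(rows)
  }

  # per-path site tables with ancestral coordinates
  sites <- list()
  for (pn in names(truth$sequences)) {
    s <- cytosine_sites(truth$sequences[[pn]])
    s$anc <- truth$anc_maps[[pn]][s$pos]
    s$path <- pn
    s$chrom <- path_chromosome(pn, n_chr)
    sites[[pn]] <- s
  }

  # shared-state draws are keyed on (chromosome, ancestral pos, strand);
  # the key range extends past the chromosome end to cover the
  # pseudo-ancestral coordinates of shared insertion alleles
  shared_u <- NULL
  if (config$shared_states) {
    shared_u <- lapply(stats::setNames(truth$chromosomes, truth$chromosomes),
                       function(ch) {
      top <- max(config$chrom_length,
                 max(unlist(lapply(sites, function(s)
                   if (s$chrom[1L] == ch) max(c(s$anc, 0L), na.rm = TRUE)
                   else 0L))) + 1L)
      list("+" = stats::runif(top), "-" = stats::runif(top))
    })
  }

  hap_of <- function(pn) sub("#.*$", "", pn)
  states <- list()
  for (pn in names(sites)) {
    hap <- hap_of(pn)
    if (!hap %in% PARENT_HAPLOTYPES) next
    s <- sites[[pn]]
    p <- probs[s$context]
    if (config$shared_states) {
      u <- stats::runif(nrow(s))
      def <- !is.na(s$anc)
      uu <- shared_u[[s$chrom[1L]]]
      plus <- def & s$strand == "+"
      minus <- def & s$strand == "-"
      u[plus] <- uu[["+"]][s$anc[plus] + 1L]
      u[minus] <- uu[["-"]][s$anc[minus] + 1L]
    } else {
      u <- stats::runif(nrow(s))
    }
    states[[pn]] <- as.integer(u < p)
  }

  # ancestral-region overrides on the parents (progeny copies them)
  states <- apply_state_overrides(states, sites, truth, config, planted,
                                  annotations)

  # progeny: copy the inherited parental haplotype, then epimutate
  for (cs in c("CSCF", "CSSB")) {
    src <- truth$inheritance[[cs]]
    for (chrom in truth$chromosomes) {
      pn <- trio_path_name(cs, chrom, n_chr)
      sp <- trio_path_name(src, chrom, n_chr)
      st <- states[[sp]]
      if (config$epimutation_rate > 0) {
        flip <- stats::rbinom(length(st), 1L, config$epimutation_rate) == 1L
        st[flip] <- 1L - st[flip]
      }
      states[[pn]] <- st
    }
  }

  site_states <- data.table::rbindlist(lapply(names(sites), function(pn) {
    s <- sites[[pn]][, c("path", "chrom", "pos", "strand", "context",
                         "trinucleotide", "anc"), with = FALSE]
    s$state <- states[[pn]]
    s$level <- mu[s$state + 1L]
    s
  }))

  # clone observations
  cultivar_haps <- list(CF = c("CF1", "CF2"), SB = c("SB1", "SB2"),
                        CS = c("CSCF", "CSSB"))
  tables <- list()
  for (cv in names(cultivar_haps)) {
    pns <- unlist(lapply(cultivar_haps[[cv]], function(h)
      vapply(truth$chromosomes, function(ch) trio_path_name(h, ch, n_chr),
             character(1))))
    base <- site_states[site_states$path %in% pns]
    tables[[cv]] <- list()
    for (k in seq_len(config$clones_per_cultivar)) {
      lvl <- pmin(pmax(base$level +
                         stats::rnorm(nrow(base), 0, config$clone_noise_sd),
                       0), 100)
      cov <- stats::rpois(nrow(base), config$mean_coverage)
      meth <- stats::rbinom(nrow(base), cov, lvl / 100)
      tab <- data.table::data.table(
        chrom = base$path, pos = base$pos, strand = base$strand,
        count_methylated = meth, count_unmethylated = cov - meth,
        context = base$context, trinucleotide = base$trinucleotide)
      tables[[cv]][[paste0(cv, "_clone", k)]] <- as_cx_table(tab)
    }
  }

  list(tables = tables, site_states = site_states, planted_dmrs = planted)
}

path_chromosome <- function(pn, n_chromosomes) {
  if (n_chromosomes == 1L) rep("chr1", length(pn))
  else sub("^.*#", "", pn)
}

# force states inside planted tiles, bias regions and forced gene
# classes; operates on parental haplotypes only (progeny copies later)
apply_state_overrides <- function(states, sites, truth, config, planted,
                                  annotations) {
  donor <- if (config$planted_dmr_donor == "CF") c("CF1", "CF2")
    else c("SB1", "SB2")
  other <- setdiff(PARENT_HAPLOTYPES, donor)
  for (pn in names(states)) {
    s <- sites[[pn]]
    hap <- sub("#.*$", "", pn)
    in_region <- function(reg) {
      if (nrow(reg) == 0L) return(rep(FALSE, nrow(s)))
      reg <- reg[reg$chrom == s$chrom[1L], ]
      if (nrow(reg) == 0L) return(rep(FALSE, nrow(s)))
      anc1 <- s$anc + 1L
      hit <- rep(FALSE, nrow(s))
      def <- !is.na(anc1)
      idx <- findInterval(anc1[def], reg$start)
      ok <- idx >= 1L & anc1[def] <= reg$end[pmax(idx, 1L)]
      hit[def] <- ok
      hit
    }
    if (nrow(planted)) {
      hit <- in_region(planted) & s$context == config$planted_dmr_context
      if (hap %in% donor) states[[pn]][hit] <- 1L
      if (hap %in% other) states[[pn]][hit] <- 0L
    }
    if (nrow(truth$bias_regions)) {
      states[[pn]][in_region(truth$bias_regions)] <- 1L
    }
    if (!is.null(annotations)) {
      forced <- annotations$genes[annotations$genes$class %in% c("gbM", "teM"), ]
      if (nrow(forced)) {
        ex <- merge(annotations$exons,
                    forced[, c("gene_id", "chrom", "class")],
                    by = c("gene_id", "chrom"))
        for (cl in c("gbM", "teM")) {
          exc <- ex[ex$class == cl & ex$chrom == s$chrom[1L], ]
          if (nrow(exc) == 0L) next
          exc <- exc[order(exc$start), ]
          anc1 <- s$anc + 1L
          hit <- rep(FALSE, nrow(s))
          def <- !is.na(anc1)
          idx <- findInterval(anc1[def], exc$start)
          ok <- idx >= 1L & anc1[def] <= exc$end[pmax(idx, 1L)]
          hit[def] <- ok
          if (cl == "gbM") {
            states[[pn]][hit & s$context == "CG"] <- 1L
            states[[pn]][hit & s$context != "CG"] <- 0L
          } else {
            states[[pn]][hit] <- 1L
          }
        }
      }
    }
  }
  states
}
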