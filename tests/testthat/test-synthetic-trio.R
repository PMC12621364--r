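test_that("configuration invariants are enforced", {
  expect_error(trio_config(snp_rate = 1.5), "rates")
  expect_error(trio_config(chrom_length = 1000), "chrom_length")
  expect_error(trio_config(clones_per_cultivar = 1), "clones_per_cultivar")
  expect_error(trio_config(snp_rate = 0.5, indel_rate = 0.2), "spacing")
  expect_error(trio_config(context_meth_prob = c(CG = 0.5, CHG = 0.1)),
               "CHH")
  expect_s3_class(trio_config(), "trio_config")
})

test_that("identical configuration and seed give identical outputs", {
  cfg <- trio_config(chrom_length = 6000, seed = 55, n_genes = 1)
  s1 <- simulate_trio(cfg, annotations = FALSE)
  s2 <- simulate_trio(cfg, annotations = FALSE)
  expect_identical(s1$truth$sequences, s2$truth$sequences)
  expect_identical(s1$truth$variants, s2$truth$variants)
  expect_identical(s1$methylomes$tables$CF[[1]], s2$methylomes$tables$CF[[1]])
  expect_identical(s1$methylomes$site_states, s2$methylomes$site_states)
})

test_that("zero variation collapses the trio to one linear sequence", {
  cfg <- trio_config(chrom_length = 3000, snp_rate = 0, indel_rate = 0,
                     sv_count = 0, seed = 4, n_genes = 1)
  sim <- simulate_trio_genomes(cfg)
  expect_length(unique(unlist(sim$truth$sequences)), 1L)
  expect_length(sim$graph$nodes, 1L)
  expect_identical(nrow(sim$truth$variants), 0L)
})

test_that("every path spells its haplotype sequence byte-identically", {
  sim <- trio_fixture("basic")
  for (p in names(sim$graph$paths)) {
    expect_identical(path_sequence(sim$graph, p), sim$truth$sequences[[p]])
    expect_identical(path_sequence(sim$chopped, p), sim$truth$sequences[[p]])
  }
  # progeny haplotypes are byte-identical to their source parent
  inh <- sim$truth$inheritance
  expect_identical(sim$truth$sequences[["CSCF"]],
                   sim$truth$sequences[[inh[["CSCF"]]]])
  expect_identical(sim$truth$sequences[["CSSB"]],
                   sim$truth$sequences[[inh[["CSSB"]]]])
})

test_that("progeny methylomes inherit parental states exactly when noiseless", {
  cfg <- trio_config(chrom_length = 5000, seed = 9, epimutation_rate = 0,
                     clone_noise_sd = 0, n_genes = 1)
  sim <- simulate_trio(cfg, annotations = FALSE)
  ss <- sim$methylomes$site_states
  src <- sim$truth$inheritance[["CSCF"]]
  a <- ss[ss$path == "CSCF", ]
  b <- ss[ss$path == src, ]
  expect_identical(a$pos, b$pos)
  expect_identical(a$level, b$level)
})

test_that("epimutations flip the inherited state at the configured rate", {
  cfg <- trio_config(chrom_length = 40000, seed = 10, epimutation_rate = 0.1,
                     n_genes = 1)
  sim <- simulate_trio(cfg, annotations = FALSE)
  ss <- sim$methylomes$site_states
  src <- sim$truth$inheritance[["CSSB"]]
  flips <- mean(ss[ss$path == "CSSB", ]$state != ss[ss$path == src, ]$state)
  n <- nrow(ss[ss$path == "CSSB", ])
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(flips - 0.1), 3 * se)
})

test_that("observed counts are binomial draws around the state level", {
  # methylated sites at 30x: mean methylated fraction within 3 SE of 0.8
  sim <- trio_fixture("basic")
  ss <- sim$methylomes$site_states
  tab <- sim$methylomes$tables$CF[[1]]
  m <- merge(tab, ss[ss$path %in% c("CF1", "CF2"), ],
             by.x = c("chrom", "pos", "strand"),
             by.y = c("path", "pos", "strand"))
  hot <- m[m$state == 1L & m$count_methylated + m$count_unmethylated > 0, ]
  frac <- sum(hot$count_methylated) /
    sum(hot$count_methylated + hot$count_unmethylated)
  # clone noise (sd 5) keeps the expectation at 0.80 but widens it a bit
  se <- sqrt(0.8 * 0.2 / (30 * nrow(hot))) + 0.05 / sqrt(nrow(hot))
  expect_lt(abs(frac - 0.80), 3 * se + 0.005)
})

test_that("reverse-strand cytosines carry reverse-complement trinucleotides", {
  s <- cytosine_sites("AACGTG")
  # the G at position 4 is a minus-strand cytosine in CG context
  row <- s[s$pos == 4 & s$strand == "-", ]
  expect_identical(row$trinucleotide, "CGT")  # revcomp of ACG
  expect_identical(row$context, "CG")
  # the G at position 6 reads CAC on the minus strand -> CHH
  row6 <- s[s$pos == 6 & s$strand == "-", ]
  expect_identical(row6$trinucleotide, "CAC")
  expect_identical(row6$context, "CHH")
  # plus-strand C at position 3 reads CGT -> CG
  expect_identical(s[s$pos == 3 & s$strand == "+", ]$context, "CG")
})

test_that("CX reports round-trip and cover every simulated cytosine", {
  sim <- trio_fixture("basic")
  f <- withr::local_tempfile(fileext = ".txt")
  tab <- sim$methylomes$tables$SB[[2]]
  write_cx_report(tab, f)
  back <- read_cx_report(f)
  expect_identical(nrow(back), nrow(tab))
  expect_identical(back$count_methylated, tab$count_methylated)
  n_truth <- nrow(sim$methylomes$site_states[
    sim$methylomes$site_states$path %in% c("SB1", "SB2"), ])
  expect_identical(nrow(tab), n_truth)
})

test_that("annotation layout respects placement and intron-repeat rates", {
  cfg <- trio_config(chrom_length = 200000, seed = 31, n_genes = 50,
                     intron_te_fraction = 0.8)
  sim <- simulate_trio_genomes(cfg)
  ann <- simulate_annotations(sim$truth, cfg)
  g <- ann$genes
  expect_identical(nrow(g), 50L)
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-nrow(g)]))
  # ~80% of genes should hold an intronic repeat (binomial tolerance)
  n_te_genes <- sum(vapply(seq_len(nrow(g)), function(i)
    any(ann$repeats$intronic & ann$repeats$start >= g$start[i] &
          ann$repeats$end <= g$end[i]), logical(1)))
  se <- sqrt(0.8 * 0.2 * 50)
  expect_lt(abs(n_te_genes - 40), 3 * se + 1)
  # too many genes for the chromosome is an error
  expect_error(simulate_annotations(
    sim$truth, trio_config(chrom_length = 200000, n_genes = 500)),
    "cannot place")
  # zero repeats write an empty BED
  cfg0 <- trio_config(chrom_length = 20000, seed = 5, n_genes = 2,
                      n_repeats = 0, intron_te_fraction = 0)
  sim0 <- simulate_trio_genomes(cfg0)
  ann0 <- simulate_annotations(sim0$truth, cfg0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_repeats_bed(ann0$repeats, f)
  expect_identical(length(readLines(f)), 0L)
})

test_that("single-reference calls reproduce the known mapping biases", {
  sim <- trio_fixture("bias")
  truth <- sim$truth
  # self-mapping is the identity
  self <- emit_single_reference_calls(truth, sim$methylomes, "CSCF", "CSCF")
  orig <- sim$methylomes$tables$CS[[1]]
  orig <- orig[orig$chrom == "CSCF", ]
  expect_identical(nrow(self[[1]]), nrow(orig))
  expect_identical(self[[1]]$count_methylated, orig$count_methylated)

  # a methylated site under a sample-side C>T SNP is emitted fully
  # unmethylated on the reference
  sb <- truth$inheritance[["CSSB"]]
  biased <- emit_single_reference_calls(truth, sim$methylomes, "CSCF", sb)
  planted <- truth$variants[truth$variants$planted_ct == TRUE, ]
  expect_gt(nrow(planted), 50L)
  amap <- truth$anc_maps[["CSCF"]]
  ref_pos <- match(planted$start - 1L, amap)   # 1-based ref position
  hits <- biased[[1]][biased[[1]]$pos %in% ref_pos, ]
  expect_gt(nrow(hits), 0.8 * nrow(planted))
  expect_true(all(hits$count_methylated == 0L))

  # sites inside a sample-side deletion disappear from the output
  dels <- truth$variants[truth$variants$type == "DEL" &
                           truth$variants[[sb]] == 1L, ]
  if (nrow(dels) > 0L) {
    anc_gone <- unlist(lapply(seq_len(nrow(dels)), function(i)
      dels$start[i]:(dels$start[i] + dels$ref_len[i] - 1L))) - 1L
    ref_gone <- stats::na.omit(match(anc_gone, amap))
    expect_false(any(biased[[1]]$pos %in% ref_gone))
  }

  expect_error(emit_single_reference_calls(truth, sim$methylomes,
                                           "CF1", "SB1"),
               "reference haplotype")
})
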