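fake_profile <- function(pos, level, context = "CG", strand = "+") {
  structure(data.table::data.table(
    chrom = "p", pos = as.integer(pos), strand = strand, context = context,
    trinucleotide = "CNN",
    meth_1 = as.integer(round(level / 10)), cov_1 = 10L, level_1 = level,
    level_mean = level), class = c("united_profile", "data.table",
                                   "data.frame"))
}

test_that("metagene binning is strand-aware and matches hand computation", {
  genes <- data.table::data.table(gene_id = "g1", chrom = "p",
                                  start = 2001L, end = 4000L, strand = "+")
  # uniform methylation gives a flat profile
  prof <- fake_profile(seq(900, 5100, by = 7), 50)
  mp <- metagene_profile(genes, prof, flank = 1000, bins = 100)
  expect_true(all(abs(mp$level - 50) < 1e-9))
  expect_true(all(mp$bin >= 1 & mp$bin <= 100))

  # hand-placed sites: one per segment at known bins
  prof2 <- fake_profile(c(1001L, 2001L, 3000L, 4500L),
                        c(10, 30, 60, 90))
  mp2 <- metagene_profile(genes, prof2, flank = 1000, bins = 100)
  expect_equal(mp2[mp2$segment == "upstream", ]$bin, 1L)     # start-1000
  expect_equal(mp2[mp2$segment == "upstream", ]$level, 10)
  body <- mp2[mp2$segment == "body", ]
  expect_identical(body$bin, c(1L, 50L))    # positions 2001 and 3000
  expect_equal(body$level, c(30, 60))
  expect_equal(mp2[mp2$segment == "downstream", ]$bin, 50L)  # 500 bp past end
  expect_equal(mp2[mp2$segment == "downstream", ]$level, 90)

  # minus-strand gene: upstream bin 1 lies 3' of the gene
  gm <- data.table::copy(genes)
  gm$strand <- "-"
  mp3 <- metagene_profile(gm, fake_profile(5000L, 80), flank = 1000,
                          bins = 100)
  expect_identical(mp3$segment, "upstream")
  expect_identical(mp3$bin, 1L)
})

test_that("gene methylation classes follow the gbM/teM thresholds", {
  genes <- data.table::data.table(gene_id = c("a", "b", "c"), chrom = "p",
                                  start = c(1L, 101L, 201L),
                                  end = c(100L, 200L, 300L), strand = "+")
  exons <- data.table::data.table(gene_id = c("a", "b", "c"),
                                  start = c(1L, 101L, 201L),
                                  end = c(100L, 200L, 300L))
  prof <- rbind(
    fake_profile(c(10, 20, 30), c(60, 2, 1), c("CG", "CHG", "CHH")),
    fake_profile(c(110, 120, 130), c(60, 30, 10), c("CG", "CHG", "CHH")),
    fake_profile(c(210, 220, 230), c(3, 3, 3), c("CG", "CHG", "CHH")))
  cls <- classify_gene_methylation(genes, exons, prof)
  expect_identical(cls$class, c("gbM", "teM", "other"))
  # a gene with no exonic CHH site is other and flagged
  prof2 <- fake_profile(c(10, 20), c(60, 2), c("CG", "CHG"))
  cls2 <- classify_gene_methylation(genes[1, ], exons[1, ], prof2)
  expect_identical(cls2$class, "other")
  expect_true(cls2$missing_context)
})

test_that("classification equals brute-force recomputation on synthetic genes", {
  sim <- trio_fixture("genes")
  ann <- lift_annotations(sim$truth, sim$annotations, "CF1")
  prof <- sim$profiles[["CF1"]]
  cls <- classify_gene_methylation(ann$genes, ann$exons, prof)
  for (i in seq_len(nrow(ann$genes))) {
    gid <- ann$genes$gene_id[i]
    ex <- ann$exons[ann$exons$gene_id == gid, ]
    inside <- rep(FALSE, nrow(prof))
    for (j in seq_len(nrow(ex)))
      inside <- inside | (prof$pos >= ex$start[j] & prof$pos <= ex$end[j])
    mean_of <- function(ctx) {
      v <- prof$level_mean[inside & prof$context == ctx]
      if (length(v)) mean(v) else NA_real_
    }
    cg <- mean_of("CG"); chg <- mean_of("CHG"); chh <- mean_of("CHH")
    want <- if (anyNA(c(cg, chg, chh))) "other"
      else if (cg >= 20 && chg < 20 && chh < 20) "gbM"
      else if (cg >= 5 && chg >= 5 && chh >= 5) "teM"
      else "other"
    row <- cls[cls$gene_id == gid, ]
    expect_identical(row$class, want)
    if (!is.na(cg)) expect_equal(row$CG, cg)
  }
  # forced labels are recovered
  cmp <- merge(cls, ann$genes[, c("gene_id", "class"), with = FALSE],
               by = "gene_id", suffixes = c("", "_truth"))
  forced <- cmp[cmp$class_truth %in% c("gbM", "teM"), ]
  expect_identical(forced$class, forced$class_truth)
})

test_that("region annotation follows the feature priority", {
  genes <- data.table::data.table(gene_id = "g", chrom = "p",
                                  start = 5000L, end = 9000L, strand = "+")
  exons <- data.table::data.table(gene_id = "g",
                                  start = c(5000L, 8000L),
                                  end = c(6000L, 9000L))
  repeats <- data.table::data.table(repeat_id = c("r1", "r2"),
                                    start = c(5500L, 6500L),
                                    end = c(5600L, 6600L))
  regions <- data.table::data.table(
    dmr_id = paste0("d", 1:5),
    start = c(5550L, 6500L, 3000L, 1L, 20000L),
    end = c(5560L, 6550L, 3100L, 100L, 20100L))
  ann <- annotate_regions(regions, genes, exons, repeats)
  # exon + repeat -> exon, TE flag kept
  expect_identical(ann$feature,
                   c("exon", "intron", "promoter", "intergenic",
                     "intergenic"))
  expect_identical(ann$te_overlap, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # invariance to annotation row order
  ann2 <- annotate_regions(regions, genes, exons[c(2, 1), ],
                           repeats[c(2, 1), ])
  expect_identical(ann$feature, ann2$feature)
})

test_that("SV proximity respects the length and distance rules", {
  dmrs <- data.table::data.table(dmr_id = c("d1", "d2", "d3"),
                                 start = c(1000L, 5000L, 9000L),
                                 end = c(1200L, 5200L, 9200L),
                                 te_overlap = c(TRUE, FALSE, FALSE))
  mk_var <- function(pos, len, refseq) data.table::data.table(
    posA = pos, posB = pos, alleleA = "",
    alleleB = refseq, type = "INDEL", length = len, sv = len >= 50)
  v <- rbind(mk_var(1100L, 60L, paste(rep("A", 60), collapse = "")),
             mk_var(4000L, 49L, paste(rep("A", 49), collapse = "")),
             mk_var(6200L, 80L, paste(rep("A", 80), collapse = "")),  # 1000 bp
             mk_var(10201L, 80L, paste(rep("A", 80), collapse = ""))) # 1001 bp
  sp <- sv_proximity(dmrs, v, maxgap = 1000)
  expect_identical(sp$pairs$class[sp$pairs$dmr_id == "d1"], "within")
  # the 49 bp indel is not an SV; it never pairs
  expect_false(any(sp$pairs$sv_length == 49L))
  # 1001 bp away is excluded, 1000 bp is proximal
  expect_identical(sp$pairs$dmr_id[sp$pairs$class == "proximal"], "d2")
  expect_false("d3" %in% sp$pairs$dmr_id)
  expect_true(!is.null(sp$test))
})

test_that("allelic pairing is reciprocal with a 50% overlap rule", {
  sim <- trio_fixture("genes")
  truth <- sim$truth
  g <- chop_nodes(sim$graph, 200)
  ga <- lift_annotations(truth, sim$annotations, "CF1")$genes
  gb <- lift_annotations(truth, sim$annotations, "CF2")$genes
  ap <- allelic_pairs(g, ga, gb, "CF1", "CF2")
  # homologous haplotypes pair every gene with its own copy
  expect_identical(nrow(ap$pairs), nrow(ga))
  expect_identical(ap$pairs$gene_a, ap$pairs$gene_b)
  expect_identical(nrow(ap$unpaired), 0L)

  # a 40% projected overlap is below the threshold
  seqs <- c(s1 = paste(rep("A", 1000), collapse = ""),
            s2 = paste(rep("C", 1000), collapse = ""))
  gg <- chop_nodes(sequence_graph(seqs, paths = list(
    h1 = c("s1+", "s2+"), h2 = c("s1+", "s2+"))), 200)
  ga2 <- data.table::data.table(gene_id = "x", chrom = "h1", start = 1L,
                                end = 1000L, strand = "+")
  gb2 <- data.table::data.table(gene_id = "y", chrom = "h2", start = 601L,
                                end = 1600L, strand = "+")
  ap2 <- allelic_pairs(gg, ga2, gb2, "h1", "h2")
  expect_identical(nrow(ap2$pairs), 0L)
  expect_identical(sort(unique(ap2$unpaired$category)), "no_overlap")

  # a gene inside a haplotype-private insertion cannot project
  seqs3 <- c(a = paste(rep("A", 500), collapse = ""),
             ins = paste(rep("G", 400), collapse = ""),
             b = paste(rep("T", 500), collapse = ""))
  g3 <- chop_nodes(sequence_graph(seqs3, paths = list(
    h1 = c("a+", "ins+", "b+"), h2 = c("a+", "b+"))), 200)
  ga3 <- data.table::data.table(gene_id = "z", chrom = "h1", start = 551L,
                                end = 850L, strand = "+")
  gb3 <- data.table::data.table(gene_id = "w", chrom = "h2", start = 1L,
                                end = 300L, strand = "+")
  ap3 <- allelic_pairs(g3, ga3, gb3, "h1", "h2")
  expect_true("unprojectable" %in%
                ap3$unpaired$category[ap3$unpaired$gene_id == "z"])
})

test_that("inherited sets intersect ids with matching signs", {
  a <- data.table::data.table(id = c("g1", "g2", "g3"),
                              sign = c("up", "up", "down"))
  b <- data.table::data.table(id = c("g1", "g2", "g4"),
                              sign = c("up", "down", "up"))
  out <- inherited_sets(a, b)
  expect_identical(out$id, "g1")
  expect_identical(out$sign, "up")
  expect_warning(
    empty <- inherited_sets(a, data.table::data.table(id = "zz",
                                                      sign = "up")),
    "no identifiers")
  expect_identical(nrow(empty), 0L)
})

test_that("metagene profiles from the trio show gene-body CG methylation", {
  sim <- trio_fixture("genes")
  ann <- lift_annotations(sim$truth, sim$annotations, "SB1")
  forced <- ann$genes[ann$genes$class == "gbM", ]
  mp <- metagene_profile(forced, sim$profiles[["SB1"]])
  body_cg <- mp[mp$segment == "body" & mp$context == "CG", ]
  body_chg <- mp[mp$segment == "body" & mp$context == "CHG", ]
  expect_gt(mean(body_cg$level), 60)
  expect_lt(mean(body_chg$level), 30)
})
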