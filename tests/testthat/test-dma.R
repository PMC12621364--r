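test_that("reference tiling follows the window, step and terminal rules", {
  g <- sequence_graph(c(a = paste(rep("A", 1000), collapse = "")),
                      paths = list(ref = c("a+")))
  w <- make_reference_windows(g, "ref", win = 200, step = 200)
  expect_identical(nrow(w), 5L)
  expect_equal(w$end - w$start, rep(200, 5))

  g2 <- sequence_graph(c(a = paste(rep("A", 1030), collapse = "")),
                       paths = list(ref = c("a+")))
  w2 <- make_reference_windows(g2, "ref", win = 200, step = 200)
  expect_identical(nrow(w2), 5L)     # 30 bp remainder dropped (< 150)

  w3 <- make_reference_windows(g, "ref", win = 200, step = 100)
  expect_identical(nrow(w3), 9L)
})

test_that("the window test matches its closed-form expectations", {
  r0 <- test_window(c(5, 5, 5), c(10, 10, 10), c(5, 5, 5), c(10, 10, 10))
  expect_equal(r0$meth_diff, 0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- test_window(c(30, 30, 30), c(30, 30, 30), c(0, 0, 0), c(30, 30, 30))
  expect_equal(r1$meth_diff, 100)
  expect_equal(r1$phi, 0)           # no residual variation, no correction
  expect_lt(r1$p_value, 1e-10)

  expect_error(test_window(c(1, 1), c(2, 2), c(0, 0), c(0, 0)),
               "zero total coverage")
  expect_error(test_window(1, 2, c(0, 0), c(2, 2)), "two samples")
})

test_that("the window test equals the brute-force likelihood oracle", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(2:4, 1)
    n_a <- rpois(k, 40) + 1L
    n_b <- rpois(k, 40) + 1L
    m_a <- rbinom(k, n_a, runif(1))
    m_b <- rbinom(k, n_b, runif(1))
    got <- test_window(m_a, n_a, m_b, n_b)
    want <- oracle_test_window(m_a, n_a, m_b, n_b)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$phi, want$phi, tolerance = 1e-10)
    # antisymmetry: swapping groups flips the differential only
    rev <- test_window(m_b, n_b, m_a, n_a)
    expect_equal(rev$meth_diff, -got$meth_diff)
    expect_equal(rev$p_value, got$p_value)
  }
})

test_that("the deviance agrees with an independent logistic regression fit", {
  set.seed(12)
  for (i in 1:20) {
    n <- rep(30L, 6)
    m <- rbinom(6, n, rep(runif(2, 0.1, 0.9), each = 3))
    grp <- factor(rep(c("A", "B"), each = 3))
    fit <- stats::glm(cbind(m, n - m) ~ grp, family = stats::binomial)
    D_glm <- fit$null.deviance - fit$deviance
    phi_glm <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
    got <- test_window(m[1:3], n[1:3], m[4:6], n[4:6])
    expect_equal(got$statistic, D_glm, tolerance = 1e-6)
    expect_equal(got$phi, phi_glm, tolerance = 1e-6)
  }
})

test_that("window projection applies the length and cytosine filters", {
  sim <- trio_fixture("basic")
  g <- sim$chopped
  w <- make_reference_windows(g, c("CSCF", "CSSB"))
  cw <- project_windows(g, w, panmeth:::TRIO_HAPLOTYPES, sim$profiles, "CG")
  expect_gt(nrow(cw$windows), 100L)
  lens <- cw$intervals$end - cw$intervals$start
  expect_true(all(lens[!is.na(lens)] >= 150 & lens[!is.na(lens)] <= 250))
  expect_true(all(cw$intervals$n_cyt[!is.na(cw$intervals$n_cyt)] >= 3))

  # a window across a large target-private insertion must be dropped
  ins <- sim$truth$variants[sim$truth$variants$type == "INS" &
                              sim$truth$variants$length >= 50, ]
  if (nrow(ins) > 0L) {
    expect_gt(cw$dropped["length"] + cw$dropped["unprojected"], 0L)
  }

  # starving a haplotype of cytosines drops all its windows
  prof2 <- sim$profiles
  prof2[["SB1"]] <- prof2[["SB1"]][prof2[["SB1"]]$context != "CG", ]
  cw2 <- project_windows(g, w, panmeth:::TRIO_HAPLOTYPES, prof2, "CG")
  expect_identical(nrow(cw2$windows), 0L)
})

test_that("per-clone counts aggregate by summation over intervals", {
  # one clone with sites 8/10, 2/10, 5/10 inside the window: m=15, n=30
  prof <- structure(data.table::data.table(
    chrom = "ref", pos = c(10L, 20L, 30L), strand = "+",
    context = "CG", trinucleotide = "CGA",
    meth_1 = c(8L, 2L, 5L), cov_1 = c(10L, 10L, 10L),
    level_1 = c(80, 20, 50),
    meth_2 = c(0L, 0L, 0L), cov_2 = c(10L, 10L, 10L),
    level_2 = c(0, 0, 0)), class = c("united_profile", "data.table",
                                     "data.frame"))
  cw <- structure(list(
    windows = data.table::data.table(window_id = "w1", ref_path = "ref",
                                     start = 0L, end = 100L),
    intervals = data.table::data.table(window_id = "w1", path = "ref",
                                       start = 0L, end = 100L,
                                       is_ref = TRUE, n_cyt = 3L),
    context = "CG"), class = "comparable_windows")
  agg <- aggregate_window_counts(cw, list(ref = prof), "@ref")
  expect_identical(agg$M[1, ], c(15L, 0L))
  expect_identical(agg$N[1, ], c(30L, 30L))

  # counts over a cultivar's two haplotypes are summed
  sim <- trio_fixture("basic")
  w <- make_reference_windows(sim$chopped, "CSCF")
  cwx <- project_windows(sim$chopped, w, panmeth:::TRIO_HAPLOTYPES,
                         sim$profiles, "CG")
  a1 <- aggregate_window_counts(cwx, sim$profiles, "CF1")
  a2 <- aggregate_window_counts(cwx, sim$profiles, "CF2")
  ab <- aggregate_window_counts(cwx, sim$profiles, c("CF1", "CF2"))
  expect_identical(ab$M, a1$M + a2$M)
  expect_identical(ab$N, a1$N + a2$N)
})

test_that("calls honour q and context-specific differential thresholds", {
  res <- data.table::data.table(
    window_id = paste0("w", 1:4),
    comparison = "CFvSB",
    context = c("CG", "CHH", "CG", "CHH"),
    meth_diff = c(15, -12, 40, 5),
    p_value = c(1e-8, 1e-8, 1e-8, 1))
  called <- adjust_and_call(res, dma_thresholds())
  expect_identical(called$call, c("ns", "hypo", "hyper", "ns"))

  allns <- adjust_and_call(data.table::data.table(
    window_id = "w", comparison = "x", context = "CG",
    meth_diff = 50, p_value = 1))
  expect_identical(allns$call, "ns")
})

test_that("inherited sets intersect comparisons with matching signs", {
  mk <- function(cmp, ids, calls) data.table::data.table(
    window_id = ids, comparison = cmp, context = "CG", call = calls)
  calls <- rbind(
    mk("CSvSB", c("w1", "w2", "w3"), c("hyper", "hyper", "ns")),
    mk("CFvSB", c("w1", "w2", "w3"), c("hyper", "hypo", "hyper")),
    mk("CSvCF", c("w1", "w2", "w3"), c("ns", "ns", "hypo")),
    mk("SBvCF", c("w1", "w2", "w3"), c("ns", "hypo", "hypo")))
  sets <- inherited_dmr_sets(calls)
  expect_identical(sets$iCF$window_id, "w1")   # same sign in both
  expect_identical(sets$iCF$call, "hyper")
  expect_identical(sets$iSB$window_id, "w3")
  expect_error(inherited_dmr_sets(calls[calls$comparison != "SBvCF", ]),
               "missing comparison")
})

test_that("intra-cultivar concordance follows the minimum-delta rule", {
  parent <- data.table::data.table(
    window_id = c("w1", "w2"), comparison = "CF1vCF2", context = "CG",
    level_A = c(82, 90), level_B = c(5, 5), meth_diff = c(77, 85),
    p_value = 1e-9, q_value = 1e-9, call = "hyper")
  cs <- data.table::data.table(window_id = c("w1", "w2"), level = c(80, 50))
  out <- intra_cultivar_concordance(parent, cs)
  expect_identical(out$records$concordant, c(TRUE, FALSE))
  expect_equal(out$fraction, 0.5)
  # a DMR without a progeny level is excluded, not counted
  cs2 <- cs[1, ]
  out2 <- intra_cultivar_concordance(parent, cs2)
  expect_identical(out2$n_excluded, 1L)
  expect_equal(out2$fraction, 1)
})

test_that("a parameter sweep is consistent and monotone", {
  sim <- trio_fixture("planted")
  g <- sim$chopped
  prof <- sim$profiles
  grid <- data.frame(win = c(200, 200, 200), step = 200,
                     min_cytosines = c(3, 3, 8), diff_min = c(20, 5, 20))
  sw <- sweep_parameters(g, prof, c("CSCF", "CSSB"),
                         panmeth:::TRIO_HAPLOTYPES, c("CF1", "CF2"),
                         c("SB1", "SB2"), "CG", grid)
  # single-cell consistency with a direct pipeline run
  w <- make_reference_windows(g, c("CSCF", "CSSB"))
  cw <- project_windows(g, w, panmeth:::TRIO_HAPLOTYPES, prof, "CG")
  direct <- adjust_and_call(
    dma_compare(cw, prof, c("CF1", "CF2"), c("SB1", "SB2")))
  expect_identical(sw$n_windows[1], nrow(cw$windows))
  expect_identical(sw$n_dmrs[1], sum(direct$call != "ns"))
  # a laxer differential can only add DMRs
  expect_gte(sw$n_dmrs[2], sw$n_dmrs[1])
  # more required cytosines can only drop windows
  expect_lte(sw$n_windows[3], sw$n_windows[1])
})

test_that("duplicate homologous windows collapse across tilings", {
  # identical haplotypes: the two reference tilings coincide exactly
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  g <- chop_nodes(sequence_graph(c(n = s), paths = list(
    CSCF = c("n+"), CSSB = c("n+"))), 200)
  prof1 <- structure(data.table::data.table(
    chrom = "CSCF", pos = seq(5L, 995L, by = 10L), strand = "+",
    context = "CG", trinucleotide = "CNN", meth_1 = 5L, cov_1 = 10L,
    level_1 = 50, level_mean = 50),
    class = c("united_profile", "data.table", "data.frame"))
  prof2 <- data.table::copy(prof1)
  prof2$chrom <- "CSSB"
  profs <- list(CSCF = prof1, CSSB = prof2)
  w <- make_reference_windows(g, c("CSCF", "CSSB"))
  cw <- project_windows(g, w, c("CSCF", "CSSB"), profs, "CG")
  dd <- dedup_windows(cw)
  expect_equal(nrow(dd$windows), nrow(cw$windows) / 2)
  expect_true(all(dd$windows$ref_path == "CSCF"))
})

test_that("DMR BED output carries coordinates, ids and differentials", {
  calls <- data.table::data.table(
    window_id = c("CSCF:0-200", "CSCF:200-400"), ref_path = "CSCF",
    comparison = "CFvSB", context = "CG", meth_diff = c(45.2, -3),
    q_value = c(1e-5, 0.5), call = c("hyper", "ns"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmrs_bed(calls, f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_identical(strsplit(lines, "\t")[[1]][1:5],
                   c("CSCF", "0", "200", "CSCF:0-200", "45.2"))
})

test_that("planted parental differentials are recovered and inherited", {
  sim <- trio_fixture("planted")
  g <- sim$chopped
  prof <- sim$profiles
  w <- make_reference_windows(g, c("CSCF", "CSSB"))
  cw <- project_windows(g, w, panmeth:::TRIO_HAPLOTYPES, prof, "CG")
  calls <- trio_dma(cw, prof)
  truth_ids <- truth_differential_windows(sim, cw, donor = "CF")
  expect_gt(length(truth_ids), 10L)
  # CF-vs-SB recovers the planted 78-point differential
  cfvsb <- calls[calls$comparison == "CFvSB" &
                   calls$window_id %in% truth_ids, ]
  expect_gte(mean(cfvsb$call == "hyper"), 0.9)
  expect_lt(abs(mean(cfvsb$meth_diff) - 78), 8)
  # windows land in the inherited set matching their anchor haplotype
  sets <- inherited_dmr_sets(calls)
  on_cf <- grepl("^CSCF", truth_ids)
  expect_gte(mean(truth_ids[on_cf] %in% sets$iCF$window_id), 0.8)
  expect_gte(mean(truth_ids[!on_cf] %in% sets$iSB$window_id), 0.8)
})
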