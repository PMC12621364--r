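# Shared fixtures: each named study design is generated once per test
# run and cached, so test files can reuse the heavier simulations.

.fixtures <- new.env(parent = emptyenv())

trio_fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  fx <- switch(
    name,
    # small all-purpose trio with default settings
    basic = {
      cfg <- trio_config(chrom_length = 30000, seed = 101, n_genes = 5,
                         sv_count = 2)
      sim <- simulate_trio(cfg)
      sim$chopped <- chop_nodes(sim$graph, 200)
      sim$profiles <- build_hap_profiles(sim$methylomes$tables, 10)
      sim
    },
    # planted CG differential between the parents, inherited by CS
    planted = {
      cfg <- trio_config(chrom_length = 60000, seed = 202,
                         planted_dmr_fraction = 0.1, n_genes = 5)
      sim <- simulate_trio(cfg, annotations = FALSE)
      sim$chopped <- chop_nodes(sim$graph, 200)
      sim$profiles <- build_hap_profiles(sim$methylomes$tables, 10)
      sim
    },
    # forced gbM/teM genes over a quiet background
    genes = {
      cfg <- trio_config(chrom_length = 50000, seed = 303, n_genes = 8,
                         n_gbm = 3, n_tem = 3,
                         context_meth_prob = c(CG = 0.3, CHG = 0.1,
                                               CHH = 0.03))
      sim <- simulate_trio(cfg)
      sim$profiles <- build_hap_profiles(sim$methylomes$tables, 10)
      sim
    },
    # reference-bias showcase: methylated regions with planted C>T SNPs
    bias = {
      cfg <- trio_config(chrom_length = 60000, seed = 404,
                         bias_region_fraction = 0.15,
                         bias_region_size = 1000, n_genes = 5)
      sim <- simulate_trio(cfg, annotations = FALSE)
      sim$chopped <- chop_nodes(sim$graph, 200)
      sim$profiles <- build_hap_profiles(sim$methylomes$tables, 10)
      sim
    },
    stop("unknown fixture: ", name))
  .fixtures[[name]] <- fx
  fx
}

# brute-force evaluation of the two-group binomial likelihood-ratio
# test with Pearson overdispersion, written against the stated formulas
# with scalar loops and dbinom: the independent oracle for test_window
oracle_test_window <- function(m_a, n_a, m_b, n_b) {
  pa <- sum(m_a) / sum(n_a)
  pb <- sum(m_b) / sum(n_b)
  p0 <- (sum(m_a) + sum(m_b)) / (sum(n_a) + sum(n_b))
  ll <- function(m, n, p) {
    tot <- 0
    for (i in seq_along(m)) {
      if (m[i] > 0) tot <- tot + m[i] * log(p)
      if (n[i] - m[i] > 0) tot <- tot + (n[i] - m[i]) * log(1 - p)
    }
    tot
  }
  D <- 2 * (ll(m_a, n_a, pa) + ll(m_b, n_b, pb) -
              ll(m_a, n_a, p0) - ll(m_b, n_b, p0))
  D <- max(D, 0)
  pear <- 0
  for (i in seq_along(m_a)) {
    den <- n_a[i] * pa * (1 - pa)
    if (den > 0) pear <- pear + (m_a[i] - n_a[i] * pa)^2 / den
  }
  for (i in seq_along(m_b)) {
    den <- n_b[i] * pb * (1 - pb)
    if (den > 0) pear <- pear + (m_b[i] - n_b[i] * pb)^2 / den
  }
  K <- length(m_a) + length(m_b)
  phi <- if (K > 2) pear / (K - 2) else 1
  Dc <- if (phi > 1) D / phi else D
  list(meth_diff = 100 * (pa - pb),
       p_value = stats::pchisq(Dc, df = 1, lower.tail = FALSE),
       statistic = D, phi = phi)
}

# Windows whose truth states realise the planted differential: the
# donor parent's sites are (almost) all methylated inside the window
# while the other parent's are (almost) all unmethylated.
truth_differential_windows <- function(sim, cw, donor = "CF",
                                       ctx = "CG",
                                       hi = 0.9, lo = 0.1) {
  ss <- sim$methylomes$site_states
  donor_haps <- if (donor == "CF") c("CF1", "CF2") else c("SB1", "SB2")
  other_haps <- setdiff(c("CF1", "CF2", "SB1", "SB2"), donor_haps)
  mean_state <- function(haps) {
    iv <- cw$intervals[sub("#.*$", "", cw$intervals$path) %in% haps &
                         !is.na(cw$intervals$start), ]
    out <- rep(NA_real_, nrow(cw$windows))
    agg <- list()
    for (pn in unique(iv$path)) {
      sites <- ss[ss$path == pn & ss$context == ctx, ]
      pi <- iv[iv$path == pn, ]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(pi$start + 1L, pi$end),
        IRanges::IRanges(sites$pos, width = 1L))
      agg[[pn]] <- data.table::data.table(
        window_id = pi$window_id[S4Vectors::queryHits(hits)],
        state = sites$state[S4Vectors::subjectHits(hits)])
    }
    agg <- data.table::rbindlist(agg)
    res <- agg[, list(m = mean(state)), by = "window_id"]
    out[match(res$window_id, cw$windows$window_id)] <- res$m
    out
  }
  d <- mean_state(donor_haps)
  o <- mean_state(other_haps)
  cw$windows$window_id[!is.na(d) & !is.na(o) & d >= hi & o <= lo]
}

# map window reference intervals to ancestral coordinates via the truth
window_anc_intervals <- function(truth, windows) {
  anc_s <- integer(nrow(windows))
  anc_e <- integer(nrow(windows))
  for (rp in unique(windows$ref_path)) {
    amap <- truth$anc_maps[[rp]]
    i <- windows$ref_path == rp
    anc_s[i] <- amap[windows$start[i] + 1L]
    anc_e[i] <- amap[windows$end[i]]
  }
  data.table::data.table(window_id = windows$window_id,
                         anc_start = anc_s, anc_end = anc_e)
}
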