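test_that("EHH matches direct pair-counting on hand fixtures", {
  # 8 haplotypes; core at site 2; derived carriers split 2/2 at the flank
  m <- rbind(c(0, 0, 1, 1, 0, 0, 1, 1),   # site 1 (left flank)
             c(1, 1, 1, 1, 0, 0, 0, 0),   # site 2 (core)
             c(0, 0, 0, 0, 0, 1, 0, 1))   # site 3 (right flank)
  hm <- hap_matrix(m, positions = c(100, 200, 300))
  left <- ehh(hm, 2, "derived", "left", cutoff = 0)
  # 4 carriers split 2/2: EHH = (1 + 1) / 6
  expect_equal(left$ehh, c(1, 1 / 3))
  # all carriers identical over the window: EHH stays 1
  # (derived carriers are constant 0 at the right flank)
  right_der <- ehh(hm, 2, "derived", "right", cutoff = 0)
  expect_equal(right_der$ehh, c(1, 1))
  # 2 carriers that differ at the first site: EHH drops to 0
  m2 <- rbind(c(1, 1, 0, 0), c(0, 1, 0, 0))
  hm2 <- hap_matrix(m2, positions = c(10, 20))
  curve <- ehh(hm2, 1, "derived", "right", cutoff = 0.05)
  expect_equal(curve$ehh, c(1, 0))
  # fewer than 2 carriers: NULL
  expect_null(ehh(hm2, 2, "derived", "left"))
})

test_that("EHH is non-increasing away from the core", {
  hm <- random_hap_matrix(60, 16, seed = 3)
  for (core in c(10, 30, 50)) for (dir in c("left", "right")) {
    cv <- ehh(hm, core, "derived", dir, cutoff = 0)
    if (!is.null(cv)) expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("iHH integration follows trapezoid, cutoff and gap rules", {
  map <- uniform_map(1e6, 1e-8) # 1 cM per Mb
  # EHH == 1 over 1 cM with no cutoff crossing and require_decay off: area 1
  curve <- data.frame(site = 1:2, pos = c(0, 1e6), ehh = c(1, 1))
  expect_equal(ihh(curve, map, require_decay = FALSE, max_gap = Inf,
                   scale_gap = Inf), 1)
  # hand trapezoid on a 4-point curve ending exactly at the cutoff
  curve2 <- data.frame(site = 1:4, pos = c(0, 1e4, 2e4, 3e4),
                       ehh = c(1, 0.6, 0.2, 0.04))
  want <- (1 + 0.6) / 2 * 0.01 + (0.6 + 0.2) / 2 * 0.01 +
    (0.2 + 0.05) / 2 * 0.01 * (0.2 - 0.05) / (0.2 - 0.04)
  expect_equal(ihh(curve2, map), want, tolerance = 1e-12)
  # a 40-kb gap with scale_gap 20 kb halves that trapezoid's contribution
  curve3 <- data.frame(site = 1:3, pos = c(0, 4e4, 5e4), ehh = c(1, 0.5, 0.01))
  got <- ihh(curve3, map)
  want3 <- (1 + 0.5) / 2 * 0.04 * 0.5 +
    (0.5 + 0.05) / 2 * 0.01 * (0.5 - 0.05) / (0.5 - 0.01)
  expect_equal(got, want3, tolerance = 1e-12)
  # gaps beyond max_gap censor with a reason
  curve4 <- data.frame(site = 1:2, pos = c(0, 3e5), ehh = c(1, 0.01))
  expect_true(is.na(ihh(curve4, map)))
  expect_equal(attr(ihh(curve4, map), "reason"), "max_gap")
  # non-decaying curves censor unless allowed
  expect_true(is.na(ihh(curve, map)))
  expect_equal(attr(ihh(curve, map), "reason"), "end_of_data")
})

test_that("iHS scores obey symmetry, polarity antisymmetry and map-rescale invariance", {
  hm <- random_hap_matrix(50, 12, length_bp = 3e5, seed = 8)
  map <- uniform_map(3e5, 1e-7)
  tab <- ihs_scores(hm, map, require_decay = FALSE, max_gap = Inf)
  expect_true(any(!is.na(tab$ihs_unstd)))
  # swapping polarity negates the unstandardized score
  flipped <- hap_matrix(1L - unclass(hm), attr(hm, "positions"))
  tab_f <- ihs_scores(flipped, map, require_decay = FALSE, max_gap = Inf)
  expect_equal(tab_f$ihs_unstd, -tab$ihs_unstd, tolerance = 1e-12)
  # uniform map rescaling multiplies iHH but cancels in the log ratio
  map10 <- uniform_map(3e5, 1e-6)
  tab10 <- ihs_scores(hm, map10, require_decay = FALSE, max_gap = Inf)
  ok <- !is.na(tab$ihs_unstd)
  expect_equal(tab10$ihh_derived[ok], 10 * tab$ihh_derived[ok], tolerance = 1e-9)
  expect_equal(tab10$ihs_unstd[ok], tab$ihs_unstd[ok], tolerance = 1e-12)
  # duplicating every haplotype changes EHH only through the C(n,2) counts,
  # checked against direct counting via the brute-force oracle
  dup <- hap_matrix(cbind(unclass(hm), unclass(hm)), attr(hm, "positions"))
  tab_d <- ihs_scores(dup, map, require_decay = FALSE, max_gap = Inf)
  bf_d <- bf_ihs_table(dup, map, require_decay = FALSE, max_gap = Inf)
  expect_equal(tab_d$ihs_unstd, bf_d$ihs_unstd, tolerance = 1e-9)
})

test_that("full scans equal the string-enumeration brute force on random fixtures", {
  set.seed(77)
  for (rep_i in 1:12) {
    n_hap <- sample(6:12, 1)
    hm <- random_hap_matrix(50, n_hap, length_bp = 4e5, seed = 700 + rep_i)
    rate <- runif(1, 5e-8, 5e-7)
    map <- uniform_map(4e5, rate)
    for (rd in c(TRUE, FALSE)) {
      got <- ihs_scores(hm, map, require_decay = rd)
      want <- bf_ihs_table(hm, map, require_decay = rd)
      expect_equal(got$pos, want$pos)
      expect_equal(got$ihs_unstd, want$ihs_unstd, tolerance = 1e-9)
    }
  }
})

test_that("standardization removes bin means and matches hand z-scores", {
  tab <- data.frame(site = 1:8, pos = 1:8 * 100,
                    derived_freq = c(0.1, 0.12, 0.15, 0.1, 0.8, 0.85, 0.9, 0.82),
                    ihh_derived = 1, ihh_ancestral = 1,
                    ihs_unstd = c(1, 2, 3, 2, -1, -3, -5, -7),
                    flag = "ok")
  class(tab) <- c("ihs_table", "data.frame")
  out <- standardize_ihs(tab, n_freq_bins = 2)
  lo <- tab$ihs_unstd[1:4]; hi <- tab$ihs_unstd[5:8]
  expect_equal(out$ihs_std, c((lo - mean(lo)) / sd(lo), (hi - mean(hi)) / sd(hi)))
  # constant shift within a bin is removed exactly
  tab2 <- tab; tab2$ihs_unstd <- tab$ihs_unstd + 5
  expect_equal(standardize_ihs(tab2, 2)$ihs_std, out$ihs_std)
  # under-filled bins merge with their neighbour instead of failing
  tab3 <- tab; tab3$derived_freq <- c(0.02, rep(0.5, 7))
  expect_silent(standardize_ihs(tab3, 20))
})

test_that("top hits honour the quantile threshold and tie rules", {
  set.seed(2)
  tab <- data.frame(site = 1:200, pos = 1:200, derived_freq = 0.5,
                    ihh_derived = 1, ihh_ancestral = 1,
                    ihs_unstd = 0, ihs_std = c(rnorm(198), 9, -9), flag = "ok")
  class(tab) <- c("ihs_table", "data.frame")
  top <- top_hits(tab, 0.01)
  expect_gte(nrow(top), 2L)
  expect_true(all(c(199, 200) %in% top$site))
  expect_equal(nrow(top_hits(tab, 1)), 200L)
  # total tie: everyone passes
  tie <- tab; tie$ihs_std <- 1
  expect_equal(nrow(top_hits(tie, 0.01)), 200L)
  expect_error(top_hits(tab[0, ], 0.01), "empty table")
  expect_error(top_hits(tab, 0), "fraction")
})

test_that("gene annotation and run comparison behave on toy inputs", {
  genes <- data.frame(chrom = "1", start = c(0, 1000, 5000, 9000),
                      end = c(500, 2000, 6000, 9500),
                      symbol = c("G1", "G2", "G3", "G4"))
  expect_equal(annotate_genes(1500, genes), "G2")
  expect_equal(annotate_genes(800, genes), character(0))
  expect_equal(annotate_genes(800, genes, flank = 400), c("G1", "G2"))
  # 5 sites vs the 4-gene list equals direct containment
  sites <- c(100, 800, 1999, 5500, 9200)
  want <- sort(unique(unlist(lapply(seq_len(nrow(genes)), function(i) {
    if (any(sites >= genes$start[i] & sites <= genes$end[i])) genes$symbol[i]
  }))))
  expect_equal(annotate_genes(sites, genes), want)
  f <- withr::local_tempfile()
  writeLines(c("1 0 500 G1", "1 oops 600 G2"), f)
  expect_error(read_gene_ranges(f), "line 2")

  hm <- random_hap_matrix(60, 14, length_bp = 1e4, seed = 12)
  map <- uniform_map(1e4, 1e-5)
  tile <- synthetic_gene_ranges(1e4, gene_width_bp = 2000, spacing_bp = 2000)
  ta <- standardize_ihs(ihs_scores(hm, map, require_decay = FALSE, max_gap = Inf))
  rep_same <- compare_runs(ta, ta, tile, fraction = 0.1)
  expect_equal(rep_same$pearson_r, 1)
  expect_equal(rep_same$overlap_fraction, 1)
  expect_length(rep_same$unique_a, 0L)
  # negated scores: r = -1 but |iHS| hit sets identical
  tb <- ta; tb$ihs_std <- -ta$ihs_std; tb$ihs_unstd <- -ta$ihs_unstd
  rep_neg <- compare_runs(ta, tb, tile, fraction = 0.1)
  expect_equal(rep_neg$pearson_r, -1)
  expect_equal(rep_neg$overlap_fraction, 1)
})
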