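test_that("map construction, cumulative cM, and interpolation are exact", {
  m <- recomb_map("1", c(0, 5e5), c(5e5, 1e6), c(1e-8, 3e-8))
  expect_equal(map_total_cm(m), 0.5 + 1.5)
  expect_equal(interp_cm(m, c(0, 5e5, 1e6)), c(0, 0.5, 2))
  # midpoint of an interval is the mean of its endpoint values
  expect_equal(interp_cm(m, 2.5e5), 0.25)
  expect_equal(interp_cm(m, 7.5e5), 0.5 + 0.75)
  expect_error(interp_cm(m, 2e6), "outside map span")
  expect_equal(interp_cm(m, 2e6, clamp = TRUE), 2)
  # hand-interpolated values on a 2-interval toy map
  expect_equal(interp_cm(m, c(1e5, 6e5, 9e5)), c(0.1, 0.8, 1.7))
})

test_that("hapmap and interval dialects round-trip and cross-check", {
  m <- recomb_map("7", c(0, 2e5, 6e5, 8e5), c(2e5, 6e5, 8e5, 1e6),
                  c(1e-8, 5e-8, 0, 2e-8))
  for (dialect in c("hapmap", "interval")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_map(m, f, dialect)
    m2 <- read_map(f, dialect)
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
    expect_equal(m2$rate, m$rate, tolerance = 1e-12)
    expect_equal(map_total_cm(m2), map_total_cm(m), tolerance = 1e-9)
  }
})

test_that("hapmap reader validates positions, rates and the Map column", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Position(bp) Rate(cM/Mb) Map(cM)",
               "0 1.0 0", "1000000 2.0 1.0", "500000 1.0 1.5"), f)
  expect_error(read_map(f, "hapmap"), "not strictly increasing")
  writeLines(c("Position(bp) Rate(cM/Mb) Map(cM)",
               "0 1.0 0", "1000000 2.0 5.0", "2000000 0 7.0"), f)
  expect_error(read_map(f, "hapmap"), "Map column inconsistent")
  # 4-line fixture: cumulative map equals the hand-summed rates
  writeLines(c("Position(bp) Rate(cM/Mb) Map(cM)",
               "0 1.0 0", "1000000 2.0 1.0", "1500000 4.0 2.0", "2000000 0 4.0"), f)
  m <- read_map(f, "hapmap")
  expect_equal(c(m$cm_start, map_total_cm(m)), c(0, 1, 2, 4))
})

test_that("binning conserves total cM and matches the closed form", {
  spec <- genetic_map_spec(5e6, background_rate = 1e-8, hotspot_rate = 3,
                           hotspot_width_bp = 2000, intensity_fold = 50)
  m <- synth_map(spec, seed = 9)
  b <- bin_rates(m, 2000)
  expect_lt(abs(sum(b$value * 2000 / 1e6, na.rm = TRUE) - map_total_cm(m)), 1e-9)
  # uniform map: every bin equals the uniform rate in cM/Mb
  u <- uniform_map(1e6, 2.5e-8)
  bu <- bin_rates(u, 2000)
  expect_true(all(abs(bu$value - 2.5) < 1e-9))
  # one hotspot fully inside a bin: length-weighted closed form
  hot <- recomb_map("1", c(0, 10500, 11000, 2e4), c(10500, 11000, 2e4, 4e4),
                    c(1e-8, 2e-7, 1e-8, 1e-8))
  bh <- bin_rates(hot, 2000)
  w <- 2000; h <- 500
  expected <- (1e-8 * (w - h) + 2e-7 * h) * 100 * 1e6 / w
  expect_equal(bh$value[bh$start == 10000], expected, tolerance = 1e-12)
  # binning at w then aggregating to 2w equals direct binning at 2w
  b1 <- bin_rates(m, 1000, partial = "scale")
  b2 <- bin_rates(m, 2000, partial = "scale")
  agg <- tapply(b1$value * 1000, b1$bin %/% 2L, sum) / 2000
  expect_equal(as.numeric(agg), b2$value, tolerance = 1e-9)
})

test_that("spearman matrix has unit diagonal, rank invariance, and missing-entry flagging", {
  spec <- genetic_map_spec(2e6, background_rate = 1e-8, hotspot_rate = 5)
  m <- synth_map(spec, seed = 21)
  b <- bin_rates(m, 2000)
  # monotone rescaling of the rates leaves the correlation at exactly 1
  b_scaled <- b; b_scaled$value <- b$value^3 + 2 * b$value # monotone transform
  mat <- spearman_matrix(list(a = b, b = b_scaled), min_overlap = 10)
  expect_equal(unname(mat["a", "b"]), 1)
  expect_equal(unname(diag(mat)), c(1, 1))
  # rank-reversed copy gives exactly -1
  b_rev <- b; b_rev$value <- -b$value
  mat2 <- spearman_matrix(list(a = b, r = b_rev), min_overlap = 10)
  expect_equal(unname(mat2["a", "r"]), -1)
  # insufficient overlap is NA, not zero
  mat3 <- spearman_matrix(list(a = b, b = b_scaled), min_overlap = 1e6)
  expect_true(is.na(mat3["a", "b"]))
  # hand-checked 6-bin pair with a tie (mid-ranks)
  mk <- function(v) structure(data.frame(bin = 0:5, start = 0:5 * 2000,
                                         end = 1:6 * 2000, value = v),
                              class = c("binned_map", "data.frame"),
                              bin_width = 2000, chrom = "1")
  x <- c(1, 2, 2, 3, 5, 4); y <- c(2, 1, 3, 4, 5, 6)
  mat4 <- spearman_matrix(list(x = mk(x), y = mk(y)), min_overlap = 6)
  expect_equal(unname(mat4["x", "y"]), cor(rank(x), rank(y)))
})

test_that("clustering groups block-structured correlation matrices", {
  lab <- c("a1", "a2", "a3", "b1", "b2")
  mat <- matrix(0.3, 5, 5, dimnames = list(lab, lab))
  mat[1:3, 1:3] <- 0.95; mat[4:5, 4:5] <- 0.95; diag(mat) <- 1
  ord <- cluster_order(mat)$order
  ia <- match(c("a1", "a2", "a3"), ord); ib <- match(c("b1", "b2"), ord)
  expect_true(max(ia) < min(ib) || min(ia) > max(ib)) # blocks contiguous
  mat[1, 2] <- NA; mat[2, 1] <- NA
  expect_error(cluster_order(mat), "missing entries")
})

test_that("hotspot calling finds spikes, ignores uniform maps, and is scale invariant", {
  u <- uniform_map(1e6)
  expect_equal(nrow(call_hotspots(u, 1e5, 10, 500)), 0L)
  spike <- recomb_map("1", c(0, 5e5, 502000), c(5e5, 502000, 1e6),
                      c(1e-8, 2e-7, 1e-8))
  calls <- call_hotspots(spike, 1e5, 10, 500)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 5e5)
  expect_equal(calls$end, 502000)
  # global rate scaling leaves the calls unchanged
  scaled <- recomb_map("1", spike$start, spike$end, spike$rate * 7)
  expect_equal(call_hotspots(scaled, 1e5, 10, 500)[c("start", "end")],
               calls[c("start", "end")])
})

test_that("sibling maps at shared_fraction 1 are identical and concordant", {
  spec <- genetic_map_spec(1e7, background_rate = 2e-9, hotspot_rate = 10)
  m <- synth_map(spec, seed = 31)
  s1 <- derive_sibling_map(m, 1, seed = 32)
  expect_identical(as.data.frame(s1), as.data.frame(m))
  c1 <- call_hotspots(m, 1e5, 10, 500)
  conc <- hotspot_concordance(c1, call_hotspots(s1, 1e5, 10, 500))
  expect_equal(conc$frac_a, 1)
  s0 <- derive_sibling_map(m, 0, seed = 33)
  shared_pos <- intersect(attr(m, "hotspots")$center, attr(s0, "hotspots")$center)
  expect_length(shared_pos, 0L)
  expect_error(derive_sibling_map(uniform_map(), 0.5, seed = 1), "no hotspot annotation")
})
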