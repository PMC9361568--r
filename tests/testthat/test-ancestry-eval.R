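test_that("msp dialect round-trips through write and read", {
  tr <- tracts_from_runs(list(
    list(sample = "s1", hap = 0L, starts = c(0, 3e5, 6e5), labels = c("A", "B", "A")),
    list(sample = "s1", hap = 1L, starts = 0, labels = "C"),
    list(sample = "s2", hap = 0L, starts = c(0, 5e5), labels = c("B", "C")),
    list(sample = "s2", hap = 1L, starts = c(0, 1e5), labels = c("A", "B"))
  ), len = 1e6, alphabet = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".msp.tsv")
  write_msp(tr, f)
  back <- read_local_ancestry(f)
  o <- function(d) d[order(d$sample, d$hap, d$start), ]
  expect_equal(o(as.data.frame(back)), o(as.data.frame(tr)),
               ignore_attr = TRUE)
  expect_equal(attr(back, "alphabet"), attr(tr, "alphabet"))
  # internal TSV dialect round-trips bit-exact
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tracts(tr, f2)
  expect_identical(readLines(f2), { write_tracts(read_tracts(f2), f2); readLines(f2) })
})

test_that("msp reader merges constant windows, validates codes and tiling", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#Subpopulation order/codes: AFR=0\tEUR=1",
               paste("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                     "s1.0", "s1.1", sep = "\t"),
               "1\t0\t100\t0\t0\t0\t0\t1",
               "1\t100\t300\t0\t0\t0\t0\t0"), f)
  tr <- read_local_ancestry(f)
  # two windows with the same label merge into one tract for s1.0
  expect_equal(nrow(tr[tr$hap == 0, ]), 1L)
  expect_equal(tr$end[tr$hap == 0], 300)
  expect_equal(nrow(tr[tr$hap == 1, ]), 2L)
  # empty body: alphabet from header only
  writeLines(readLines(f)[1:2], f)
  empty <- read_local_ancestry(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "alphabet"), c("AFR", "EUR"))
  # unknown code and non-tiling windows raise located errors
  writeLines(c("#Subpopulation order/codes: AFR=0\tEUR=1",
               paste("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                     "s1.0", "s1.1", sep = "\t"),
               "1\t0\t100\t0\t0\t0\t0\t5"), f)
  expect_error(read_local_ancestry(f), "unknown ancestry code")
  writeLines(c("#Subpopulation order/codes: AFR=0\tEUR=1",
               paste("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                     "s1.0", "s1.1", sep = "\t"),
               "1\t0\t100\t0\t0\t0\t0\t1",
               "1\t150\t300\t0\t0\t0\t0\t0"), f)
  expect_error(read_local_ancestry(f), "do not tile")
})

test_that("global proportions follow tract length arithmetic", {
  tr <- tracts_from_runs(list(
    list(sample = "s1", hap = 0L, starts = c(0, 3e7, 5e7),
         labels = c("A", "B", "C")),
    list(sample = "s1", hap = 1L, starts = c(0, 3e7, 5e7),
         labels = c("A", "B", "C"))
  ), len = 1e8, alphabet = c("A", "B", "C"))
  p <- global_proportions(tr)
  expect_equal(p$A, 0.3); expect_equal(p$B, 0.2); expect_equal(p$C, 0.5)
  # one haplotype all A, the other all B
  tr2 <- tracts_from_runs(list(
    list(sample = "s", hap = 0L, starts = 0, labels = "A"),
    list(sample = "s", hap = 1L, starts = 0, labels = "B")
  ), len = 1e6, alphabet = c("A", "B"))
  p2 <- global_proportions(tr2)
  expect_equal(unname(unlist(p2)), c(0.5, 0.5))
})

test_that("accuracy scoring is exact against the per-base oracle", {
  truth <- tracts_from_runs(list(
    list(sample = "s1", hap = 0L, starts = c(0, 400000), labels = c("A", "B")),
    list(sample = "s1", hap = 1L, starts = 0, labels = "C")
  ), len = 1e6, alphabet = c("A", "B", "C"))
  inferred <- corrupt_tracts(truth, switch_error_per_mb = 2, seed = 5,
                             window_bp = 1e5)
  # snap boundaries to integers so the per-base oracle is exact
  inferred$start <- round(inferred$start); inferred$end <- round(inferred$end)
  inferred <- tract_set(as.data.frame(inferred)[inferred$end > inferred$start, ],
                        alphabet = attr(truth, "alphabet"))
  rep <- lai_accuracy(truth, inferred)
  oracle <- bf_accuracy_per_base(truth, inferred)
  expect_equal(rep$global_accuracy, oracle$global)
  expect_equal(unname(rep$per_ancestry_recall[!is.nan(oracle$recall)]),
               unname(oracle$recall[!is.nan(oracle$recall)]))
  # identical tracts: everything 1
  perfect <- lai_accuracy(truth, truth)
  expect_equal(perfect$global_accuracy, 1)
  expect_true(all(perfect$per_ancestry_recall == 1, na.rm = TRUE))
  # deranged labels: global accuracy exactly 0
  der <- truth
  der$ancestry <- c(A = "B", B = "C", C = "A")[der$ancestry]
  der <- tract_set(as.data.frame(der), alphabet = attr(truth, "alphabet"))
  expect_equal(lai_accuracy(truth, der)$global_accuracy, 0)
  # mismatched sample sets are reported by name
  other <- truth; other$sample <- "s2"
  other <- tract_set(as.data.frame(other), alphabet = attr(truth, "alphabet"))
  expect_error(lai_accuracy(truth, other), "s2")
})

test_that("global accuracy is the truth-length-weighted mean of recalls", {
  fx <- small_admixed_cohort(seed = 81, n_ind = 12, n_gen = 10, n_sites = 0)
  truth <- cohort_tracts(fx$cohort)
  inferred <- corrupt_tracts(truth, 0.5, seed = 82)
  rep <- lai_accuracy(truth, inferred)
  w <- rep$truth_ancestry_length
  expect_equal(rep$global_accuracy,
               sum(rep$per_ancestry_recall * w, na.rm = TRUE) / sum(w))
})

test_that("tract corruption preserves tiling and obeys rate limits", {
  fx <- small_admixed_cohort(seed = 83, n_ind = 10, n_gen = 8, n_sites = 0)
  truth <- cohort_tracts(fx$cohort)
  expect_identical(corrupt_tracts(truth, 0, seed = 1), truth)
  noisy <- corrupt_tracts(truth, 1, seed = 2)
  expect_true(validate_tracts(noisy))
  expect_setequal(unique(noisy$ancestry), attr(truth, "alphabet"))
  # heavy corruption drives accuracy towards the 1/|alphabet| floor
  wrecked <- corrupt_tracts(truth, 200, seed = 3, window_bp = 1e6)
  acc <- lai_accuracy(truth, wrecked)$global_accuracy
  expect_lt(acc, 0.5)
  # determinism
  expect_identical(corrupt_tracts(truth, 1, seed = 9),
                   corrupt_tracts(truth, 1, seed = 9))
  single <- tracts_from_runs(list(list(sample = "s", hap = 0L, starts = 0,
                                       labels = "A")),
                             len = 1e6, alphabet = "A")
  expect_error(corrupt_tracts(single, 1, seed = 1), "single-ancestry")
})
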