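test_that("TPM normalises by length and sums to one million", {
  single <- compute_tpm(matrix(50, 1, 1, dimnames = list("g1", "s1")), 100)
  expect_equal(unname(single[1, 1]), 1e6)

  two <- compute_tpm(matrix(c(10, 10), 2, 1,
                            dimnames = list(c("a", "b"), "s1")),
                     c(100, 200))
  expect_equal(unname(two[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  set.seed(51)
  m <- matrix(rpois(40, 50), 10, 4)
  expect_equal(unname(colSums(compute_tpm(m, runif(10, 100, 1000)))),
               rep(1e6, 4), tolerance = 1e-6)
  expect_error(compute_tpm(matrix(0, 2, 1), c(10, 10)), "all-zero")
})

test_that("RIP filter gates on expression, fold change and q-value", {
  stats_df <- data.frame(
    gene_id = c("lowtpm", "pass", "lowfc", "edge_tpm", "edge_fc", "edge_q"),
    log2fc = c(2.0, 0.6, 0.4, 0.6, 0.5, 0.6),
    qvalue = c(1e-6, 5e-4, 1e-6, 5e-4, 5e-4, 0.001))
  tpm <- c(lowtpm = 4.9, pass = 10, lowfc = 10, edge_tpm = 5.0,
           edge_fc = 10, edge_q = 10)
  ts <- rip_enrichment_filter(stats_df, tpm)
  # TPM 4.9 excluded regardless of fold change; TPM 5.0 kept;
  # log2fc 0.5 kept under the >= rule; q exactly at 0.001 excluded
  expect_setequal(ts$members, c("pass", "edge_tpm", "edge_fc"))
  strict <- rip_enrichment_filter(stats_df, tpm, strict = TRUE)
  expect_false("edge_fc" %in% strict$members)
})

test_that("DEG filter requires q < 0.05 and TPM > 1 in some genotype", {
  stats_df <- data.frame(gene_id = c("in", "q_fail", "tpm_fail", "edge"),
                         qvalue = c(0.04, 0.06, 0.01, 0.05))
  tpm <- rbind("in" = c(0.5, 1.2), q_fail = c(5, 5),
               tpm_fail = c(0.9, 0.8), edge = c(5, 5))
  ts <- deg_filter(stats_df, tpm)
  expect_identical(ts$members, "in")
})

test_that("q-values are BH-recomputed from p and preserve the p ordering", {
  set.seed(52)
  stats_df <- data.frame(gene_id = sprintf("g%02d", 1:20),
                         log2fc = 1, pvalue = runif(20))
  with_q <- clipxl:::ensure_qvalue(stats_df)
  expect_equal(with_q$qvalue, p.adjust(stats_df$pvalue, "BH"))
  o <- order(stats_df$pvalue)
  expect_true(all(diff(with_q$qvalue[o]) >= -1e-12))
  expect_error(clipxl:::ensure_qvalue(data.frame(gene_id = "a")), "qvalue")
})

test_that("overlap reports reproduce printed-precision percentages", {
  a <- target_set(sprintf("g%04d", 1:858), "iCLIP")
  b <- target_set(sprintf("g%04d", c(1:452, 2000:4000)), "RIP")
  ov <- intersect_targets(a, b)
  expect_identical(ov$n_both, 452L)
  expect_identical(ov$pct_of_a, 53)

  same <- intersect_targets(a, a)
  expect_identical(same$pct_of_a, 100)
  disjoint <- intersect_targets(a, target_set("x", "other"))
  expect_identical(disjoint$pct_of_a, 0)
  expect_identical(disjoint$pct_of_b, 0)
})

test_that("cross-referencing matches the hypergeometric expectation under permutation", {
  set.seed(53)
  universe <- sprintf("g%04d", 1:1000)
  a <- sample(universe, 300)
  b_size <- 200
  expected <- 300 * b_size / 1000
  overlaps <- vapply(1:100, function(i) {
    b <- target_set(sample(universe, b_size), "b")
    crossref_summary(list(target_set(a, "a")), list(b))$n_overlap
  }, 0)
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 3 * se + 1e-9)

  empty_row <- crossref_summary(list(target_set(character(0), "none")),
                                list(target_set(universe, "all")))
  expect_identical(empty_row$n_overlap, 0L)
  expect_identical(empty_row$pct_of_reference, 0)
})

test_that("direction summary counts signs and tests against the DEG distribution", {
  set.seed(54)
  deg <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  all_set <- target_set(names(deg), "all")
  res <- direction_summary(deg, list(all_set))
  expect_equal(res$pvalue, 1, tolerance = 1e-9)  # identical distributions
  expect_identical(res$n_up + res$n_down, sum(deg != 0))

  sep <- c(setNames(rep(-1, 50), paste0("d", 1:50)),
           setNames(rep(1, 50), paste0("u", 1:50)))
  res2 <- direction_summary(sep, list(target_set(paste0("d", 1:50), "down")))
  expect_lt(res2$pvalue, 1e-6)

  expect_warning(direction_summary(deg, list(target_set("g001", "tiny"))),
                 "skipped")
})

test_that("the U statistic equals exhaustive pair counting", {
  set.seed(55)
  for (i in 1:20) {
    x <- sample(1:10, sample(2:15, 1), replace = TRUE)  # ties included
    y <- sample(1:10, sample(2:15, 1), replace = TRUE)
    expect_equal(clipxl:::mann_whitney_u(x, y), oracle_u(x, y))
  }
})

test_that("PSI is inclusion TPM over total TPM with single-isoform exclusion", {
  tpm <- rbind(gA.i1 = c(3, 3), gA.i2 = c(7, 7),
               gB.i1 = c(5, 0), gB.i2 = c(5, 0),
               gC.i1 = c(4, 4))
  colnames(tpm) <- c("wt_1", "wt_2")
  events <- data.frame(
    event_id = c("evA", "evB", "evC"),
    gene_id = c("gA", "gB", "gC"),
    inclusion = c("gA.i1", "gB.i1", "gC.i1"),
    all = c("gA.i1,gA.i2", "gB.i1,gB.i2", "gC.i1"))
  res <- suppressWarnings(
    compute_psi(tpm, events, sample_groups = c("wt", "wt")))
  expect_setequal(res$psi$event_id, c("evA", "evB"))  # gC single isoform
  expect_equal(res$psi$psi_wt[res$psi$event_id == "evA"], 0.3)
  # gB replicate 2 has zero total TPM: replicate dropped, mean over the rest
  expect_warning(compute_psi(tpm, events, c("wt", "wt")), "undefined")
  expect_equal(res$psi$psi_wt[res$psi$event_id == "evB"], 0.5)
})

test_that("complementary inclusion groups have PSI summing to one", {
  set.seed(56)
  tpm <- matrix(rpois(12, 100) + 1, 2, 6,
                dimnames = list(c("g.i1", "g.i2"), paste0("s", 1:6)))
  ev <- data.frame(event_id = c("e_in", "e_out"), gene_id = "g",
                   inclusion = c("g.i1", "g.i2"),
                   all = "g.i1,g.i2")
  res <- compute_psi(tpm, ev, rep(c("wt", "ox"), each = 3))
  expect_equal(res$psi$psi_wt[1] + res$psi$psi_wt[2], 1, tolerance = 1e-12)
  expect_equal(res$psi$psi_ox[1] + res$psi$psi_ox[2], 1, tolerance = 1e-12)
})

test_that("delta-PSI filter applies strict effect and significance gates", {
  psi <- data.frame(event_id = paste0("e", 1:4),
                    delta_psi = c(0.12, 0.09, -0.2, 0.12),
                    pvalue = c(0.005, 1e-5, 0.005, 0.02))
  sig <- delta_psi_filter(psi)
  expect_setequal(sig$event_id, c("e1", "e3"))
})

test_that("the permutation p-value is exact, symmetric and never zero", {
  set.seed(57)
  rep_psi <- matrix(runif(12), 2, 6,
                    dimnames = list(c("e1", "e2"), paste0("s", 1:6)))
  groups <- rep(c("wt", "ox"), each = 3)
  p <- psi_permutation_pvalue(rep_psi, groups, "ox")
  expect_true(all(p >= 1 / choose(6, 3)))
  expect_true(all(p <= 1))
  # identical replicate PSI in both genotypes: every permutation ties
  flat <- matrix(0.5, 1, 6, dimnames = list("e", paste0("s", 1:6)))
  expect_equal(psi_permutation_pvalue(flat, groups, "ox"), 1)
})
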