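test_that("the length-normalized inclusion level matches its formula", {
  expect_equal(exon_inclusion_level(20, 5), 2 / 3)
  expect_equal(exon_inclusion_level(7, 0), 1)
  expect_equal(exon_inclusion_level(0, 9), 0)
  expect_true(is.na(exon_inclusion_level(0, 0)))
  expect_error(exon_inclusion_level(-1, 2), "negative")

  # monotone non-decreasing in I for fixed S, always in [0, 1]
  psis <- exon_inclusion_level(0:50, rep(10, 51))
  expect_true(all(diff(psis) >= 0))
  expect_true(all(psis >= 0 & psis <= 1))
})

test_that("duplicate exons collapse to the minimum inclusion level", {
  ev <- data.frame(
    contig = "c", strand = "+",
    exon_start = c(10, 10, 50, 90, 90, 90),
    exon_end   = c(20, 20, 60, 99, 99, 99),
    psi = c(0.8, 0.3, 0.7, 1.0, 0.99, 0.5))
  out <- collapse_duplicate_exons(ev)
  expect_equal(nrow(out), 3L)
  expect_equal(out$psi[out$exon_start == 10], 0.3)
  expect_equal(out$psi[out$exon_start == 50], 0.7)   # unique: unchanged
  expect_equal(out$psi[out$exon_start == 90], 0.5)   # min of three
})

test_that("the commitment score counts strictly committed exons", {
  idx <- toy_idx(tpm = 100)
  res <- exon_commitment_score(
    make_commitment_events(c(1.0, 0.0, 0.5, 0.995, 0.005)), idx)
  expect_equal(res$score, 4 / 5)
  expect_equal(res$n_total, 5L)

  # strict inequalities at both bounds
  res2 <- exon_commitment_score(make_commitment_events(c(0.99, 0.01, 1)), idx)
  expect_equal(res2$score, 1 / 3)

  res3 <- exon_commitment_score(make_commitment_events(c(0, 1, 1, 0)), idx)
  expect_equal(res3$score, 1)

  # appending an uncommitted exon never increases the score
  res4 <- exon_commitment_score(make_commitment_events(c(1, 0, 0.5, 0.995,
                                                         0.005, 0.5)), idx)
  expect_lte(res4$score, res$score)

  # TPM gate: events in unexpressed genes are not scorable
  idx_low <- toy_idx(tpm = 5)
  expect_error(exon_commitment_score(make_commitment_events(c(1, 0)), idx_low),
               "no scorable")
})

test_that("the commitment score equals a one-line oracle over random psi vectors", {
  idx <- toy_idx(tpm = 100)
  set.seed(11)
  for (i in 1:200) {
    psi <- runif(sample(3:40, 1))
    res <- exon_commitment_score(make_commitment_events(psi), idx,
                                 min_depth = 0)
    expect_equal(res$score, mean(psi > 0.99 | psi < 0.01))
  }
})

test_that("differential inclusion reports exact two-sided p-values and BH FDR", {
  mk <- function(I, S) data.frame(
    event_id = paste0("e", seq_along(I)), gene_id = "GENE1",
    inclusion_reads = I, skip_reads = S)
  d0 <- differential_inclusion(mk(10, 10), mk(10, 10))
  expect_equal(d0$delta_psi, 0)
  expect_equal(d0$p_value, 1)

  d1 <- differential_inclusion(mk(30, 0), mk(0, 30))
  expect_equal(d1$delta_psi, 1)
  expect_equal(d1$p_value, oracle_fisher_2x2(30, 0, 0, 30), tolerance = 1e-10)

  # agreement with the enumeration oracle for small tables
  set.seed(3)
  for (i in 1:30) {
    tab <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    d <- differential_inclusion(mk(tab[1], tab[2]), mk(tab[3], tab[4]))
    if (!nrow(d)) next
    expect_equal(d$p_value, oracle_fisher_2x2(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }

  # BH: fdr >= p, and matches p.adjust
  set.seed(4)
  I1 <- rbinom(50, 60, 0.5); S1 <- 60 - I1
  I2 <- rbinom(50, 60, 0.5); S2 <- 60 - I2
  d <- differential_inclusion(mk(I1, S1), mk(I2, S2))
  expect_equal(d$fdr, p.adjust(d$p_value, "BH"))
  expect_true(all(d$fdr >= d$p_value))
})

test_that("a null simulation yields no BH-significant events", {
  set.seed(5)
  n <- 100
  I1 <- rbinom(n, 200, 2 * 0.5 / 1.5); S1 <- 200 - I1
  I2 <- rbinom(n, 200, 2 * 0.5 / 1.5); S2 <- 200 - I2
  d <- differential_inclusion(
    data.frame(event_id = paste0("e", 1:n), gene_id = "g",
               inclusion_reads = I1, skip_reads = S1),
    data.frame(event_id = paste0("e", 1:n), gene_id = "g",
               inclusion_reads = I2, skip_reads = S2))
  expect_equal(sum(d$fdr < 0.05), 0L)
})

test_that("estimated psi recovers the simulation truth as depth grows", {
  set.seed(6)
  rmse_at <- function(n) {
    psi_true <- 0.4
    w <- 2 * psi_true / (1 + psi_true)
    I <- rbinom(200, n, w)
    psi_hat <- exon_inclusion_level(I, n - I)
    sqrt(mean((psi_hat - psi_true)^2))
  }
  expect_lt(rmse_at(400), 0.05)
  expect_lt(rmse_at(400), rmse_at(40))
})
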