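test_that("prevalence uses recorded-only denominators and round-trips k/n labels", {
  co <- make_cohort(list(hearing = statuses_from_counts(345, 408 - 345, 443 - 408)))
  p <- prevalence(co, "hearing")
  expect_equal(p$n_recorded, 408L)
  expect_equal(round(100 * p$proportion, 2), 84.56)
  expect_equal(p$label, "84.56% (345/408)")

  co2 <- make_cohort(list(megacolon = statuses_from_counts(18, 32, 10)),
                     gene = rep("SOX10", 60))
  p2 <- prevalence(co2, "megacolon", gene = "SOX10")
  expect_equal(p2$label, "36.00% (18/50)")

  none <- make_cohort(list(ph = rep("unrecorded", 5)))
  expect_true(is.na(prevalence(none, "ph")$proportion))
  expect_error(prevalence(co, "nope"), "unknown phenotype")
})

test_that("Pearson chi-square matches the direct formula without continuity correction", {
  flat <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  perfect <- pearson_chi2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(perfect$statistic, 40)
  expect_lt(perfect$p, 1e-9)
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rpois(6, 8) + 1, nrow = 2)
    got <- pearson_chi2(m)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$statistic, sum((m - E)^2 / E))
    expect_equal(got$df, 2)
    expect_equal(got$p, pchisq(got$statistic, 2, lower.tail = FALSE))
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("the exact test reproduces enumeration oracles and the classic table", {
  m <- matrix(c(1, 11, 9, 3), 2)
  expect_equal(fisher_exact(m), fisher_2x2_oracle(m), tolerance = 1e-12)
  expect_equal(fisher_exact(m), 0.002759456, tolerance = 1e-7)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(41)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact(t2), fisher_2x2_oracle(t2), tolerance = 1e-12)
    t3 <- matrix(rpois(6, 4), 2)
    expect_equal(fisher_exact(t3), fisher_2x3_oracle(t3), tolerance = 1e-12)
    # independent cross-check against the reference implementation
    if (all(rowSums(t3) > 0) && all(colSums(t3) > 0)) {
      expect_equal(fisher_exact(t3), stats::fisher.test(t3)$p.value, tolerance = 1e-6)
    }
  }
  expect_error(fisher_exact(matrix(2000, 2, 2)), "bound")
  expect_error(fisher_exact(matrix(200, 2, 3)), "bound")
})

cohort_from_tables <- function(tables, genes = c("PAX3", "MITF", "SOX10")) {
  # tables: list per gene of c(present, absent, unrecorded)
  status <- unlist(lapply(tables, function(x) statuses_from_counts(x[1], x[2], x[3])))
  make_cohort(list(ph = status),
              gene = rep(genes, vapply(tables, sum, 0)))
}

test_that("group tests pick the exact test under sparse expectation and report pairwise p", {
  co <- cohort_from_tables(list(c(80, 20, 5), c(60, 40, 5), c(95, 5, 5)))
  res <- group_association_test(co, "ph")
  expect_equal(res$test_used, "pearson_chi2")
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p > 0 & res$pairwise$p <= 1))
  expect_equal(unname(colSums(res$counts)), res$prevalence$n_recorded)

  # expected counts below 5 force the exact test (here: tiny absent margins)
  sparse <- cohort_from_tables(list(c(20, 1, 0), c(19, 2, 0), c(18, 1, 0)))
  expect_equal(group_association_test(sparse, "ph")$test_used, "fisher_exact")

  empty_stratum <- cohort_from_tables(list(c(20, 10, 0), c(15, 15, 0), c(0, 0, 10)))
  expect_warning(res2 <- group_association_test(empty_stratum, "ph"), "dropped")
  expect_equal(res2$strata, c("PAX3", "MITF"))
  one <- cohort_from_tables(list(c(20, 10, 0), c(0, 0, 5), c(0, 0, 5)))
  expect_error(suppressWarnings(group_association_test(one, "ph")), "fewer than 2")
})

test_that("phi matches its closed form, the chi-square identity, and label-swap symmetry", {
  expect_equal(wsdecipher:::phi_from_counts(10, 0, 0, 10)$phi, 1)
  expect_equal(wsdecipher:::phi_from_counts(9, 3, 6, 2)$phi, 0)
  expect_true(is.na(wsdecipher:::phi_from_counts(5, 5, 0, 0)$phi))
  set.seed(51)
  for (i in 1:200) {
    x <- rpois(4, 6) + 1
    r <- wsdecipher:::phi_from_counts(x[1], x[2], x[3], x[4])
    n <- sum(x)
    chi <- pearson_chi2(matrix(c(x[1], x[3], x[2], x[4]), 2))
    expect_equal(n * r$phi^2, chi$statistic, tolerance = 1e-9)
    # swapping both labels preserves phi; swapping one flips its sign
    expect_equal(wsdecipher:::phi_from_counts(x[4], x[3], x[2], x[1])$phi, r$phi)
    expect_equal(wsdecipher:::phi_from_counts(x[2], x[1], x[4], x[3])$phi, -r$phi)
  }
})

test_that("phi_correlation restricts to doubly-recorded patients", {
  co <- make_cohort(list(
    a = c("present", "present", "absent", "absent", "unrecorded", "present"),
    b = c("present", "absent", "present", "absent", "present", "unrecorded")))
  r <- phi_correlation(co, "a", "b")
  expect_equal(r$n, 4L)
  expect_equal(c(r$a, r$b, r$c, r$d), c(1L, 1L, 1L, 1L))
  expect_equal(r$phi, 0)
})

test_that("the phi matrix is symmetric with a unit diagonal and honest NA cells", {
  set.seed(61)
  n <- 80
  co <- make_cohort(list(x = sample(c("present", "absent"), n, TRUE),
                         y = sample(c("present", "absent"), n, TRUE),
                         z = rep("present", n)))
  pm <- phi_matrix(co, c("x", "y", "z"))
  expect_equal(pm$phi, t(pm$phi))
  expect_equal(unname(diag(pm$phi)), c(1, 1, 1))
  expect_true(is.na(pm$phi["x", "z"]))  # zero margin: undefined, not 0
  expect_false(any(pm$significant[is.na(pm$p)]))
  expect_error(phi_matrix(co, "x"), "at least 2")
})

test_that("sex tests require both groups and give p = 1 on identical tables", {
  co <- make_cohort(list(ph = rep(c("present", "absent"), each = 20)),
                    sex = rep(c("male", "female"), 20))
  res <- sex_difference_tests(co, "ph")
  expect_equal(res$p, 1)
  expect_equal(res$male_recorded, 20L)
  males <- make_cohort(list(ph = rep("present", 5)), sex = rep("male", 5))
  expect_error(sex_difference_tests(males, "ph"), "per group")
})

test_that("distribution summaries state counts, denominators and percentages", {
  genes <- rep(c("PAX3", "MITF", "SOX10"), c(138, 161, 144))
  co <- make_cohort(list(ph = rep("absent", 443)), gene = genes,
                    subtype = rep(c("WS1", "WS2"), c(200, 243)),
                    variant_type = rep(c("missense", "nonsense"), c(300, 143)))
  d <- distribution_summaries(co)
  expect_equal(d$n_total, 443L)
  expect_equal(d$gene_overall$n[d$gene_overall$gene == "PAX3"], 138L)
  expect_equal(round(d$gene_overall$pct[d$gene_overall$gene == "PAX3"], 2), 31.15)
  expect_equal(sum(d$gene_by_subtype$n), 443L)
  expect_equal(sum(d$variant_type_overall$pct), 100)
  empty <- distribution_summaries(make_cohort(list(ph = character(0)),
                                              gene = character(0),
                                              subtype = character(0),
                                              variant_type = character(0)))
  expect_equal(nrow(empty$gene_overall), 0L)
})
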