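#' Missing-aware phenotype prevalence
#'
#' Counts patients with the phenotype present over patients with a recorded
#' status (present or absent); patients with unrecorded status are excluded
#' from the denominator, so denominators can be smaller than the stratum size.
#'
#' @param cohort A `cohort_table`.
#' @param phenotype Name of one ternary phenotype column.
#' @param gene Optional gene symbol; restricts to patients carrying a variant
#'   in that gene.
#' @return List with `phenotype`, `stratum`, `n_present`, `n_recorded`,
#'   `proportion` (`NA` when nothing is recorded), and `label` — the
#'   conventional `"x% (k/n)"` rendering.
#' @export
prevalence <- function(cohort, phenotype, gene = NULL) {
  if (!phenotype %in% attr(cohort, "phenotypes")) {
    stop(sprintf("unknown phenotype column '%s'", phenotype))
  }
  rows <- if (is.null(gene)) rep(TRUE, nrow(cohort)) else
    cohort$gene == normalize_gene_symbols(gene)
  status <- cohort[[phenotype]][rows]
  n_present <- sum(status == "present")
  n_recorded <- sum(status != "unrecorded")
  prop <- if (n_recorded > 0L) n_present / n_recorded else NA_real_
  list(phenotype = phenotype, stratum = if (is.null(gene)) "all" else normalize_gene_symbols(gene),
       n_present = n_present, n_recorded = n_recorded, proportion = prop,
       label = if (is.na(prop)) NA_character_ else
         sprintf("%.2f%% (%d/%d)", 100 * prop, n_present, n_recorded))
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic on an r x c contingency table:
#' sum((O - E)^2 / E) with df = (r-1)(c-1) and an upper-tail chi-square
#' p-value. No continuity correction is applied unless requested.
#'
#' @param counts Numeric matrix of nonnegative counts; every row and column
#'   margin must be positive.
#' @param correct Apply the Yates continuity correction (2x2 only); off by
#'   default.
#' @return List with `statistic`, `df`, `p`, and `expected`.
#' @export
pearson_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative and complete")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin: chi-square test undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected)
}

# Hypergeometric probabilities of every 2x2 table with the observed margins,
# indexed by the count in cell [1,1].
hyper_probs_2x2 <- function(counts) {
  r1 <- sum(counts[1, ]); c1 <- sum(counts[, 1]); n <- sum(counts)
  a <- max(0L, r1 + c1 - n):min(r1, c1)
  list(a = a, prob = stats::dhyper(a, c1, n - c1, r1))
}

# All first rows (a1, a2, a3) compatible with the margins of a 2x3 table,
# with their multivariate hypergeometric probabilities.
freeman_halton_probs <- function(counts) {
  r1 <- sum(counts[1, ]); cs <- colSums(counts); n <- sum(counts)
  lden <- lchoose(n, r1)
  a1 <- 0:min(r1, cs[1])
  out_a <- NULL; out_p <- NULL
  for (x1 in a1) {
    a2 <- max(0L, r1 - x1 - cs[3]):min(r1 - x1, cs[2])
    if (length(a2) == 0L || a2[1] > a2[length(a2)]) next
    a3 <- r1 - x1 - a2
    lp <- lchoose(cs[1], x1) + lchoose(cs[2], a2) + lchoose(cs[3], a3) - lden
    out_a <- rbind(out_a, cbind(x1, a2, a3))
    out_p <- c(out_p, exp(lp))
  }
  list(rows = out_a, prob = out_p)
}

#' Two-sided Fisher exact test
#'
#' For a 2x2 table, the two-sided p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of every table
#' whose probability does not exceed the observed table's (with a 1e-12
#' relative slack for floating-point ties). For a 2x3 table, the
#' Freeman-Halton extension is computed by full enumeration of margin-fixed
#' tables under the multivariate hypergeometric null. Tables larger than the
#' enumeration bound are refused with an error instructing chi-square use.
#'
#' @param counts 2x2 or 2x3 matrix of nonnegative counts.
#' @param max_n_2x2,max_n_2x3 Enumeration bounds on the table total.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact <- function(counts, max_n_2x2 = 2000, max_n_2x3 = 500) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || !ncol(counts) %in% c(2L, 3L)) {
    stop("fisher_exact handles 2x2 and 2x3 tables only")
  }
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative and complete")
  n <- sum(counts)
  slack <- 1 + 1e-12
  if (ncol(counts) == 2L) {
    if (n > max_n_2x2) {
      stop(sprintf("table total %d exceeds the 2x2 enumeration bound %d; use the chi-square test",
                   n, max_n_2x2))
    }
    hp <- hyper_probs_2x2(counts)
    p_obs <- hp$prob[hp$a == counts[1, 1]]
    min(1, sum(hp$prob[hp$prob <= p_obs * slack]))
  } else {
    if (n > max_n_2x3) {
      stop(sprintf("table total %d exceeds the 2x3 enumeration bound %d; use the chi-square test",
                   n, max_n_2x3))
    }
    fh <- freeman_halton_probs(counts)
    obs <- which(fh$rows[, 1] == counts[1, 1] & fh$rows[, 2] == counts[1, 2])
    p_obs <- fh$prob[obs]
    min(1, sum(fh$prob[fh$prob <= p_obs * slack]))
  }
}

# Present/absent x stratum contingency table over recorded patients.
phenotype_gene_table <- function(cohort, phenotype, genes) {
  counts <- vapply(genes, function(g) {
    status <- cohort[[phenotype]][cohort$gene == g]
    c(present = sum(status == "present"), absent = sum(status == "absent"))
  }, c(present = 0, absent = 0))
  matrix(counts, nrow = 2L, dimnames = list(c("present", "absent"), genes))
}

# Shared test-selection rule: Fisher when any expected count < 5, else
# Pearson chi-square; Fisher falls back to chi-square (with a warning) when
# the table exceeds the exact enumeration bound.
select_and_run_test <- function(counts, expected_min = 5) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_fisher <- any(E < expected_min)
  if (use_fisher) {
    p <- tryCatch(fisher_exact(counts), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(p)) return(list(test_used = "fisher_exact", p = p))
  }
  list(test_used = "pearson_chi2", p = pearson_chi2(counts)$p)
}

#' Genotype-phenotype group association test
#'
#' Builds the present/absent x gene table for one phenotype over recorded
#' patients, runs a group test (Fisher's exact test when any expected count is
#' below 5, Pearson chi-square otherwise), and the same rule on every pairwise
#' 2x2 sub-table. P-values are raw, two-sided, unadjusted for multiplicity.
#'
#' @param cohort A `cohort_table`.
#' @param phenotype Name of one ternary phenotype column.
#' @param genes Strata to compare; defaults to the three major disease genes.
#' @param expected_min Expected-count threshold of the test-selection rule.
#' @return An `association_result`: list with `phenotype`, `strata`, `counts`,
#'   `test_used`, `p_group`, `pairwise` (data frame), and `prevalence` per
#'   stratum.
#' @export
group_association_test <- function(cohort, phenotype,
                                   genes = c("PAX3", "MITF", "SOX10"),
                                   expected_min = 5) {
  if (!phenotype %in% attr(cohort, "phenotypes")) {
    stop(sprintf("unknown phenotype column '%s'", phenotype))
  }
  genes <- normalize_gene_symbols(genes)
  counts <- phenotype_gene_table(cohort, phenotype, genes)
  usable <- colSums(counts) > 0
  if (any(!usable)) {
    warning(sprintf("stratum(a) with no recorded patients dropped: %s",
                    paste(genes[!usable], collapse = ", ")))
    counts <- counts[, usable, drop = FALSE]
    genes <- genes[usable]
  }
  if (length(genes) < 2L) stop("fewer than 2 usable strata")
  group <- if (any(rowSums(counts) == 0)) {
    # All-present or all-absent phenotype: no association detectable.
    list(test_used = "degenerate", p = 1)
  } else {
    select_and_run_test(counts, expected_min)
  }
  pairs <- utils::combn(genes, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    sub <- counts[, pairs[, k], drop = FALSE]
    res <- if (any(rowSums(sub) == 0)) list(test_used = "degenerate", p = 1) else
      select_and_run_test(sub, expected_min)
    data.frame(stratum_a = pairs[1, k], stratum_b = pairs[2, k],
               test_used = res$test_used, p = res$p, stringsAsFactors = FALSE)
  }))
  prev <- do.call(rbind, lapply(genes, function(g) {
    p <- prevalence(cohort, phenotype, gene = g)
    data.frame(gene = g, n_present = p$n_present, n_recorded = p$n_recorded,
               proportion = p$proportion, stringsAsFactors = FALSE)
  }))
  structure(list(phenotype = phenotype, strata = genes, counts = counts,
                 test_used = group$test_used, p_group = group$p,
                 pairwise = pairwise, prevalence = prev),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Association of '%s' across %s: %s p = %.4g\n", x$phenotype,
              paste(x$strata, collapse = "/"), x$test_used, x$p_group))
  invisible(x)
}

# Phi coefficient and chi-square p from 2x2 counts (a,b;c,d). Undefined
# (NA) when any margin is zero.
phi_from_counts <- function(a, b, c, d) {
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) return(list(phi = NA_real_, p = NA_real_))
  phi <- (a * d - b * c) / sqrt(prod(m))
  list(phi = phi, p = pearson_chi2(matrix(c(a, c, b, d), 2L))$p)
}

#' Phi coefficient between two phenotypes
#'
#' Pearson correlation of two binary phenotype indicators computed from the
#' 2x2 co-occurrence table over patients with both statuses recorded:
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)). The association p-value
#' comes from the uncorrected Pearson chi-square on the same table (the
#' identity chi2 = n * phi^2 holds for 2x2 tables). Phi is undefined (`NA`)
#' when any margin is zero.
#'
#' @param cohort A `cohort_table`.
#' @param phenotype_a,phenotype_b Two ternary phenotype columns.
#' @return A `phi_result`: list with the pair, the 2x2 counts
#'   (`a` both present, `b` a only, `c` b only, `d` neither), `n`, `phi`, `p`.
#' @export
phi_correlation <- function(cohort, phenotype_a, phenotype_b) {
  for (ph in c(phenotype_a, phenotype_b)) {
    if (!ph %in% attr(cohort, "phenotypes")) stop(sprintf("unknown phenotype column '%s'", ph))
  }
  sa <- cohort[[phenotype_a]]; sb <- cohort[[phenotype_b]]
  both <- sa != "unrecorded" & sb != "unrecorded"
  pa <- sa[both] == "present"; pb <- sb[both] == "present"
  a <- sum(pa & pb); b <- sum(pa & !pb); c <- sum(!pa & pb); d <- sum(!pa & !pb)
  res <- phi_from_counts(a, b, c, d)
  structure(list(phenotype_a = phenotype_a, phenotype_b = phenotype_b,
                 a = a, b = b, c = c, d = d, n = a + b + c + d,
                 phi = res$phi, p = res$p),
            class = "phi_result")
}

#' Phenotype co-occurrence phi matrix
#'
#' Computes the phi coefficient and its chi-square p-value for every unordered
#' phenotype pair, plus a significance mask at level `alpha`. The diagonal is
#' 1 by convention; undefined phi values stay `NA` (never coerced to 0) and
#' are never flagged significant.
#'
#' @param cohort A `cohort_table`.
#' @param phenotypes At least two ternary phenotype columns; defaults to all.
#' @param alpha Significance level for the mask; default 0.05.
#' @return List with symmetric matrices `phi`, `p`, logical `significant`,
#'   and the pairwise long-format data frame `pairs`.
#' @export
phi_matrix <- function(cohort, phenotypes = attr(cohort, "phenotypes"), alpha = 0.05) {
  if (length(phenotypes) < 2L) stop("phi_matrix needs at least 2 phenotypes")
  k <- length(phenotypes)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(phenotypes, phenotypes))
  diag(phi) <- 1
  pairs <- NULL
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      r <- phi_correlation(cohort, phenotypes[i], phenotypes[j])
      phi[i, j] <- phi[j, i] <- r$phi
      p[i, j] <- p[j, i] <- r$p
      pairs <- rbind(pairs, data.frame(phenotype_a = phenotypes[i],
                                       phenotype_b = phenotypes[j], n = r$n,
                                       phi = r$phi, p = r$p, stringsAsFactors = FALSE))
    }
  }
  sig <- !is.na(p) & p < alpha
  list(phi = phi, p = p, significant = sig, pairs = pairs, alpha = alpha)
}

#' Sex differences in phenotype prevalence
#'
#' For each phenotype, a 2x2 present/absent x sex table over patients with
#' recorded sex and recorded phenotype status, tested under the same
#' selection rule as [group_association_test()].
#'
#' @param cohort A `cohort_table` with a `sex` column coded
#'   `male`/`female`/`unrecorded`.
#' @param phenotypes Ternary phenotype columns to test; defaults to all.
#' @param expected_min Expected-count threshold of the test-selection rule.
#' @return Data frame with per-sex recorded/present counts, `test_used`, `p`.
#' @export
sex_difference_tests <- function(cohort, phenotypes = attr(cohort, "phenotypes"),
                                 expected_min = 5) {
  if (!"sex" %in% names(cohort)) stop("cohort has no 'sex' column")
  sex <- tolower(cohort$sex)
  if (sum(sex == "male") == 0L || sum(sex == "female") == 0L) {
    stop("sex must be recorded for at least one patient per group")
  }
  do.call(rbind, lapply(phenotypes, function(ph) {
    status <- cohort[[ph]]
    keep <- sex %in% c("male", "female") & status != "unrecorded"
    counts <- matrix(c(sum(keep & sex == "male" & status == "present"),
                       sum(keep & sex == "male" & status == "absent"),
                       sum(keep & sex == "female" & status == "present"),
                       sum(keep & sex == "female" & status == "absent")),
                     nrow = 2L, dimnames = list(c("present", "absent"), c("male", "female")))
    res <- if (any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
      list(test_used = "degenerate", p = NA_real_)
    } else {
      select_and_run_test(counts, expected_min)
    }
    data.frame(phenotype = ph,
               male_recorded = sum(counts[, "male"]), male_present = counts["present", "male"],
               female_recorded = sum(counts[, "female"]), female_present = counts["present", "female"],
               test_used = res$test_used, p = res$p, stringsAsFactors = FALSE)
  }))
}

#' Cohort composition summaries
#'
#' Gene-by-subtype and variant-type-by-gene count tables with percentages and
#' explicit denominators: overall shares use the total cohort size, subtype
#' shares use per-subtype totals, and per-gene variant-type shares use
#' per-gene totals.
#'
#' @param cohort A `cohort_table` with `gene`, `subtype`, and `variant_type`
#'   columns.
#' @return List of data frames: `gene_overall`, `gene_by_subtype`,
#'   `variant_type_overall`, `variant_type_by_gene`; plus `n_total`.
#' @export
distribution_summaries <- function(cohort) {
  n_total <- nrow(cohort)
  count_df <- function(x, name) {
    tab <- as.data.frame(table(x), stringsAsFactors = FALSE)
    names(tab) <- c(name, "n")
    tab[order(tab[[name]], method = "radix"), , drop = FALSE]
  }
  if (n_total == 0L) {
    return(list(gene_overall = data.frame(gene = character(0), n = integer(0), pct = numeric(0)),
                gene_by_subtype = data.frame(subtype = character(0), gene = character(0),
                                             n = integer(0), n_subtype = integer(0), pct = numeric(0)),
                variant_type_overall = data.frame(variant_type = character(0), n = integer(0), pct = numeric(0)),
                variant_type_by_gene = data.frame(gene = character(0), variant_type = character(0),
                                                  n = integer(0), n_gene = integer(0), pct = numeric(0)),
                n_total = 0L))
  }
  gene_overall <- count_df(cohort$gene, "gene")
  gene_overall$pct <- 100 * gene_overall$n / n_total
  gbs <- as.data.frame(table(subtype = cohort$subtype, gene = cohort$gene),
                       stringsAsFactors = FALSE)
  gbs <- gbs[gbs$Freq > 0, , drop = FALSE]
  names(gbs)[3] <- "n"
  sub_totals <- table(cohort$subtype)
  gbs$n_subtype <- as.integer(sub_totals[gbs$subtype])
  gbs$pct <- 100 * gbs$n / gbs$n_subtype
  gbs <- gbs[order(gbs$subtype, gbs$gene, method = "radix"), , drop = FALSE]
  vt_overall <- count_df(cohort$variant_type, "variant_type")
  vt_overall$pct <- 100 * vt_overall$n / n_total
  vbg <- as.data.frame(table(gene = cohort$gene, variant_type = cohort$variant_type),
                       stringsAsFactors = FALSE)
  vbg <- vbg[vbg$Freq > 0, , drop = FALSE]
  names(vbg)[3] <- "n"
  gene_totals <- table(cohort$gene)
  vbg$n_gene <- as.integer(gene_totals[vbg$gene])
  vbg$pct <- 100 * vbg$n / vbg$n_gene
  vbg <- vbg[order(vbg$gene, vbg$variant_type, method = "radix"), , drop = FALSE]
  rownames(gene_overall) <- rownames(gbs) <- rownames(vt_overall) <- rownames(vbg) <- NULL
  list(gene_overall = gene_overall, gene_by_subtype = gbs,
       variant_type_overall = vt_overall, variant_type_by_gene = vbg,
       n_total = n_total)
}
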