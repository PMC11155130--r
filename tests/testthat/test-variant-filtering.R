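variant_df <- function(sift, pp2, mt, cadd, gerp, gene = "PAX3",
                       id = sprintf("rs%d", seq_along(sift)),
                       pc = "p.R156C") {
  data.frame(gene = gene, variant_id = id, protein_change = pc,
             sift = sift, polyphen2_hvar = pp2, mutationtaster = mt,
             cadd_phred = cadd, gerp_rs = gerp, stringsAsFactors = FALSE)
}

test_that("the consensus filter honours the printed boundary semantics", {
  pass <- consensus_filter(variant_df(0.0005, 0.998, 1, 29.1, 5.2))
  expect_true(pass$pass)
  # SIFT boundary is non-strict; CADD and GERP++ boundaries are strict
  boundary <- consensus_filter(variant_df(0.001, 0.958, 1, 25.0, 4.0))
  expect_false(boundary$pass)
  expect_equal(boundary$sift, "pass")
  expect_equal(boundary$cadd_phred, "fail")
  expect_equal(boundary$gerp_rs, "fail")
})

test_that("a missing score fails closed", {
  v <- variant_df(NA, 0.998, 1, 29.1, 5.2)
  dec <- consensus_filter(v)
  expect_equal(dec$sift, "missing")
  expect_false(dec$pass)
})

test_that("overall pass equals brute-force evaluation of the five comparisons", {
  set.seed(14)
  n <- 200
  v <- variant_df(runif(n), runif(n), sample(c(0, 0.5, 1), n, replace = TRUE),
                  runif(n, 0, 60), runif(n, -5, 6))
  holes <- matrix(runif(n * 5) < 0.1, nrow = n)
  cols <- c("sift", "polyphen2_hvar", "mutationtaster", "cadd_phred", "gerp_rs")
  for (j in 1:5) v[[cols[j]]][holes[, j]] <- NA
  dec <- consensus_filter(v)
  oracle <- !is.na(v$sift) & v$sift <= 0.001 &
    !is.na(v$polyphen2_hvar) & v$polyphen2_hvar > 0.957 &
    !is.na(v$mutationtaster) & v$mutationtaster == 1 &
    !is.na(v$cadd_phred) & v$cadd_phred > 25 &
    !is.na(v$gerp_rs) & v$gerp_rs > 4
  expect_equal(dec$pass, oracle)
})

test_that("categorical MutationTaster codes are accepted when configured", {
  v <- variant_df(0.0005, 0.998, NA, 29.1, 5.2)
  v$mutationtaster <- "D"
  th <- filter_thresholds(mutationtaster_categorical = TRUE)
  expect_true(consensus_filter(v, th)$pass)
  v$mutationtaster <- "N"
  expect_false(consensus_filter(v, th)$pass)
})

test_that("filter_table preserves input order and counts per gene", {
  set.seed(2)
  v <- variant_df(c(rep(0.0005, 3), rep(0.5, 7)), 0.998, 1, 30, 5,
                  gene = rep(c("PAX3", "MITF"), 5))
  res <- filter_table(v)
  expect_equal(nrow(res$survivors), 3L)
  expect_equal(res$survivors$variant_id, v$variant_id[1:3])
  expect_equal(sum(res$gene_counts$n_survivors), 3L)

  all_missing <- variant_df(NA, NA, NA, NA, NA)
  expect_equal(nrow(filter_table(all_missing)$survivors), 0L)
})

test_that("relaxing any threshold never shrinks the survivor set", {
  set.seed(6)
  n <- 150
  v <- variant_df(runif(n, 0, 0.01), runif(n, 0.9, 1), sample(c(1, 0.99), n, TRUE),
                  runif(n, 20, 30), runif(n, 3, 5))
  strict <- filter_table(v)$survivors$variant_id
  relaxed <- list(filter_thresholds(sift_max = 0.005),
                  filter_thresholds(polyphen2_hvar_min = 0.9),
                  filter_thresholds(cadd_phred_min = 20),
                  filter_thresholds(gerp_rs_min = 3))
  for (th in relaxed) {
    expect_true(all(strict %in% filter_table(v, th)$survivors$variant_id))
  }
})

test_that("cross-referencing partitions survivors into known and novel", {
  surv <- variant_df(rep(0.0005, 57), 0.998, 1, 30, 5)
  known <- surv$variant_id[1:16]
  parts <- crossref_known(surv, known)
  expect_equal(nrow(parts$known), 16L)
  expect_equal(nrow(parts$novel), 41L)
  expect_equal(nrow(parts$known) + nrow(parts$novel), nrow(surv))
  expect_equal(nrow(crossref_known(surv, character(0))$novel), 57L)
  # set-difference oracle on random overlap
  set.seed(10)
  rand_known <- sample(surv$variant_id, 20)
  parts2 <- crossref_known(surv, rand_known)
  expect_setequal(parts2$novel$variant_id, setdiff(surv$variant_id, rand_known))
})

write_fasta <- function(named_seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(named_seqs), function(n) c(paste0(">", n), named_seqs[[n]]))), path)
  path
}

test_that("conservation maps reference positions through gaps and judges columns", {
  # reference has a gap before its 3rd residue: ungapped position 3 -> column 4
  aln <- read_alignment(write_fasta(c(REF = "MR-RT", S2 = "MRKRT", S3 = "MRKRT")), "REF")
  v <- list(gene = "G", protein_change = "p.R3C")
  expect_true(conservation_check(v, aln))
  # one deviant residue breaks strict identity but not a 2/3 fraction
  aln2 <- read_alignment(write_fasta(c(REF = "MR-RT", S2 = "MRKKT", S3 = "MRKRT")), "REF")
  expect_false(conservation_check(v, aln2))
  expect_true(conservation_check(v, aln2, min_identity_fraction = 2 / 3))
  # a gap in any row at the column means not conserved
  aln3 <- read_alignment(write_fasta(c(REF = "MRRT", S2 = "MR-T")), "REF")
  expect_false(conservation_check(list(gene = "G", protein_change = "p.R3C"), aln3))
  # stated reference residue must match the alignment
  expect_warning(out <- conservation_check(list(gene = "G", protein_change = "p.K3C"), aln),
                 "does not match")
  expect_true(is.na(out))
  expect_error(conservation_check(list(gene = "G", protein_change = "p.R99C"), aln),
               "beyond")
})

test_that("column verdicts equal a brute-force column tally on a random toy alignment", {
  set.seed(18)
  aa <- c("A", "R", "K")
  mat <- matrix(sample(aa, 7 * 20, replace = TRUE), nrow = 7)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- c("REF", sprintf("S%d", 2:7))
  aln <- read_alignment(write_fasta(as.list(seqs)), "REF")
  for (pos in 1:20) {
    v <- list(gene = "G", protein_change = sprintf("p.%s%d%s", mat[1, pos], pos,
                                                   setdiff(aa, mat[1, pos])[1]))
    expect_equal(conservation_check(v, aln),
                 length(unique(mat[, pos])) == 1L)
  }
})

test_that("domain localization uses 1-based inclusive bounds and first-match order", {
  domains <- data.frame(protein = c("PAX3", "PAX3"), domain = c("paired domain", "homeodomain"),
                        start = c(1L, 220L), end = c(128L, 280L), stringsAsFactors = FALSE)
  expect_equal(domain_localization(list(gene = "PAX3", protein_change = "p.V114M"), domains),
               "paired domain")
  expect_equal(domain_localization(list(gene = "PAX3", protein_change = "p.G128A"), domains),
               "paired domain")
  expect_true(is.na(domain_localization(list(gene = "PAX3", protein_change = "p.A150V"), domains)))
  # overlapping intervals: first by (start, end, name)
  ov <- data.frame(protein = "G", domain = c("b", "a"), start = c(1L, 1L), end = c(10L, 10L))
  expect_equal(domain_localization(list(gene = "G", protein_change = "p.A5V"), ov), "a")
  # brute-force interval oracle
  set.seed(25)
  iv <- data.frame(protein = "G", domain = sprintf("d%d", 1:8),
                   start = sample(1:50, 8), stringsAsFactors = FALSE)
  iv$end <- iv$start + sample(0:20, 8)
  for (pos in sample(1:70, 15)) {
    got <- domain_localization(list(gene = "G", protein_change = sprintf("p.A%dV", pos)), iv)
    hits <- iv[iv$start <= pos & pos <= iv$end, , drop = FALSE]
    if (nrow(hits) == 0L) expect_true(is.na(got)) else {
      hits <- hits[order(hits$start, hits$end, hits$domain), , drop = FALSE]
      expect_equal(got, hits$domain[1])
    }
  }
})

test_that("the staged report keeps non-increasing counts and flags each failure stage", {
  aln <- read_alignment(write_fasta(c(REF = "MARK", S2 = "MARK", S3 = "MARC")), "REF")
  domains <- data.frame(protein = "G", domain = "dom", start = 1L, end = 3L)
  v <- variant_df(sift = c(0.0005, 0.5, 0.0005, 0.0005, 0.0005),
                  pp2 = 0.998, mt = 1, cadd = 30, gerp = 5, gene = "G",
                  id = sprintf("v%d", 1:5),
                  pc = c("p.A2V", "p.A2V", "p.R3C", "p.K4E", "p.M1T"))
  # v1 final; v2 fails filter; v3 known; v4 not conserved (col 4 differs) and
  # outside the domain; v5 conserved in-domain but known? no - keep novel final
  res <- build_variant_report(v, known = "v3", alignments = list(G = aln),
                              domains = domains)
  r <- res$report
  expect_equal(r$variant_id[r$final_candidate], c("v1", "v5"))
  expect_false(r$final_candidate[r$variant_id == "v4"])
  expect_false(r$conserved[r$variant_id == "v4"])
  gc <- res$gene_counts
  expect_true(all(gc$n_filter_pass >= gc$n_novel & gc$n_novel >= gc$n_conserved &
                    gc$n_conserved >= gc$n_final))
  empty <- build_variant_report(v[0, , drop = FALSE])
  expect_equal(nrow(empty$report), 0L)
})
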