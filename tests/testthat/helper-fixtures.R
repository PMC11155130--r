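# Fixtures are built in code at test time; nothing is stored on disk.

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small, fast simulation configuration for tests that do not need the full
# default problem sizes.
small_sim_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 120L, n_decoy_partners = 12L,
               n_background_edges = 40L, n_background_variants = 10L,
               n_patients = 150L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# Build a cohort_table directly from per-column status vectors
# ("present"/"absent"/"unrecorded"), bypassing file IO.
make_cohort <- function(statuses, gene = NULL, sex = NULL, subtype = NULL,
                        variant_type = NULL, inheritance = NULL) {
  n <- length(statuses[[1]])
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   gene = if (is.null(gene)) rep("PAX3", n) else gene,
                   sex = if (is.null(sex)) rep("unrecorded", n) else sex,
                   stringsAsFactors = FALSE)
  if (!is.null(subtype)) df$subtype <- subtype
  if (!is.null(variant_type)) df$variant_type <- variant_type
  if (!is.null(inheritance)) df$inheritance <- inheritance
  for (ph in names(statuses)) df[[ph]] <- statuses[[ph]]
  structure(df, phenotypes = names(statuses),
            class = c("cohort_table", "data.frame"))
}

# Expand a 2xk present/absent table into per-patient status vectors.
statuses_from_counts <- function(present, absent, unrecorded = 0L) {
  c(rep("present", present), rep("absent", absent), rep("unrecorded", unrecorded))
}

# Independent enumeration oracle for the two-sided 2x2 Fisher test, written
# from the hypergeometric definition with choose() products.
fisher_2x2_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  po <- pr[a == m[1, 1]]
  min(1, sum(pr[pr <= po * (1 + 1e-12)]))
}

# Brute-force Freeman-Halton oracle for 2x3 tables: enumerate every table
# with the observed margins.
fisher_2x3_oracle <- function(m) {
  r1 <- sum(m[1, ]); cs <- colSums(m); n <- sum(m)
  probs <- c(); p_obs <- NA
  for (a1 in 0:min(r1, cs[1])) for (a2 in 0:min(r1 - a1, cs[2])) {
    a3 <- r1 - a1 - a2
    if (a3 < 0 || a3 > cs[3]) next
    p <- choose(cs[1], a1) * choose(cs[2], a2) * choose(cs[3], a3) / choose(n, r1)
    probs <- c(probs, p)
    if (a1 == m[1, 1] && a2 == m[1, 2]) p_obs <- p
  }
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
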