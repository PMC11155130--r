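# Seeded generators that emulate every pipeline input with retained ground
# truth: three PPI edge lists with planted consensus partners, a gene-to-
# phenotype annotation file with planted overlap counts, a variant bundle
# (scores, known list, protein alignments, domains) with planted survivors and
# per-stage decoys, and a patient cohort drawn from per-gene phenotype
# prevalences with controlled missingness.

# Independent child seed per generator stream: adding a generator never
# perturbs the others. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + k) %% 2147483647
}

ws_seed_genes <- c("PAX3", "MITF", "SOX10", "SNAI2", "EDNRB", "EDN3", "KITLG")

default_prevalence_matrix <- function() {
  phen <- c("hearing_impairment", "iris_pigmentary_abnormality", "telecanthus",
            "synophrys", "broad_nasal_root", "white_forelock",
            "hypopigmented_skin_patches", "skin_freckles",
            "premature_graying_of_hair", "aganglionic_megacolon",
            "constipation", "underdeveloped_nasal_alae", "wide_nasal_bridge")
  m <- rbind(
    PAX3  = c(0.78, 0.80, 0.85, 0.55, 0.60, 0.50, 0.35, 0.10, 0.20, 0.00, 0.02, 0.15, 0.20),
    MITF  = c(0.85, 0.62, 0.08, 0.40, 0.35, 0.30, 0.35, 0.71, 0.43, 0.00, 0.02, 0.00, 0.00),
    SOX10 = c(0.97, 0.82, 0.05, 0.10, 0.10, 0.22, 0.35, 0.10, 0.15, 0.36, 0.30, 0.00, 0.00),
    EDNRB = c(0.80, 0.70, 0.05, 0.10, 0.10, 0.25, 0.35, 0.10, 0.15, 0.30, 0.25, 0.00, 0.00),
    EDN3  = c(0.80, 0.70, 0.05, 0.10, 0.10, 0.25, 0.35, 0.10, 0.15, 0.30, 0.25, 0.00, 0.00),
    SNAI2 = c(0.85, 0.60, 0.05, 0.10, 0.10, 0.25, 0.35, 0.20, 0.20, 0.00, 0.02, 0.00, 0.00),
    KITLG = c(0.85, 0.60, 0.05, 0.10, 0.10, 0.25, 0.35, 0.20, 0.20, 0.00, 0.02, 0.00, 0.00))
  colnames(m) <- phen
  m
}

default_subtype_probs <- function() {
  rbind(
    PAX3  = c(WS1 = 0.78, WS2 = 0.10, WS3 = 0.035, WS4 = 0.005, unclassified = 0.08),
    MITF  = c(WS1 = 0.03, WS2 = 0.90, WS3 = 0.000, WS4 = 0.000, unclassified = 0.07),
    SOX10 = c(WS1 = 0.04, WS2 = 0.70, WS3 = 0.000, WS4 = 0.180, unclassified = 0.08),
    EDNRB = c(WS1 = 0.10, WS2 = 0.30, WS3 = 0.000, WS4 = 0.500, unclassified = 0.10),
    EDN3  = c(WS1 = 0.00, WS2 = 0.20, WS3 = 0.000, WS4 = 0.700, unclassified = 0.10),
    SNAI2 = c(WS1 = 0.00, WS2 = 0.90, WS3 = 0.000, WS4 = 0.000, unclassified = 0.10),
    KITLG = c(WS1 = 0.00, WS2 = 0.90, WS3 = 0.000, WS4 = 0.000, unclassified = 0.10))
}

default_variant_type_probs <- function() {
  types <- c("nonsense", "frameshift", "missense", "splicing",
             "gross deletion", "in-frame deletion", "other")
  m <- rbind(
    PAX3  = c(0.15, 0.25, 0.35, 0.10, 0.0698, 0.05, 0.0302),
    MITF  = c(0.45, 0.20, 0.15, 0.08, 0.0190, 0.07, 0.0310),
    SOX10 = c(0.15, 0.30, 0.25, 0.10, 0.1000, 0.05, 0.0500),
    EDNRB = c(0.10, 0.25, 0.40, 0.10, 0.0500, 0.05, 0.0500),
    EDN3  = c(0.10, 0.25, 0.40, 0.10, 0.0500, 0.05, 0.0500),
    SNAI2 = c(0.10, 0.25, 0.40, 0.10, 0.0500, 0.05, 0.0500),
    KITLG = c(0.10, 0.25, 0.40, 0.10, 0.0500, 0.05, 0.0500))
  colnames(m) <- types
  m / rowSums(m)
}

#' Configuration for the synthetic-data generators
#'
#' One integer master seed drives independent child streams per generator.
#' Defaults reflect the study conditions the pipeline targets: 7 seed genes,
#' a pooled disease phenotype set of 70 terms over 4707 annotated genes,
#' planted candidate genes SIN3A/EP300/CHD7/KIT sharing 17/16/15/15 terms,
#' and a 443-patient cohort with gene mixture 138/161/124/13/4/2/1 and ~8%
#' per-cell phenotype missingness.
#'
#' @param seed Integer master seed.
#' @param seeds Seed (known causative) gene symbols.
#' @param planted_consensus_genes Genes planted as consensus interaction
#'   partners in every generated PPI source.
#' @param planted_n_overlap Named integer vector: planted shared-phenotype
#'   count (N_g) per planted gene; every value must be `<= n_ws`.
#' @param n_ws Size of the pooled disease phenotype set.
#' @param n_genes Total number of annotated genes (seeds and planted genes
#'   included).
#' @param bg_overlap_prob Per-term probability with which a background gene's
#'   annotation overlaps the disease set.
#' @param n_ppi_sources Number of PPI sources to generate.
#' @param n_decoy_partners Decoy partner genes appearing in only 1 or 2
#'   sources.
#' @param extra_partner_rate Per-source inclusion probability for each decoy.
#' @param n_background_edges Random non-seed edges added per source.
#' @param variant_genes Genes for which variant bundles are generated.
#' @param n_planted_final Named integer vector: planted final candidate
#'   variants per gene.
#' @param n_planted_known Named integer vector: planted filter-passing but
#'   already-known variants per gene.
#' @param n_background_variants Background variants per gene with independent
#'   per-score pass probabilities.
#' @param score_pass_prob Probability each of the five scores passes its
#'   cutoff for a background variant.
#' @param score_missing_rate Probability a background score cell is missing.
#' @param n_patients Cohort size.
#' @param gene_mixture Named numeric vector of gene proportions (sums to 1).
#' @param prevalence Genes x phenotypes matrix of per-gene phenotype
#'   prevalences.
#' @param missingness Per-cell probability a phenotype status is unrecorded.
#' @param p_male Probability of male sex among recorded.
#' @param sex_unrecorded_rate Probability sex is unrecorded.
#' @param de_novo_rate Named numeric vector: per-gene probability of de novo
#'   inheritance among recorded.
#' @param inheritance_unrecorded_rate Probability inheritance is unrecorded.
#' @param subtype_probs Genes x subtypes probability matrix.
#' @param variant_type_probs Genes x variant-type probability matrix.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              seeds = ws_seed_genes,
                              planted_consensus_genes = c("SIN3A", "EP300", "CHD7", "KIT"),
                              planted_n_overlap = c(SIN3A = 17L, EP300 = 16L,
                                                    CHD7 = 15L, KIT = 15L),
                              n_ws = 70L, n_genes = 4707L, bg_overlap_prob = 0.05,
                              n_ppi_sources = 3L, n_decoy_partners = 60L,
                              extra_partner_rate = 0.5, n_background_edges = 200L,
                              variant_genes = c("PAX3", "MITF", "SOX10"),
                              n_planted_final = c(PAX3 = 20L, MITF = 7L, SOX10 = 5L),
                              n_planted_known = c(PAX3 = 8L, MITF = 4L, SOX10 = 4L),
                              n_background_variants = 40L, score_pass_prob = 0.3,
                              score_missing_rate = 0,
                              n_patients = 443L,
                              gene_mixture = c(PAX3 = 138, MITF = 161, SOX10 = 124,
                                               EDNRB = 13, EDN3 = 4, SNAI2 = 2,
                                               KITLG = 1) / 443,
                              prevalence = default_prevalence_matrix(),
                              missingness = 0.08, p_male = 0.5,
                              sex_unrecorded_rate = 0.27,
                              de_novo_rate = c(PAX3 = 0.15, MITF = 0.25, SOX10 = 0.617,
                                               EDNRB = 0.3, EDN3 = 0.3, SNAI2 = 0.3,
                                               KITLG = 0.3),
                              inheritance_unrecorded_rate = 0.2,
                              subtype_probs = default_subtype_probs(),
                              variant_type_probs = default_variant_type_probs()) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  probs <- c(bg_overlap_prob, extra_partner_rate, score_pass_prob,
             score_missing_rate, missingness, p_male, sex_unrecorded_rate,
             inheritance_unrecorded_rate, de_novo_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(gene_mixture) - 1) > 1e-9) stop("gene_mixture proportions must sum to 1")
  if (any(planted_n_overlap > n_ws)) stop("planted N_g targets must not exceed n_ws")
  if (n_ppi_sources < 2L) stop("need at least 2 PPI sources")
  structure(list(seed = as.integer(seed), seeds = normalize_gene_symbols(seeds),
                 planted_consensus_genes = normalize_gene_symbols(planted_consensus_genes),
                 planted_n_overlap = planted_n_overlap, n_ws = as.integer(n_ws),
                 n_genes = as.integer(n_genes), bg_overlap_prob = bg_overlap_prob,
                 n_ppi_sources = as.integer(n_ppi_sources),
                 n_decoy_partners = as.integer(n_decoy_partners),
                 extra_partner_rate = extra_partner_rate,
                 n_background_edges = as.integer(n_background_edges),
                 variant_genes = normalize_gene_symbols(variant_genes),
                 n_planted_final = n_planted_final, n_planted_known = n_planted_known,
                 n_background_variants = as.integer(n_background_variants),
                 score_pass_prob = score_pass_prob,
                 score_missing_rate = score_missing_rate,
                 n_patients = as.integer(n_patients), gene_mixture = gene_mixture,
                 prevalence = prevalence, missingness = missingness,
                 p_male = p_male, sex_unrecorded_rate = sex_unrecorded_rate,
                 de_novo_rate = de_novo_rate,
                 inheritance_unrecorded_rate = inheritance_unrecorded_rate,
                 subtype_probs = subtype_probs,
                 variant_type_probs = variant_type_probs),
            class = "simulation_config")
}

bg_gene_names <- function(n) sprintf("BGGENE%04d", seq_len(n))

#' Generate PPI edge lists with planted consensus partners
#'
#' Writes one edge-list TSV per source. Every planted consensus gene is
#' adjacent to at least one seed in every source; each decoy partner appears
#' in only 1 or 2 sources, so the full-intersection consensus recovers exactly
#' the planted set. Background edges never touch the seeds.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Ground truth list: `files`, `planted`, `partner_sets` (per-source
#'   seed-partner sets).
#' @export
generate_ppi_trio <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(child_seed(config$seed, 101L))
  k <- config$n_ppi_sources
  decoys <- sprintf("DECOY%03d", seq_len(config$n_decoy_partners))
  membership <- matrix(stats::runif(config$n_decoy_partners * k) < config$extra_partner_rate,
                       ncol = k)
  all_in <- rowSums(membership) == k
  for (i in which(all_in)) membership[i, sample.int(k, 1L)] <- FALSE
  bg <- bg_gene_names(500L)
  files <- character(k)
  partner_sets <- vector("list", k)
  for (s in seq_len(k)) {
    planted_edges <- data.frame(a = sample(config$seeds, length(config$planted_consensus_genes),
                                           replace = TRUE),
                                b = config$planted_consensus_genes)
    in_s <- decoys[membership[, s]]
    decoy_edges <- if (length(in_s)) {
      data.frame(a = sample(config$seeds, length(in_s), replace = TRUE), b = in_s)
    } else data.frame(a = character(0), b = character(0))
    bg_edges <- data.frame(a = sample(bg, config$n_background_edges, replace = TRUE),
                           b = sample(bg, config$n_background_edges, replace = TRUE))
    bg_edges <- bg_edges[bg_edges$a != bg_edges$b, , drop = FALSE]
    edges <- rbind(planted_edges, decoy_edges, bg_edges)
    edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
    files[s] <- file.path(out_dir, sprintf("ppi_source_%d.tsv", s))
    con <- file(files[s], open = "wb")
    writeLines(c("gene_a\tgene_b", paste(edges$a, edges$b, sep = "\t")), con, sep = "\n")
    close(con)
    partner_sets[[s]] <- sort_c(c(config$planted_consensus_genes, in_s))
  }
  list(files = files, planted = sort_c(config$planted_consensus_genes),
       partner_sets = partner_sets)
}

#' Generate a gene-to-phenotype annotation file
#'
#' The seed genes' term sets union to a disease phenotype set of exactly
#' `n_ws` terms; every planted gene receives exactly its target overlap N_g
#' plus off-target terms; background genes overlap the disease set
#' binomially.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Ground truth list: `file`, `p_ws` (the disease term set),
#'   `planted_n_overlap`.
#' @export
generate_phenotype_annotations <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(child_seed(config$seed, 202L))
  p_ws <- sprintf("HP:%07d", seq_len(config$n_ws))
  off_target <- sprintf("HP:%07d", 1000000L + seq_len(2000L))
  rows <- list()
  # Each disease term annotated to 1-3 seeds. The disease set is by
  # definition the union of the seeds' annotations, so seeds carry only
  # disease-set terms: their union is exactly the n_ws configured terms.
  owner <- lapply(p_ws, function(t) sample(config$seeds, sample.int(3L, 1L)))
  for (i in seq_along(config$seeds)) {
    terms <- p_ws[vapply(owner, function(o) config$seeds[i] %in% o, TRUE)]
    if (length(terms) == 0L) terms <- sample(p_ws, 1L)
    rows[[length(rows) + 1L]] <- data.frame(gene = config$seeds[i], term = terms)
  }
  for (g in names(config$planted_n_overlap)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, term = c(sample(p_ws, config$planted_n_overlap[[g]]),
                         sample(off_target, 10L)))
  }
  n_bg <- config$n_genes - length(config$seeds) - length(config$planted_n_overlap)
  if (n_bg > 0L) {
    bg <- bg_gene_names(n_bg)
    n_in <- stats::rbinom(n_bg, config$n_ws, config$bg_overlap_prob)
    n_out <- stats::rpois(n_bg, 5) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rep(bg, n_in + n_out),
      term = unlist(lapply(seq_len(n_bg), function(i)
        c(if (n_in[i] > 0L) sample(p_ws, n_in[i]) else character(0),
          sample(off_target, n_out[i])))))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  path <- file.path(out_dir, "gene_phenotypes.tsv")
  con <- file(path, open = "wb")
  writeLines(c("gene\thpo_term_id", paste(tab$gene, tab$term, sep = "\t")), con, sep = "\n")
  close(con)
  list(file = path, p_ws = p_ws, planted_n_overlap = config$planted_n_overlap)
}

# Draw one score vector column-wise: each score passes its cutoff with the
# given probability (values uniform within the pass/fail region), or is
# missing with `missing_rate`.
simulate_scores <- function(n, pass_prob, missing_rate = 0) {
  draw <- function(pass_lo, pass_hi, fail_lo, fail_hi) {
    pass <- stats::runif(n) < pass_prob
    val <- ifelse(pass, stats::runif(n, pass_lo, pass_hi),
                  stats::runif(n, fail_lo, fail_hi))
    val[stats::runif(n) < missing_rate] <- NA_real_
    val
  }
  mt_pass <- stats::runif(n) < pass_prob
  mt <- ifelse(mt_pass, 1, stats::runif(n, 0, 0.999))
  mt[stats::runif(n) < missing_rate] <- NA_real_
  data.frame(sift = draw(0, 0.001, 0.0011, 1),
             polyphen2_hvar = draw(0.9571, 1, 0, 0.957),
             mutationtaster = mt,
             cadd_phred = draw(25.1, 60, 0, 25),
             gerp_rs = draw(4.1, 6, -5, 4))
}

all_pass_scores <- function(n) {
  data.frame(sift = stats::runif(n, 0, 0.001),
             polyphen2_hvar = stats::runif(n, 0.9571, 1),
             mutationtaster = rep(1, n),
             cadd_phred = stats::runif(n, 25.1, 60),
             gerp_rs = stats::runif(n, 4.1, 6))
}

synthetic_domains <- function() {
  data.frame(protein = c("PAX3", "PAX3", "PAX3", "MITF", "MITF",
                         "SOX10", "SOX10", "SOX10", "SOX10"),
             domain = c("paired domain", "homeodomain", "transactivation domain",
                        "transactivation domain", "b-HLH-Zip",
                        "dimerization domain", "HMG", "K2 domain",
                        "transactivation domain"),
             start = c(1L, 220L, 330L, 115L, 198L, 61L, 102L, 233L, 400L),
             end = c(128L, 280L, 479L, 180L, 290L, 101L, 180L, 306L, 466L),
             stringsAsFactors = FALSE)
}

protein_lengths <- c(PAX3 = 479L, MITF = 520L, SOX10 = 466L)

msa_species <- c("Homo_sapiens", "Macaca_mulatta", "Pan_troglodytes",
                 "Mus_musculus", "Equus_caballus", "Sus_scrofa",
                 "Canis_lupus_familiaris")

#' Generate a variant bundle with planted survivors and per-stage decoys
#'
#' Writes, per gene: an ANNOVAR-style variant table, a known-pathogenic ID
#' list, a 7-species protein alignment FASTA, and a shared domain TSV. Planted
#' final variants pass all five score cutoffs, are absent from the known list,
#' sit at fully conserved alignment columns, and fall inside a domain. Decoys
#' fail exactly one stage each: one score-failing, one known, one at a
#' non-conserved column, one outside every domain. Background variants draw
#' each score independently with `score_pass_prob`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Ground truth list: file paths, planted final variant IDs per gene,
#'   decoy IDs annotated with their designed failure stage.
#' @export
generate_variant_table <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(child_seed(config$seed, 303L))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  domains <- synthetic_domains()
  variants <- list(); known_ids <- character(0)
  planted_final <- list(); decoy_stage <- list()
  msa_files <- character(0)
  next_rs <- 900000001L
  new_ids <- function(n) {
    ids <- sprintf("rs%d", next_rs + seq_len(n) - 1L)
    next_rs <<- next_rs + n
    ids
  }
  for (g in config$variant_genes) {
    L <- protein_lengths[[g]]
    ref <- sample(aa, L, replace = TRUE)
    # ~70% of columns fully conserved; the rest mutated in 1-3 non-human rows.
    conserved_col <- stats::runif(L) < 0.7
    rows <- matrix(rep(ref, length(msa_species)), nrow = length(msa_species), byrow = TRUE)
    for (p in which(!conserved_col)) {
      for (r in sample(seq(2L, length(msa_species)), sample.int(3L, 1L))) {
        rows[r, p] <- sample(setdiff(aa, ref[p]), 1L)
      }
    }
    dom_g <- domains[domains$protein == g, , drop = FALSE]
    in_dom <- rep(FALSE, L)
    for (i in seq_len(nrow(dom_g))) in_dom[dom_g$start[i]:dom_g$end[i]] <- TRUE
    pick_pos <- function(n, want_dom, want_cons) {
      pool <- which(in_dom == want_dom & conserved_col == want_cons)
      if (length(pool) < n) stop("not enough eligible positions to plant variants")
      pool[sample.int(length(pool), n)]
    }
    sub_at <- function(pos) {
      alt <- vapply(pos, function(p) sample(setdiff(aa, ref[p]), 1L), "")
      sprintf("p.%s%d%s", ref[pos], pos, alt)
    }
    n_fin <- config$n_planted_final[[g]]; n_kn <- config$n_planted_known[[g]]
    fin_ids <- new_ids(n_fin); kn_ids <- new_ids(n_kn)
    dec_ids <- new_ids(3L)
    gene_rows <- rbind(
      if (n_fin > 0L) data.frame(gene = g, variant_id = fin_ids,
                 protein_change = sub_at(pick_pos(n_fin, TRUE, TRUE)),
                 all_pass_scores(n_fin), role = "planted_final"),
      if (n_kn > 0L) data.frame(gene = g, variant_id = kn_ids,
                 protein_change = sub_at(pick_pos(n_kn, TRUE, TRUE)),
                 all_pass_scores(n_kn), role = "decoy_known"),
      # Decoy failing only the score filter (single failing score).
      data.frame(gene = g, variant_id = dec_ids[1],
                 protein_change = sub_at(pick_pos(1L, TRUE, TRUE)),
                 within(all_pass_scores(1L), sift <- 0.5), role = "decoy_filter"),
      # Decoy failing only conservation.
      data.frame(gene = g, variant_id = dec_ids[2],
                 protein_change = sub_at(pick_pos(1L, TRUE, FALSE)),
                 all_pass_scores(1L), role = "decoy_conservation"),
      # Decoy failing only domain localization.
      data.frame(gene = g, variant_id = dec_ids[3],
                 protein_change = sub_at(pick_pos(1L, FALSE, TRUE)),
                 all_pass_scores(1L), role = "decoy_domain"),
      if (config$n_background_variants > 0L) {
        n_bg <- config$n_background_variants
        data.frame(gene = g, variant_id = new_ids(n_bg),
                   protein_change = sub_at(sample.int(L, n_bg, replace = TRUE)),
                   simulate_scores(n_bg, config$score_pass_prob, config$score_missing_rate),
                   role = "background")
      })
    variants[[g]] <- gene_rows
    known_ids <- c(known_ids, kn_ids)
    planted_final[[g]] <- fin_ids
    decoy_stage[[g]] <- data.frame(variant_id = dec_ids,
                                   stage = c("filter", "conservation", "domain"),
                                   stringsAsFactors = FALSE)
    msa_path <- file.path(out_dir, sprintf("msa_%s.fasta", g))
    con <- file(msa_path, open = "wb")
    for (r in seq_along(msa_species)) {
      writeLines(c(paste0(">", msa_species[r]), paste(rows[r, ], collapse = "")),
                 con, sep = "\n")
    }
    close(con)
    msa_files[g] <- msa_path
  }
  tab <- do.call(rbind, variants)
  roles <- tab$role
  tab$role <- NULL
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 6, format = "g"))
  var_path <- file.path(out_dir, "variants.tsv")
  con <- file(var_path, open = "wb")
  writeLines(c(paste(c("Gene.refGene", "avsnp147", "AAChange", "SIFT_score",
                       "Polyphen2_HVAR_score", "MutationTaster_score",
                       "CADD_phred", "GERP++_RS"), collapse = "\t"),
               paste(tab$gene, tab$variant_id, tab$protein_change, fmt(tab$sift),
                     fmt(tab$polyphen2_hvar), fmt(tab$mutationtaster),
                     fmt(tab$cadd_phred), fmt(tab$gerp_rs), sep = "\t")),
             con, sep = "\n")
  close(con)
  known_path <- file.path(out_dir, "known_variants.tsv")
  con <- file(known_path, open = "wb")
  writeLines(c("variant_id", known_ids), con, sep = "\n")
  close(con)
  dom_path <- file.path(out_dir, "domains.tsv")
  con <- file(dom_path, open = "wb")
  writeLines(c("protein\tdomain\tstart\tend",
               paste(domains$protein, domains$domain, domains$start, domains$end,
                     sep = "\t")), con, sep = "\n")
  close(con)
  list(variants_file = var_path, known_file = known_path, domains_file = dom_path,
       msa_files = msa_files, planted_final = planted_final,
       decoy_stage = decoy_stage, n_variants = nrow(tab), roles = table(roles))
}

#' Simulate a patient cohort in memory
#'
#' Each patient draws a gene from the mixture, each phenotype independently as
#' Bernoulli with the gene's prevalence, then each phenotype cell is masked
#' unrecorded with the missingness rate. Sex, inheritance, subtype, and
#' variant type are drawn per configuration.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed override for this stream (defaults to the
#'   config's cohort child stream).
#' @return A `cohort_table`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(if (is.null(seed)) child_seed(config$seed, 404L) else seed)
  n <- config$n_patients
  genes <- sample(names(config$gene_mixture), n, replace = TRUE,
                  prob = config$gene_mixture)
  phen <- colnames(config$prevalence)
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       family_id = sprintf("FAM%04d", sample.int(max(1L, n %/% 2L), n, replace = TRUE)),
                       country = sample(c("China", "France", "Japan", "USA", "Brazil",
                                          "India", "Germany"), n, replace = TRUE),
                       sex = ifelse(stats::runif(n) < config$sex_unrecorded_rate, "unrecorded",
                                    ifelse(stats::runif(n) < config$p_male, "male", "female")),
                       age = sample.int(60L, n, replace = TRUE),
                       gene = genes, stringsAsFactors = FALSE)
  cohort$subtype <- vapply(genes, function(g)
    sample(colnames(config$subtype_probs), 1L, prob = config$subtype_probs[g, ]), "")
  cohort$variant <- sprintf("c.%d%s>%s", sample.int(2000L, n, replace = TRUE),
                            sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            sample(c("A", "C", "G", "T"), n, replace = TRUE))
  cohort$variant_type <- vapply(genes, function(g)
    sample(colnames(config$variant_type_probs), 1L, prob = config$variant_type_probs[g, ]), "")
  cohort$inheritance <- ifelse(stats::runif(n) < config$inheritance_unrecorded_rate,
                               "unrecorded",
                               ifelse(stats::runif(n) < config$de_novo_rate[genes],
                                      "de novo", "familial"))
  for (ph in phen) {
    present <- stats::runif(n) < config$prevalence[genes, ph]
    status <- ifelse(present, "present", "absent")
    status[stats::runif(n) < config$missingness] <- "unrecorded"
    cohort[[ph]] <- status
  }
  structure(cohort, phenotypes = phen, class = c("cohort_table", "data.frame"))
}

#' Generate a cohort TSV with ground truth
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Ground truth list: `file`, `phenotypes`, `true_prevalence`,
#'   `gene_mixture`, `missingness`.
#' @export
generate_cohort <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  path <- file.path(out_dir, "cohort.tsv")
  write_cohort_table(cohort, path)
  list(file = path, phenotypes = attr(cohort, "phenotypes"),
       true_prevalence = config$prevalence, gene_mixture = config$gene_mixture,
       missingness = config$missingness)
}

#' Generate every pipeline input from one configuration
#'
#' Runs all four generators into one directory and writes the combined ground
#' truth as `ground_truth.json`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the combined ground-truth list (`ppi`, `phenotypes`,
#'   `variants`, `cohort`, `seeds_file`).
#' @export
generate_all <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- list(ppi = generate_ppi_trio(config, out_dir),
             phenotypes = generate_phenotype_annotations(config, out_dir),
             variants = generate_variant_table(config, out_dir),
             cohort = generate_cohort(config, out_dir))
  seeds_path <- file.path(out_dir, "seed_genes.tsv")
  con <- file(seeds_path, open = "wb")
  writeLines(config$seeds, con, sep = "\n")
  close(con)
  gt$seeds_file <- seeds_path
  gt_out <- gt
  gt_out$variants$roles <- as.list(gt_out$variants$roles)
  jsonlite::write_json(gt_out, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(gt)
}
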