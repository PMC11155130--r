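#' Consensus deleteriousness filter thresholds
#'
#' The five predictor cutoffs a variant must satisfy simultaneously:
#' SIFT <= `sift_max`, PolyPhen2-HVAR > `polyphen2_hvar_min`, MutationTaster
#' score = `mutationtaster_eq` (within `mutationtaster_tol`; or, with
#' `mutationtaster_categorical = TRUE`, a categorical code in
#' `mutationtaster_codes`), CADD-phred > `cadd_phred_min`, and GERP++ RS >
#' `gerp_rs_min`. Boundary semantics are exactly as stated: non-strict for
#' SIFT, strict for the other four.
#'
#' @param sift_max Pass if SIFT score `<=` this value.
#' @param polyphen2_hvar_min Pass if PolyPhen2-HVAR score `>` this value.
#' @param mutationtaster_eq Pass if MutationTaster converted score equals this.
#' @param cadd_phred_min Pass if CADD-phred `>` this value.
#' @param gerp_rs_min Pass if GERP++ RS `>` this value.
#' @param mutationtaster_tol Numeric tolerance for the equality comparison.
#' @param mutationtaster_categorical If `TRUE`, the MutationTaster column is
#'   read as a categorical prediction code instead of a score.
#' @param mutationtaster_codes Accepted categorical codes (disease-causing).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(sift_max = 0.001, polyphen2_hvar_min = 0.957,
                              mutationtaster_eq = 1, cadd_phred_min = 25,
                              gerp_rs_min = 4, mutationtaster_tol = 1e-9,
                              mutationtaster_categorical = FALSE,
                              mutationtaster_codes = c("D", "A")) {
  structure(list(sift_max = sift_max, polyphen2_hvar_min = polyphen2_hvar_min,
                 mutationtaster_eq = mutationtaster_eq,
                 cadd_phred_min = cadd_phred_min, gerp_rs_min = gerp_rs_min,
                 mutationtaster_tol = mutationtaster_tol,
                 mutationtaster_categorical = mutationtaster_categorical,
                 mutationtaster_codes = mutationtaster_codes),
            class = "filter_thresholds")
}

# Per-score verdict matrix ("pass"/"fail"/"missing") for a variant data frame.
score_verdicts <- function(variants, thresholds) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(variants)
  verdict <- function(value, ok) {
    out <- rep("missing", n)
    present <- !is.na(value)
    out[present] <- ifelse(ok[present], "pass", "fail")
    out
  }
  if (thresholds$mutationtaster_categorical) {
    mt_raw <- toupper(trimws(as.character(variants$mutationtaster)))
    mt_raw[mt_raw %in% c("", ".", "NA")] <- NA_character_
    mt <- verdict(mt_raw, mt_raw %in% thresholds$mutationtaster_codes)
  } else {
    mt <- verdict(variants$mutationtaster,
                  abs(variants$mutationtaster - thresholds$mutationtaster_eq) <=
                    thresholds$mutationtaster_tol)
  }
  cbind(sift = verdict(variants$sift, variants$sift <= thresholds$sift_max),
        polyphen2_hvar = verdict(variants$polyphen2_hvar,
                                 variants$polyphen2_hvar > thresholds$polyphen2_hvar_min),
        mutationtaster = mt,
        cadd_phred = verdict(variants$cadd_phred, variants$cadd_phred > thresholds$cadd_phred_min),
        gerp_rs = verdict(variants$gerp_rs, variants$gerp_rs > thresholds$gerp_rs_min))
}

#' Five-score consensus deleteriousness decision
#'
#' Evaluates each predictor cutoff for one or more variants. A variant passes
#' overall only if all five verdicts are "pass"; a missing score yields a
#' "missing" verdict and the variant fails closed.
#'
#' @param variants Data frame of variants (one row each) as produced by
#'   [read_variant_table()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Data frame with `gene`, `variant_id`, the five per-score verdict
#'   columns (each `"pass"`/`"fail"`/`"missing"`), and logical `pass`.
#' @export
consensus_filter <- function(variants, thresholds = filter_thresholds()) {
  v <- score_verdicts(variants, thresholds)
  data.frame(gene = variants$gene, variant_id = variants$variant_id,
             as.data.frame(v, stringsAsFactors = FALSE),
             pass = rowSums(v == "pass") == 5L,
             stringsAsFactors = FALSE)
}

#' Apply the consensus filter to a variant table
#'
#' @inheritParams consensus_filter
#' @return List with `survivors` (passing rows of `variants`, input order
#'   preserved), `decisions` (the [consensus_filter()] output), and
#'   `gene_counts` (data frame of survivor counts per gene).
#' @export
filter_table <- function(variants, thresholds = filter_thresholds()) {
  decisions <- consensus_filter(variants, thresholds)
  survivors <- variants[decisions$pass, , drop = FALSE]
  rownames(survivors) <- NULL
  counts <- if (nrow(survivors)) {
    tab <- as.data.frame(table(gene = survivors$gene), stringsAsFactors = FALSE)
    names(tab) <- c("gene", "n_survivors")
    tab[order(tab$gene, method = "radix"), , drop = FALSE]
  } else {
    data.frame(gene = character(0), n_survivors = integer(0))
  }
  rownames(counts) <- NULL
  list(survivors = survivors, decisions = decisions, gene_counts = counts)
}

#' Partition survivors into known-pathogenic and novel
#'
#' Exact variant-ID match against a list of variants already reported
#' pathogenic (ClinVar/DVD-style). IDs are compared after whitespace trimming;
#' no other normalization is applied, so both sides must use the same ID
#' scheme.
#'
#' @param survivors Data frame of filter-passing variants.
#' @param known Character vector of known-pathogenic variant IDs.
#' @return List with `known` and `novel` subsets of `survivors`
#'   (`nrow(known) + nrow(novel) == nrow(survivors)`).
#' @export
crossref_known <- function(survivors, known) {
  known <- trimws(as.character(known))
  is_known <- trimws(survivors$variant_id) %in% known
  list(known = `rownames<-`(survivors[is_known, , drop = FALSE], NULL),
       novel = `rownames<-`(survivors[!is_known, , drop = FALSE], NULL))
}

# Map a 1-based ungapped reference position to its alignment column.
reference_column <- function(alignment, pos) {
  ref <- strsplit(alignment$sequences[[alignment$reference_id]], "", fixed = TRUE)[[1]]
  non_gap <- which(ref != "-")
  if (pos > length(non_gap)) {
    stop(sprintf("position %d beyond ungapped reference length %d", pos, length(non_gap)))
  }
  non_gap[pos]
}

#' Cross-species conservation of a variant position
#'
#' Maps the variant's 1-based protein position to the alignment column holding
#' the corresponding reference residue and judges conservation there: the
#' column must have no gap in any sequence and the modal residue must be
#' carried by at least `min_identity_fraction` of the sequences (default 1.0 =
#' strict identity across all rows). If the reference residue at that column
#' does not match the variant's stated reference amino acid, the check is not
#' evaluable and returns `NA` with a warning.
#'
#' @param variant One-row data frame (or list) with `gene` and
#'   `protein_change`.
#' @param alignment A `protein_alignment` whose reference is the variant's
#'   protein.
#' @param min_identity_fraction Minimum fraction of sequences sharing the
#'   modal residue; in `(0, 1]`.
#' @return `TRUE` (conserved), `FALSE` (not conserved), or `NA` (not
#'   evaluable).
#' @export
conservation_check <- function(variant, alignment, min_identity_fraction = 1.0) {
  stopifnot(inherits(alignment, "protein_alignment"),
            min_identity_fraction > 0, min_identity_fraction <= 1)
  pc <- parse_protein_change(variant$protein_change[1])
  if (is.na(pc$pos[1])) {
    warning(sprintf("protein change '%s' is not a simple substitution; conservation not evaluable",
                    variant$protein_change[1]))
    return(NA)
  }
  col <- reference_column(alignment, pc$pos[1])
  residues <- vapply(alignment$sequences, substr, "", col, col)
  if (residues[[alignment$reference_id]] != pc$ref[1]) {
    warning(sprintf("reference residue '%s' at position %d does not match variant reference '%s'; not evaluable",
                    residues[[alignment$reference_id]], pc$pos[1], pc$ref[1]))
    return(NA)
  }
  if (any(residues == "-")) return(FALSE)
  max(table(residues)) / length(residues) >= min_identity_fraction
}

#' Locate a variant within protein domains
#'
#' Returns the name of the first domain interval (ordered by start, end, then
#' name) that encloses the variant's protein position, with 1-based inclusive
#' bounds; `NA` if the position falls in no domain or the protein change is
#' not a simple substitution.
#'
#' @param variant One-row data frame (or list) with `gene` and
#'   `protein_change`.
#' @param domains Data frame from [read_domain_table()].
#' @return Domain name, or `NA_character_`.
#' @export
domain_localization <- function(variant, domains) {
  pc <- parse_protein_change(variant$protein_change[1])
  if (is.na(pc$pos[1])) return(NA_character_)
  gene <- normalize_gene_symbols(variant$gene[1])
  iv <- domains[domains$protein == gene, , drop = FALSE]
  iv <- iv[order(iv$start, iv$end, iv$domain, method = "radix"), , drop = FALSE]
  hit <- iv$start <= pc$pos[1] & pc$pos[1] <= iv$end
  if (any(hit)) iv$domain[which(hit)[1]] else NA_character_
}

#' Staged candidate-variant report
#'
#' Runs the full variant-nomination pipeline: five-score consensus filter,
#' cross-reference against known pathogenic variants, per-residue conservation
#' against the protein alignment, and domain localization. A variant is a
#' final candidate only if it passes the filter, is novel, is conserved, and
#' lies inside a domain.
#'
#' @param variants Variant table from [read_variant_table()].
#' @param thresholds A [filter_thresholds()] object.
#' @param known Character vector of known-pathogenic variant IDs.
#' @param alignments Named list of `protein_alignment` objects, one per gene
#'   (names are gene symbols). Genes without an alignment get conservation
#'   `NA`.
#' @param domains Data frame from [read_domain_table()].
#' @param min_identity_fraction Passed to [conservation_check()].
#' @return List with `report` (per-variant data frame: `gene`, `variant_id`,
#'   `protein_change`, `filter_pass`, `known_pathogenic`, `conserved`,
#'   `domain`, `final_candidate`) and `gene_counts` (per-gene counts at each
#'   stage).
#' @export
build_variant_report <- function(variants, thresholds = filter_thresholds(),
                                 known = character(0), alignments = list(),
                                 domains = NULL, min_identity_fraction = 1.0) {
  if (nrow(variants) == 0L) {
    empty <- data.frame(gene = character(0), variant_id = character(0),
                        protein_change = character(0), filter_pass = logical(0),
                        known_pathogenic = logical(0), conserved = logical(0),
                        domain = character(0), final_candidate = logical(0),
                        stringsAsFactors = FALSE)
    return(list(report = empty,
                gene_counts = data.frame(gene = character(0), n_filter_pass = integer(0),
                                         n_novel = integer(0), n_conserved = integer(0),
                                         n_final = integer(0), stringsAsFactors = FALSE)))
  }
  decisions <- consensus_filter(variants, thresholds)
  known <- trimws(as.character(known))
  rep_df <- data.frame(gene = variants$gene, variant_id = variants$variant_id,
                       protein_change = variants$protein_change,
                       filter_pass = decisions$pass,
                       known_pathogenic = trimws(variants$variant_id) %in% known,
                       conserved = NA, domain = NA_character_,
                       final_candidate = FALSE, stringsAsFactors = FALSE)
  names(alignments) <- normalize_gene_symbols(names(alignments))
  for (i in seq_len(nrow(rep_df))) {
    if (!rep_df$filter_pass[i] || rep_df$known_pathogenic[i]) next
    aln <- alignments[[normalize_gene_symbols(rep_df$gene[i])]]
    if (!is.null(aln)) {
      rep_df$conserved[i] <- conservation_check(variants[i, , drop = FALSE], aln,
                                                min_identity_fraction)
    }
    if (!is.null(domains)) {
      rep_df$domain[i] <- domain_localization(variants[i, , drop = FALSE], domains)
    }
  }
  rep_df$final_candidate <- rep_df$filter_pass & !rep_df$known_pathogenic &
    rep_df$conserved %in% TRUE & !is.na(rep_df$domain)
  genes <- sort_c(rep_df$gene)
  gene_counts <- data.frame(
    gene = genes,
    n_filter_pass = vapply(genes, function(g) sum(rep_df$filter_pass & rep_df$gene == g), 0L),
    n_novel = vapply(genes, function(g)
      sum(rep_df$filter_pass & !rep_df$known_pathogenic & rep_df$gene == g), 0L),
    n_conserved = vapply(genes, function(g)
      sum(rep_df$filter_pass & !rep_df$known_pathogenic & rep_df$conserved %in% TRUE &
            rep_df$gene == g), 0L),
    n_final = vapply(genes, function(g) sum(rep_df$final_candidate & rep_df$gene == g), 0L),
    stringsAsFactors = FALSE)
  rownames(gene_counts) <- NULL
  list(report = rep_df, gene_counts = gene_counts)
}
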