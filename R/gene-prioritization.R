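#' One-hop interaction partners of a set of seed genes
#'
#' Returns every gene adjacent to at least one seed in the network, excluding
#' the seeds themselves. Only direct (one-hop) neighbors count; no path
#' expansion is performed. Seeds absent from the network simply contribute
#' nothing.
#'
#' @param seeds Character vector of seed gene symbols (normalized internally).
#' @param network A `ppi_network` from [read_edge_list()].
#' @return Sorted character vector of partner genes.
#' @export
direct_partners <- function(seeds, network) {
  stopifnot(inherits(network, "ppi_network"))
  seeds <- normalize_gene_symbols(seeds)
  if (length(seeds) == 0L) stop("seeds must be nonempty")
  e <- network$edges
  hit_a <- e$gene_a %in% seeds
  hit_b <- e$gene_b %in% seeds
  partners <- c(e$gene_b[hit_a], e$gene_a[hit_b])
  sort_c(setdiff(partners, seeds))
}

#' Consensus partners across interaction sources
#'
#' Exact intersection of two or more partner sets, one per PPI source. Using
#' only partners supported by every source trades recall for precision.
#'
#' @param partner_sets List of at least two character vectors.
#' @return Sorted character vector of genes present in every set.
#' @export
consensus_partners <- function(partner_sets) {
  if (!is.list(partner_sets) || length(partner_sets) < 2L) {
    stop("consensus requires at least 2 partner sets")
  }
  sort_c(Reduce(intersect, partner_sets))
}

#' Pooled disease phenotype set of the seed genes
#'
#' Union of the phenotype term sets annotated to the seed genes — the disease
#' phenotype profile P_ws whose cardinality N_ws is the denominator of the
#' similarity weight. Seeds without annotation are skipped with a warning;
#' if no seed is annotated at all that is an error.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param annotations A `phenotype_annotation_map`.
#' @return A `phenotype_set`: list with sorted `terms` and `n` (= N_ws).
#' @export
ws_phenotype_union <- function(seeds, annotations) {
  seeds <- normalize_gene_symbols(seeds)
  sets <- gene_terms(annotations, seeds)
  missing <- seeds[lengths(sets) == 0L]
  if (length(missing) == length(seeds)) stop("none of the seed genes is annotated")
  if (length(missing)) {
    warning(sprintf("seed gene(s) without phenotype annotation skipped: %s",
                    paste(missing, collapse = ", ")))
  }
  terms <- sort_c(unlist(sets, use.names = FALSE))
  structure(list(terms = terms, n = length(terms)), class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("Phenotype set: %d terms\n", x$n))
  invisible(x)
}

#' Phenotype-similarity weight of one gene
#'
#' The weight is the fraction of the pooled disease phenotype set that the
#' gene's own annotation covers: W_g = N_g / N_ws, where N_g is the number of
#' terms shared between the gene's set P_g and the disease set P_ws. A gene
#' absent from the annotation map scores N_g = 0, W_g = 0.
#'
#' @param gene One gene symbol.
#' @param p_ws A `phenotype_set` from [ws_phenotype_union()].
#' @param annotations A `phenotype_annotation_map`.
#' @return List with `gene`, `n_overlap` (N_g), `weight` (W_g), and the sorted
#'   `shared_terms`.
#' @export
phenotype_weight <- function(gene, p_ws, annotations) {
  stopifnot(inherits(p_ws, "phenotype_set"), p_ws$n > 0L)
  gene <- normalize_gene_symbols(gene)
  shared <- intersect(gene_terms(annotations, gene)[[1]], p_ws$terms)
  list(gene = gene, n_overlap = length(shared),
       weight = length(shared) / p_ws$n, shared_terms = sort_c(shared))
}

#' Phenotype-similarity weights for many genes
#'
#' @inheritParams phenotype_weight
#' @param genes Character vector of gene symbols.
#' @return Data frame with columns `gene`, `n_overlap`, `weight`, and a list
#'   column `shared_terms`; rows in lexicographic gene order.
#' @export
phenotype_weights <- function(genes, p_ws, annotations) {
  genes <- sort_c(normalize_gene_symbols(genes))
  ws <- lapply(genes, phenotype_weight, p_ws = p_ws, annotations = annotations)
  data.frame(gene = vapply(ws, `[[`, "", "gene"),
             n_overlap = vapply(ws, `[[`, 0L, "n_overlap"),
             weight = vapply(ws, `[[`, 0, "weight"),
             shared_terms = I(lapply(ws, `[[`, "shared_terms")),
             stringsAsFactors = FALSE)
}

#' Select the phenotype-similarity gene set (set B)
#'
#' Genes whose weight is strictly greater than the threshold. The comparison
#' is strict: with N_ws = 70 and the default threshold 0.2, a gene needs at
#' least 15 shared phenotypes to enter; 14 shared terms (W_g = 0.2 exactly) is
#' excluded. Seed genes never enter set B.
#'
#' @param weights Data frame from [phenotype_weights()] (columns `gene`,
#'   `weight`).
#' @param threshold Weight cutoff in `[0, 1]`; default 0.2.
#' @param seeds Seed genes to exclude.
#' @return Sorted character vector of selected genes.
#' @export
select_set_B <- function(weights, threshold = 0.2, seeds = character(0)) {
  stopifnot(is.data.frame(weights), threshold >= 0, threshold <= 1)
  sel <- weights$gene[weights$weight > threshold]
  sort_c(setdiff(sel, normalize_gene_symbols(seeds)))
}

#' Intersect the interaction and phenotype-similarity gene sets
#'
#' The preliminary candidate genes are those supported by both lines of
#' evidence: consensus interaction partners of the seeds (set A) and
#' phenotype-similarity selection (set B).
#'
#' @param set_A Character vector (consensus interactors).
#' @param set_B Character vector (weight-selected genes).
#' @param seeds Seed genes, excluded from every reported set.
#' @return A `candidate_gene_sets`: list with `set_A`, `set_B`, `preliminary`
#'   (their intersection, sorted), `high_priority` (`NULL` until
#'   [evidence_filter()] is applied), and `seeds`.
#' @export
prioritize <- function(set_A, set_B, seeds = character(0)) {
  seeds <- normalize_gene_symbols(seeds)
  set_A <- sort_c(setdiff(normalize_gene_symbols(set_A), seeds))
  set_B <- sort_c(setdiff(normalize_gene_symbols(set_B), seeds))
  structure(list(set_A = set_A, set_B = set_B,
                 preliminary = sort_c(intersect(set_A, set_B)),
                 high_priority = NULL, seeds = seeds),
            class = "candidate_gene_sets")
}

#' @export
print.candidate_gene_sets <- function(x, ...) {
  cat(sprintf("Candidate gene sets: |A| = %d, |B| = %d, preliminary = %d%s\n",
              length(x$set_A), length(x$set_B), length(x$preliminary),
              if (is.null(x$high_priority)) "" else
                sprintf(", high-priority = %d", length(x$high_priority))))
  if (length(x$preliminary)) cat("  preliminary:", paste(x$preliminary, collapse = ", "), "\n")
  invisible(x)
}

#' Filter preliminary candidates by external evidence flags
#'
#' Keeps candidates for which every required boolean flag (e.g. "mutations
#' cause hearing impairment in mouse") is true in the evidence table. Genes
#' absent from the evidence table are excluded and logged. An empty
#' `required_flags` is the identity filter.
#'
#' @param preliminary Character vector of candidate genes.
#' @param evidence Data frame from [read_evidence_table()].
#' @param required_flags Character vector of flag column names that must all be
#'   `TRUE`.
#' @return Sorted character vector of genes passing the filter.
#' @export
evidence_filter <- function(preliminary, evidence, required_flags) {
  preliminary <- normalize_gene_symbols(preliminary)
  if (length(required_flags) == 0L) return(sort_c(preliminary))
  unknown <- setdiff(required_flags, names(evidence))
  if (length(unknown)) stop(sprintf("unknown evidence flag(s): %s", paste(unknown, collapse = ", ")))
  absent <- setdiff(preliminary, evidence$gene)
  if (length(absent)) {
    message(sprintf("evidence_filter: gene(s) absent from evidence table excluded: %s",
                    paste(sort_c(absent), collapse = ", ")))
  }
  idx <- match(preliminary, evidence$gene)
  keep <- !is.na(idx)
  for (fl in required_flags) keep <- keep & !is.na(idx) & evidence[[fl]][idx] %in% TRUE
  sort_c(preliminary[keep])
}

#' Shared phenotype terms between candidates and the disease set
#'
#' For each candidate gene, the number of phenotype terms it shares with the
#' pooled disease set and the sorted list of those terms; the attribute
#' `total_shared_terms` counts the distinct shared terms across all
#' candidates.
#'
#' @param candidates Character vector of candidate genes.
#' @param p_ws A `phenotype_set`.
#' @param annotations A `phenotype_annotation_map`.
#' @return Data frame (gene, `n_overlap`, list column `shared_terms`,
#'   `shared_terms_joined` for serialization) with attribute
#'   `total_shared_terms`.
#' @export
shared_phenotype_counts <- function(candidates, p_ws, annotations) {
  tab <- phenotype_weights(candidates, p_ws, annotations)
  tab$weight <- NULL
  tab$shared_terms_joined <- vapply(tab$shared_terms, paste, "", collapse = ",")
  attr(tab, "total_shared_terms") <- length(sort_c(unlist(tab$shared_terms, use.names = FALSE)))
  tab
}
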