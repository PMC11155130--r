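#' Build a pipeline run configuration
#'
#' A flat, human-editable configuration covering all three stages. Every CLI
#' flag has an equivalent field here. Stages can be toggled independently;
#' inputs of disabled stages are ignored.
#'
#' @param seeds_file Path to a file with one seed gene symbol per line.
#' @param ppi_files Character vector of PPI edge-list TSV paths (>= 2 for the
#'   prioritization stage).
#' @param gene_phenotype_file Gene-to-phenotype annotation TSV.
#' @param evidence_file Optional evidence-flag TSV.
#' @param required_flags Evidence flags that must all be true for
#'   high-priority candidates.
#' @param variants_file ANNOVAR-style variant TSV.
#' @param known_file Known-pathogenic variant ID list (TSV, `variant_id`
#'   column or one ID per line).
#' @param msa_files Named character vector of aligned FASTA paths; names are
#'   gene symbols.
#' @param msa_reference Reference sequence ID within each alignment.
#' @param domains_file Protein-domain interval TSV.
#' @param cohort_file Patient cohort TSV.
#' @param phenotype_columns Ternary phenotype columns of the cohort.
#' @param association_genes Gene strata for the association stage.
#' @param weight_threshold Similarity-weight cutoff for set B.
#' @param thresholds A [filter_thresholds()] object.
#' @param min_identity_fraction Conservation cutoff.
#' @param alpha Significance level for the phi-matrix mask.
#' @param stages Character subset of
#'   `c("prioritize", "filter_variants", "associate")`.
#' @param out_dir Output directory.
#' @param seed Seed for any stochastic utilities (recorded in the report).
#' @return A `run_config` list.
#' @export
run_config <- function(seeds_file = NULL, ppi_files = NULL,
                       gene_phenotype_file = NULL, evidence_file = NULL,
                       required_flags = character(0), variants_file = NULL,
                       known_file = NULL, msa_files = NULL, domains_file = NULL,
                       msa_reference = "Homo_sapiens",
                       cohort_file = NULL, phenotype_columns = NULL,
                       association_genes = c("PAX3", "MITF", "SOX10"),
                       weight_threshold = 0.2, thresholds = filter_thresholds(),
                       min_identity_fraction = 1.0, alpha = 0.05,
                       stages = c("prioritize", "filter_variants", "associate"),
                       out_dir = ".", seed = 1L) {
  stopifnot(weight_threshold >= 0, weight_threshold <= 1, alpha > 0, alpha < 1)
  # An empty stage list is a validation-only run.
  if (length(stages)) {
    stages <- match.arg(stages, c("prioritize", "filter_variants", "associate"),
                        several.ok = TRUE)
  } else {
    stages <- character(0)
  }
  structure(list(seeds_file = seeds_file, ppi_files = ppi_files,
                 gene_phenotype_file = gene_phenotype_file,
                 evidence_file = evidence_file, required_flags = required_flags,
                 variants_file = variants_file, known_file = known_file,
                 msa_files = msa_files, msa_reference = msa_reference,
                 domains_file = domains_file,
                 cohort_file = cohort_file, phenotype_columns = phenotype_columns,
                 association_genes = association_genes,
                 weight_threshold = weight_threshold, thresholds = thresholds,
                 min_identity_fraction = min_identity_fraction, alpha = alpha,
                 stages = stages, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments; `thresholds` may be a mapping of cutoff names.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(filter_thresholds, y$thresholds)
  if (!is.null(y$msa_files)) y$msa_files <- unlist(y$msa_files)
  do.call(run_config, y)
}

read_seed_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\t.*$", "", sub("\r$", "", lines)))
  normalize_gene_symbols(lines[lines != "" & tolower(lines) != "gene"])
}

read_known_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines[lines != "" & tolower(lines) != "variant_id"]
}

validate_run_config <- function(config) {
  need <- list()
  if ("prioritize" %in% config$stages) {
    need <- c(need, config$seeds_file, as.list(config$ppi_files), config$gene_phenotype_file,
              if (!is.null(config$evidence_file)) config$evidence_file)
    if (length(config$ppi_files) < 2L) stop("prioritization needs at least 2 PPI files")
  }
  if ("filter_variants" %in% config$stages) {
    need <- c(need, config$variants_file, config$known_file,
              as.list(config$msa_files), config$domains_file)
  }
  if ("associate" %in% config$stages) {
    need <- c(need, config$cohort_file)
    if (is.null(config$phenotype_columns)) stop("association stage needs phenotype_columns")
  }
  need <- unlist(need)
  if (is.null(need)) return(invisible(character(0)))
  absent <- need[!file.exists(need)]
  if (length(absent)) {
    stop(sprintf("missing input file(s) for enabled stage(s): %s",
                 paste(absent, collapse = ", ")))
  }
  invisible(need)
}

#' Run the full pipeline
#'
#' Validates every enabled stage's inputs up front (fail-fast: nothing is
#' computed or written if any input is missing), runs the stages in order
#' prioritize -> filter-variants -> associate, writes per-stage TSV outputs
#' and a combined JSON report. Outputs are staged in a temporary directory and
#' moved into place only on success, so a failed run never leaves partial
#' outputs.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (also written as `run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- file.path(config$out_dir, sprintf(".staging-%d", Sys.getpid()))
  dir.create(tmp, showWarnings = FALSE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  report <- list(package_version = as.character(utils::packageVersion("wsdecipher")),
                 seed = config$seed,
                 config = config[!vapply(config, is.null, TRUE) &
                                   names(config) != "thresholds"],
                 input_checksums = if (length(inputs))
                   as.list(tools::md5sum(unique(inputs))) else list(),
                 stages = list())

  if ("prioritize" %in% config$stages) {
    seeds <- read_seed_file(config$seeds_file)
    networks <- lapply(config$ppi_files, function(f) read_edge_list(f))
    partner_sets <- lapply(networks, direct_partners, seeds = seeds)
    set_A <- consensus_partners(partner_sets)
    annotations <- read_gene_phenotype_map(config$gene_phenotype_file)
    p_ws <- ws_phenotype_union(seeds, annotations)
    weights <- phenotype_weights(names(annotations$annotations), p_ws, annotations)
    set_B <- select_set_B(weights, config$weight_threshold, seeds)
    cand <- prioritize(set_A, set_B, seeds)
    if (!is.null(config$evidence_file) && length(config$required_flags)) {
      evidence <- read_evidence_table(config$evidence_file)
      cand$high_priority <- evidence_filter(cand$preliminary, evidence,
                                            config$required_flags)
    }
    shared <- shared_phenotype_counts(cand$preliminary, p_ws, annotations)
    write_report(data.frame(gene = cand$set_A), file.path(tmp, "set_A.tsv"))
    write_report(weights[weights$n_overlap > 0, c("gene", "n_overlap", "weight")],
                 file.path(tmp, "weights.tsv"))
    write_report(data.frame(gene = cand$set_B), file.path(tmp, "set_B.tsv"))
    write_report(data.frame(gene = cand$preliminary,
                            high_priority = if (is.null(cand$high_priority)) NA else
                              cand$preliminary %in% cand$high_priority),
                 file.path(tmp, "candidates.tsv"))
    write_report(shared[, c("gene", "n_overlap", "shared_terms_joined")],
                 file.path(tmp, "shared_phenotypes.tsv"))
    report$stages$prioritize <- list(
      n_seeds = length(seeds), n_ws = p_ws$n,
      partner_counts = lengths(partner_sets),
      n_set_A = length(cand$set_A), n_set_B = length(cand$set_B),
      preliminary = cand$preliminary, high_priority = cand$high_priority,
      total_shared_terms = attr(shared, "total_shared_terms"))
  }

  if ("filter_variants" %in% config$stages) {
    variants <- read_variant_table(config$variants_file)
    known <- read_known_file(config$known_file)
    alignments <- lapply(config$msa_files, function(f) NULL)
    for (g in names(config$msa_files)) {
      alignments[[g]] <- read_alignment(config$msa_files[[g]], config$msa_reference)
    }
    domains <- read_domain_table(config$domains_file)
    res <- build_variant_report(variants, config$thresholds, known, alignments,
                                domains, config$min_identity_fraction)
    decisions <- consensus_filter(variants, config$thresholds)
    write_report(decisions, file.path(tmp, "decisions.tsv"))
    write_report(res$report, file.path(tmp, "variant_report.tsv"))
    jsonlite::write_json(res$gene_counts, file.path(tmp, "variant_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    report$stages$filter_variants <- list(
      n_variants = nrow(variants),
      n_filter_pass = sum(res$report$filter_pass),
      n_final = sum(res$report$final_candidate),
      gene_counts = res$gene_counts)
  }

  if ("associate" %in% config$stages) {
    cohort <- read_cohort_table(config$cohort_file, config$phenotype_columns)
    genes <- normalize_gene_symbols(config$association_genes)
    sub <- cohort[cohort$gene %in% genes, , drop = FALSE]
    attr(sub, "phenotypes") <- attr(cohort, "phenotypes")
    class(sub) <- class(cohort)
    prev <- do.call(rbind, lapply(config$phenotype_columns, function(ph) {
      do.call(rbind, lapply(c(list(NULL), as.list(genes)), function(g) {
        p <- prevalence(sub, ph, gene = g)
        data.frame(phenotype = ph, stratum = p$stratum, n_present = p$n_present,
                   n_recorded = p$n_recorded, proportion = p$proportion,
                   stringsAsFactors = FALSE)
      }))
    }))
    tests <- lapply(config$phenotype_columns, function(ph)
      group_association_test(sub, ph, genes))
    group_df <- do.call(rbind, lapply(tests, function(t)
      data.frame(phenotype = t$phenotype, test_used = t$test_used, p = t$p_group,
                 stringsAsFactors = FALSE)))
    pairwise_df <- do.call(rbind, lapply(tests, function(t)
      cbind(phenotype = t$phenotype, t$pairwise)))
    phim <- phi_matrix(sub, config$phenotype_columns, config$alpha)
    sex_df <- tryCatch(sex_difference_tests(sub, config$phenotype_columns),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         NULL
                       })
    dist <- distribution_summaries(cohort)
    write_report(prev, file.path(tmp, "prevalence.tsv"))
    write_report(group_df, file.path(tmp, "group_tests.tsv"))
    write_report(pairwise_df, file.path(tmp, "pairwise_tests.tsv"))
    write_report(phim$pairs, file.path(tmp, "phi_matrix.tsv"))
    if (!is.null(sex_df)) write_report(sex_df, file.path(tmp, "sex_tests.tsv"))
    write_report(dist$gene_overall, file.path(tmp, "distributions.tsv"))
    report$stages$associate <- list(
      n_patients = nrow(cohort), n_analyzed = nrow(sub),
      n_phenotypes = length(config$phenotype_columns),
      n_significant_group = sum(group_df$p < config$alpha, na.rm = TRUE),
      n_significant_pairs = sum(phim$significant) / 2L)
  }

  # Move staged outputs into place only once everything has succeeded.
  for (f in list.files(tmp)) {
    file.copy(file.path(tmp, f), file.path(config$out_dir, f), overwrite = TRUE)
  }
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (wsdecipher %s): stages %s\n", x$package_version,
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
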