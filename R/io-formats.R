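#' Read a protein-protein interaction edge list
#'
#' Reads a two-column TSV of gene symbols (an optional header row is detected
#' and skipped) into an undirected interaction network: symbols are normalized,
#' self-loops dropped, and the edge set deduplicated so that (A,B) and (B,A)
#' count once.
#'
#' @param path Path to the edge-list TSV.
#' @param source_name Label for the interaction source (e.g. a database name).
#' @param alias Optional alias map passed to [normalize_gene_symbols()].
#' @return A `ppi_network`: list with `source_name`, `edges` (data frame with
#'   columns `gene_a`, `gene_b`, `gene_a < gene_b` lexicographically), `genes`,
#'   and `n_self_loops_dropped`.
#' @export
read_edge_list <- function(path, source_name = basename(path), alias = NULL) {
  parsed <- read_tsv_lines(path)
  rows <- parsed$fields
  if (length(rows) && looks_like_header(
        rows[[1]], c("gene", "gene_a", "gene_b", "gene1", "gene2", "symbol",
                     "protein", "protein_a", "protein_b", "interactor",
                     "interactor_a", "interactor_b", "source", "target"))) {
    rows <- rows[-1L]
    parsed$lineno <- parsed$lineno[-1L]
  }
  bad <- which(lengths(rows) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list row at line %d of '%s': expected 2 tab-separated columns, found %d",
                 parsed$lineno[bad[1]], path, length(rows[[bad[1]]])))
  }
  a <- normalize_gene_symbols(vapply(rows, `[[`, "", 1L), alias)
  b <- normalize_gene_symbols(vapply(rows, `[[`, "", 2L), alias)
  if (any(a == "" | b == "")) stop(sprintf("empty gene symbol at line %d of '%s'",
                                           parsed$lineno[which(a == "" | b == "")[1]], path))
  self <- a == b
  n_self <- sum(self)
  if (n_self) message(sprintf("read_edge_list: dropped %d self-loop(s) from '%s'", n_self, source_name))
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  edges <- unique(data.frame(gene_a = a2, gene_b = b2, stringsAsFactors = FALSE))
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(source_name = source_name, edges = edges,
                 genes = sort_c(c(edges$gene_a, edges$gene_b)),
                 n_self_loops_dropped = n_self),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network '%s': %d edges over %d genes (%d self-loop(s) dropped)\n",
              x$source_name, nrow(x$edges), length(x$genes), x$n_self_loops_dropped))
  invisible(x)
}

#' Read a gene-to-phenotype annotation table
#'
#' Reads a two-column TSV of (gene symbol, phenotype term ID) pairs, in the
#' dialect of HPO's `genes_to_phenotype` download. Duplicate pairs collapse;
#' genes end up mapped to their set of annotated terms.
#'
#' @param path Path to the TSV.
#' @param alias Optional alias map for gene symbols.
#' @return A `phenotype_annotation_map`: list with `annotations` (named list,
#'   gene -> sorted character vector of term IDs) and `vocabulary` (all term
#'   IDs seen).
#' @export
read_gene_phenotype_map <- function(path, alias = NULL) {
  parsed <- read_tsv_lines(path)
  rows <- parsed$fields
  if (length(rows) && looks_like_header(
        rows[[1]], c("gene", "gene_symbol", "symbol", "term", "term_id",
                     "hpo_id", "hpo_term_id", "phenotype"))) {
    rows <- rows[-1L]
    parsed$lineno <- parsed$lineno[-1L]
  }
  bad <- which(lengths(rows) < 2L)
  if (length(bad)) stop(sprintf("malformed gene-phenotype row at line %d of '%s': expected 2 columns",
                                parsed$lineno[bad[1]], path))
  gene <- normalize_gene_symbols(vapply(rows, `[[`, "", 1L), alias)
  term <- trimws(vapply(rows, `[[`, "", 2L))
  empty <- gene == "" | term == ""
  if (any(empty)) stop(sprintf("empty gene or term field at line %d of '%s'",
                               parsed$lineno[which(empty)[1]], path))
  ann <- lapply(split(term, gene), sort_c)
  ann <- ann[sort_c(names(ann))]
  structure(list(annotations = ann, vocabulary = sort_c(term)),
            class = "phenotype_annotation_map")
}

#' @export
print.phenotype_annotation_map <- function(x, ...) {
  cat(sprintf("Phenotype annotation map: %d genes, %d distinct terms\n",
              length(x$annotations), length(x$vocabulary)))
  invisible(x)
}

# Term sets for a vector of genes; genes without annotation give character(0).
gene_terms <- function(map, genes) {
  stopifnot(inherits(map, "phenotype_annotation_map"))
  out <- map$annotations[genes]
  out[vapply(out, is.null, TRUE)] <- list(character(0))
  names(out) <- genes
  out
}

# Canonical variant-table columns and the ANNOVAR-multianno spellings accepted
# for each. Matching is case-insensitive on the cleaned-up header.
variant_column_synonyms <- list(
  gene           = c("gene", "gene.refgene", "gene_refgene", "gene.symbol"),
  variant_id     = c("variant_id", "avsnp147", "avsnp150", "avsnp", "id", "snp_id"),
  protein_change = c("protein_change", "aachange", "aachange.refgene", "aa_change", "hgvs_p"),
  sift           = c("sift", "sift_score"),
  polyphen2_hvar = c("polyphen2_hvar", "polyphen2_hvar_score"),
  mutationtaster = c("mutationtaster", "mutationtaster_score", "mutationtaster_converted_rankscore"),
  cadd_phred     = c("cadd_phred", "cadd13_phred", "cadd_phred_score"),
  gerp_rs        = c("gerp_rs", "gerp++_rs", "gerp.._rs", "gerp_rs_score")
)

score_ranges <- list(sift = c(0, 1), polyphen2_hvar = c(0, 1), mutationtaster = c(0, 1),
                     cadd_phred = c(0, Inf), gerp_rs = c(-Inf, Inf))

#' Read an annotated variant table
#'
#' Reads an ANNOVAR-multianno-style TSV with named columns for gene, variant
#' ID, amino-acid change, and the five deleteriousness predictor scores (SIFT,
#' PolyPhen2-HVAR, MutationTaster, CADD-phred, GERP++ RS). `"."` or empty
#' cells denote missing scores; unparseable score cells become missing with a
#' warning giving the total count. Extra columns (e.g. population frequencies)
#' are carried through untouched.
#'
#' @param path Path to the TSV.
#' @param alias Optional gene-symbol alias map.
#' @return A data frame with canonical columns `gene`, `variant_id`,
#'   `protein_change`, `sift`, `polyphen2_hvar`, `mutationtaster`,
#'   `cadd_phred`, `gerp_rs`, followed by any extra input columns.
#' @export
read_variant_table <- function(path, alias = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, quote = "")
  hdr <- tolower(trimws(names(raw)))
  idx <- vapply(names(variant_column_synonyms), function(canon) {
    m <- which(hdr %in% variant_column_synonyms[[canon]])
    if (length(m)) m[1] else NA_integer_
  }, integer(1))
  missing_cols <- names(idx)[is.na(idx)]
  if (length(missing_cols)) {
    stop(sprintf("variant table '%s' is missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  out <- data.frame(gene = normalize_gene_symbols(raw[[idx[["gene"]]]], alias),
                    variant_id = trimws(raw[[idx[["variant_id"]]]]),
                    protein_change = trimws(raw[[idx[["protein_change"]]]]),
                    stringsAsFactors = FALSE)
  n_unparseable <- 0L
  for (sc in names(score_ranges)) {
    cell <- trimws(raw[[idx[[sc]]]])
    is_missing <- cell %in% c("", ".", "NA", "na")
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(val)
    n_unparseable <- n_unparseable + sum(bad)
    val[is_missing | bad] <- NA_real_
    rng <- score_ranges[[sc]]
    oob <- !is.na(val) & (val < rng[1] | val > rng[2])
    if (any(oob)) {
      stop(sprintf("variant table '%s': %s score out of range [%s, %s] at data row %d",
                   path, sc, rng[1], rng[2], which(oob)[1]))
    }
    out[[sc]] <- val
  }
  if (n_unparseable > 0L) {
    warning(sprintf("read_variant_table: %d unparseable score cell(s) treated as missing", n_unparseable))
  }
  extra <- setdiff(seq_along(raw), idx)
  for (j in extra) out[[names(raw)[j]]] <- raw[[j]]
  out
}

#' Parse a simple protein substitution
#'
#' Parses `p.<ref><pos><alt>` HGVS-style substitutions in either one-letter
#' (`p.R156C`) or three-letter (`p.Arg156Cys`) form. Anything else (frameshift,
#' splice notation, multi-residue changes) is passed through untyped as `NA`.
#'
#' @param x Character vector of protein-change strings.
#' @return Data frame with columns `ref`, `pos`, `alt` (one-letter codes;
#'   `NA` rows for strings that are not simple substitutions).
#' @export
parse_protein_change <- function(x) {
  aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
           Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
           Tyr = "Y", Val = "V", Ter = "*")
  x <- trimws(as.character(x))
  out <- data.frame(ref = NA_character_, pos = NA_integer_, alt = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  re3 <- "^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$"
  re1 <- "^p\\.([A-Z])([0-9]+)([A-Z*])$"
  m3 <- regmatches(x, regexec(re3, x))
  m1 <- regmatches(x, regexec(re1, x))
  for (i in seq_along(x)) {
    if (length(m3[[i]]) == 4L) {
      r <- unname(aa3[m3[[i]][2]]); a <- unname(aa3[m3[[i]][4]])
      if (!is.na(r) && !is.na(a)) {
        out$ref[i] <- r; out$alt[i] <- a; out$pos[i] <- as.integer(m3[[i]][3])
      }
    } else if (length(m1[[i]]) == 4L) {
      out$ref[i] <- m1[[i]][2]; out$alt[i] <- m1[[i]][4]
      out$pos[i] <- as.integer(m1[[i]][3])
    }
  }
  if (any(!is.na(out$pos) & out$pos < 1L)) stop("protein position must be >= 1")
  out
}

#' Read a patient cohort table
#'
#' Reads the curated cohort TSV: one row per patient with metadata columns and
#' one ternary column per phenotype. The ternary encoding is configurable; by
#' default `"1"` = present, `"0"` = absent, and `""`/`"NA"` = unrecorded. Any
#' other cell value in a phenotype column is a schema error, never silently
#' missing.
#'
#' @param path Path to the cohort TSV.
#' @param phenotype_columns Character vector naming the ternary phenotype
#'   columns.
#' @param coding List with elements `present`, `absent`, `unrecorded`, each a
#'   character vector of accepted codes.
#' @param gene_vocabulary Optional character vector; if given, every patient's
#'   gene must be drawn from it.
#' @return A `cohort_table`: data frame with the metadata columns plus the
#'   phenotype columns recoded to `"present"` / `"absent"` / `"unrecorded"`;
#'   attribute `phenotypes` names the phenotype columns.
#' @export
read_cohort_table <- function(path, phenotype_columns,
                              coding = list(present = "1", absent = "0",
                                            unrecorded = c("", "NA")),
                              gene_vocabulary = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, quote = "")
  if (!"patient_id" %in% names(raw)) stop("cohort table must have a 'patient_id' column")
  dup <- duplicated(raw$patient_id)
  if (any(dup)) stop(sprintf("duplicate patient_id '%s' in cohort table", raw$patient_id[which(dup)[1]]))
  absent_cols <- setdiff(phenotype_columns, names(raw))
  if (length(absent_cols)) stop(sprintf("cohort table is missing phenotype column(s): %s",
                                        paste(absent_cols, collapse = ", ")))
  if ("gene" %in% names(raw)) raw$gene <- normalize_gene_symbols(raw$gene)
  if (!is.null(gene_vocabulary) && "gene" %in% names(raw)) {
    unknown <- setdiff(raw$gene, normalize_gene_symbols(gene_vocabulary))
    if (length(unknown)) stop(sprintf("cohort gene(s) outside the declared vocabulary: %s",
                                      paste(sort_c(unknown), collapse = ", ")))
  }
  n_unrec <- integer(length(phenotype_columns))
  names(n_unrec) <- phenotype_columns
  for (ph in phenotype_columns) {
    cell <- trimws(raw[[ph]])
    code <- rep(NA_character_, length(cell))
    code[cell %in% coding$present] <- "present"
    code[cell %in% coding$absent] <- "absent"
    code[cell %in% coding$unrecorded] <- "unrecorded"
    if (anyNA(code)) {
      i <- which(is.na(code))[1]
      stop(sprintf("illegal ternary code '%s' at row %d, column '%s' of cohort table",
                   cell[i], i, ph))
    }
    n_unrec[[ph]] <- sum(code == "unrecorded")
    raw[[ph]] <- code
  }
  message(sprintf("read_cohort_table: %d patients; unrecorded cells per phenotype: %s",
                  nrow(raw), paste(sprintf("%s=%d", phenotype_columns, n_unrec), collapse = ", ")))
  structure(raw, phenotypes = phenotype_columns,
            class = c("cohort_table", "data.frame"))
}

#' Write a cohort table in the format [read_cohort_table()] accepts
#'
#' @param cohort A `cohort_table` (or data frame with a `phenotypes` attribute).
#' @param path Output TSV path.
#' @param coding Ternary coding to emit; defaults match the reader's default.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path,
                               coding = list(present = "1", absent = "0",
                                             unrecorded = "NA")) {
  phen <- attr(cohort, "phenotypes")
  out <- as.data.frame(cohort, stringsAsFactors = FALSE)
  for (ph in phen) {
    out[[ph]] <- c(present = coding$present[1], absent = coding$absent[1],
                   unrecorded = coding$unrecorded[1])[out[[ph]]]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read an aligned protein FASTA
#'
#' Reads a multiple sequence alignment in FASTA format (gap character `-`).
#' All sequences must have equal aligned length and the designated reference
#' must be present.
#'
#' @param path Path to the aligned FASTA.
#' @param reference_id Name of the reference sequence (typically the human
#'   protein the variant coordinates refer to).
#' @return A `protein_alignment`: list with `sequences` (named character
#'   vector of aligned sequences), `reference_id`, and `width`.
#' @export
read_alignment <- function(path, reference_id) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("alignment '%s' contains no sequences", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    stop(sprintf("ragged alignment in '%s': sequence lengths %s",
                 path, paste(sort(unique(w)), collapse = ", ")))
  }
  if (!reference_id %in% ids) {
    stop(sprintf("reference_id '%s' not present in alignment '%s'", reference_id, path))
  }
  sq <- toupper(as.character(seqs))
  names(sq) <- ids
  structure(list(sequences = sq, reference_id = reference_id, width = w[1]),
            class = "protein_alignment")
}

#' Read a protein domain interval table
#'
#' Reads a 4-column TSV of (protein/gene symbol, domain name, start, end) with
#' 1-based inclusive amino-acid coordinates. Overlapping intervals for one
#' protein are allowed and reported, not rejected.
#'
#' @param path Path to the domain TSV.
#' @return Data frame with columns `protein`, `domain`, `start`, `end`.
#' @export
read_domain_table <- function(path) {
  parsed <- read_tsv_lines(path)
  rows <- parsed$fields
  if (length(rows) && looks_like_header(rows[[1]], c("protein", "gene", "domain", "start", "end", "name"))) {
    rows <- rows[-1L]
    parsed$lineno <- parsed$lineno[-1L]
  }
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) stop(sprintf("malformed domain row at line %d of '%s': expected 4 columns",
                                parsed$lineno[bad[1]], path))
  out <- data.frame(protein = normalize_gene_symbols(vapply(rows, `[[`, "", 1L)),
                    domain = trimws(vapply(rows, `[[`, "", 2L)),
                    start = as.integer(vapply(rows, `[[`, "", 3L)),
                    end = as.integer(vapply(rows, `[[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) stop(sprintf("non-integer domain coordinate in '%s'", path))
  if (any(out$start > out$end)) {
    i <- which(out$start > out$end)[1]
    stop(sprintf("domain interval with start > end at line %d of '%s'", parsed$lineno[i], path))
  }
  if (any(out$start < 1L)) stop("domain coordinates are 1-based; start must be >= 1")
  for (p in unique(out$protein)) {
    iv <- out[out$protein == p, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
      message(sprintf("read_domain_table: overlapping domain intervals for %s (allowed)", p))
    }
  }
  out
}

#' Read an evidence table of per-gene boolean flags
#'
#' Reads a TSV whose first column is the gene symbol and whose remaining
#' columns are boolean evidence flags (accepted codes: 1/0, TRUE/FALSE,
#' yes/no, case-insensitive).
#'
#' @param path Path to the TSV.
#' @return Data frame with column `gene` plus one logical column per flag.
#' @export
read_evidence_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, quote = "")
  if (ncol(raw) < 2L) stop("evidence table needs a gene column plus at least one flag column")
  names(raw)[1] <- "gene"
  raw$gene <- normalize_gene_symbols(raw$gene)
  if (anyDuplicated(raw$gene)) stop("duplicate gene in evidence table")
  for (j in seq(2L, ncol(raw))) {
    cell <- tolower(trimws(raw[[j]]))
    val <- rep(NA, length(cell))
    val[cell %in% c("1", "true", "yes", "t", "y")] <- TRUE
    val[cell %in% c("0", "false", "no", "f", "n")] <- FALSE
    if (anyNA(val)) stop(sprintf("non-boolean cell '%s' in evidence column '%s'",
                                 cell[which(is.na(val))[1]], names(raw)[j]))
    raw[[j]] <- val
  }
  raw
}
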