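#' Variant classes recognised by the pipeline
#'
#' Internal variant-class vocabulary. Nonsynonymous mutations comprise
#' missense, nonsense, splice-site and nonstop single-nucleotide variants.
#'
#' @format Character vectors.
#' @name var_classes
#' @export
VAR_CLASSES <- c("synonymous", "missense", "nonsense", "splice_site",
                 "nonstop", "other")

#' @rdname var_classes
#' @export
NONSYN_CLASSES <- c("missense", "nonsense", "splice_site", "nonstop")

#' Default MAF-compatible column dialect
#'
#' Maps the internal column names of a mutation table onto the column names
#' found in the input file. The defaults follow the MC3 MAF conventions
#' (e.g. `Tumor_Sample_Barcode`, `Variant_Classification`), with RNA allele
#' counts supplied as extra columns. Any entry can be overridden, and a YAML
#' file with the same structure can be loaded with [read_dialect()].
#'
#' @param ... named overrides, either of column-name entries (e.g.
#'   `sample_id = "patient"`) or of the special entries `class_map`
#'   (named character vector mapping file tokens to internal variant
#'   classes) and `required` (internal names that must be present).
#' @return A list with elements `columns`, `class_map` and `required`.
#' @export
maf_dialect <- function(...) {
  d <- list(
    columns = c(
      sample_id  = "Tumor_Sample_Barcode",
      gene       = "Hugo_Symbol",
      chrom      = "Chromosome",
      pos        = "Start_Position",
      ref_allele = "Reference_Allele",
      alt_allele = "Tumor_Seq_Allele2",
      var_class  = "Variant_Classification",
      dna_vaf    = "DNA_VAF",
      dna_alt    = "t_alt_count",
      dna_depth  = "t_depth",
      rna_alt    = "RNA_alt_count",
      rna_ref    = "RNA_ref_count",
      nmd_score  = "NMD_score",
      purity     = "purity",
      ncn        = "ncn",
      tcn        = "tcn"
    ),
    class_map = c(
      Silent            = "synonymous",
      Missense_Mutation = "missense",
      Nonsense_Mutation = "nonsense",
      Splice_Site       = "splice_site",
      Nonstop_Mutation  = "nonstop"
    ),
    required = c("sample_id", "gene", "chrom", "pos", "ref_allele",
                 "alt_allele", "var_class", "rna_alt", "rna_ref")
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("class_map", "required")) {
      d[[nm]] <- ov[[nm]]
    } else if (nm %in% names(d$columns)) {
      d$columns[[nm]] <- ov[[nm]]
    } else {
      stop("unknown dialect entry: ", nm)
    }
  }
  d
}

#' Load a column dialect from a YAML file
#'
#' @param path YAML file with optional `columns`, `class_map`, `required`.
#' @return A dialect list as returned by [maf_dialect()].
#' @export
read_dialect <- function(path) {
  y <- yaml::read_yaml(path)
  d <- maf_dialect()
  if (!is.null(y$columns))   d$columns[names(y$columns)] <- unlist(y$columns)
  if (!is.null(y$class_map)) d$class_map <- unlist(y$class_map)
  if (!is.null(y$required))  d$required <- unlist(y$required)
  d
}

# internal: per-row invariant checks; returns character vector of reasons
# ("" = valid row)
.row_problems <- function(df) {
  reason <- character(nrow(df))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- msg
  }
  bad(!(df$pos >= 1), "pos must be >= 1")
  bad(nchar(df$ref_allele) != 1 | nchar(df$alt_allele) != 1,
      "ref/alt alleles must be single nucleotides")
  bad(df$ref_allele == df$alt_allele, "ref_allele equals alt_allele")
  bad(df$rna_alt < 0 | df$rna_ref < 0, "negative RNA allele count")
  bad(df$dna_alt < 0 | df$dna_depth < 0, "negative DNA read count")
  bad(df$dna_alt > df$dna_depth, "dna_alt exceeds dna_depth")
  bad(df$dna_vaf < 0 | df$dna_vaf > 1, "dna_vaf outside [0, 1]")
  ok_pur <- is.na(df$purity) | (df$purity > 0 & df$purity <= 1)
  reason[!ok_pur & reason == ""] <- "purity outside (0, 1]"
  bad(df$tcn < 1 | df$ncn < 1, "copy numbers must be >= 1")
  reason
}

#' Construct a validated cohort table
#'
#' A cohort table is a `data.frame` of somatic single-nucleotide variants,
#' one row per mutation per sample, carrying DNA and RNA allele counts and
#' the purity/copy-number context. The attribute `n_cohort` records the
#' number of distinct samples and `cancer_type` the cohort label.
#'
#' @param records data.frame with the internal columns (`sample_id`, `gene`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `var_class`, `dna_vaf`,
#'   `dna_alt`, `dna_depth`, `rna_alt`, `rna_ref`, `nmd_score`, `purity`,
#'   `ncn`, `tcn`).
#' @param cancer_type cohort label.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(records, cancer_type = NA_character_) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "gene", "chrom", "pos", "ref_allele", "alt_allele",
            "var_class", "rna_alt", "rna_ref")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  records <- .fill_optional(records)
  bad_class <- setdiff(unique(records$var_class), VAR_CLASSES)
  if (length(bad_class))
    stop("unknown variant class token(s): ", paste(bad_class, collapse = ", "))
  key <- paste(records$sample_id, records$chrom, records$pos,
               records$alt_allele, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, chrom, pos, alt) records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  rownames(records) <- NULL
  structure(records,
            class = c("cohort_table", "data.frame"),
            cancer_type = cancer_type,
            n_cohort = length(unique(records$sample_id)))
}

# internal: add optional columns with defaults
.fill_optional <- function(df) {
  n <- nrow(df)
  if (is.null(df$dna_alt))   df$dna_alt   <- rep(0L, n)
  if (is.null(df$dna_depth)) df$dna_depth <- rep(0L, n)
  if (is.null(df$dna_vaf))
    df$dna_vaf <- ifelse(df$dna_depth > 0, df$dna_alt / df$dna_depth, 0)
  if (is.null(df$nmd_score)) df$nmd_score <- rep(NA_real_, n)
  if (is.null(df$purity))    df$purity    <- rep(NA_real_, n)
  if (is.null(df$ncn))       df$ncn       <- rep(2L, n)
  if (is.null(df$tcn))       df$tcn       <- rep(2L, n)
  df
}

# internal: re-derive cohort attributes after a row subset
.refresh_cohort <- function(df, template) {
  structure(as.data.frame(df),
            class = c("cohort_table", "data.frame"),
            cancer_type = attr(template, "cancer_type"),
            n_cohort = length(unique(df$sample_id)))
}

#' Number of distinct samples in a cohort
#' @param cohort a `cohort_table`.
#' @return Integer cohort size.
#' @export
n_cohort <- function(cohort) attr(cohort, "n_cohort")

#' Read and validate a mutation/RNA-count table
#'
#' Reads a tab-separated mutation table (MAF-compatible column names,
#' remappable through a dialect), maps variant-classification tokens onto
#' the internal vocabulary, validates every row against the type invariants
#' and returns a [cohort_table()]. Rows failing validation are dropped with
#' a warning; the per-row report is attached as attribute `rejected`.
#'
#' @param path TSV file path.
#' @param dialect column dialect, see [maf_dialect()].
#' @param cancer_type cohort label stored on the result.
#' @return A `cohort_table`; attribute `rejected` holds a data.frame of
#'   dropped rows (`row`, `reason`).
#' @export
read_mutation_table <- function(path, dialect = maf_dialect(),
                                cancer_type = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as character: allele columns like "T" must not become logicals
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ".", ""))
  cols <- dialect$columns
  miss <- dialect$required[!cols[dialect$required] %in% names(raw)]
  if (length(miss))
    stop("missing required column(s): ",
         paste(cols[miss], collapse = ", "))
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   matrix(nrow = nrow(raw), ncol = 0))
  for (internal in names(cols)) {
    file_col <- cols[[internal]]
    if (file_col %in% names(raw)) df[[internal]] <- raw[[file_col]]
  }
  df$pos <- as.integer(df$pos)
  for (cc in intersect(c("dna_alt", "dna_depth", "rna_alt", "rna_ref",
                         "ncn", "tcn"), names(df)))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(c("dna_vaf", "purity", "nmd_score"), names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  df$chrom <- as.character(df$chrom)
  # classification tokens: dialect map first, internal tokens pass through,
  # anything else becomes "other"
  vc <- as.character(df$var_class)
  mapped <- unname(dialect$class_map[vc])
  vc_out <- ifelse(!is.na(mapped), mapped,
                   ifelse(vc %in% VAR_CLASSES, vc, "other"))
  df$var_class <- vc_out
  df <- .fill_optional(df)
  df$rna_alt[is.na(df$rna_alt)] <- 0L
  df$rna_ref[is.na(df$rna_ref)] <- 0L
  problems <- .row_problems(df)
  if (any(problems != "")) {
    rejected <- data.frame(row = which(problems != ""),
                           reason = problems[problems != ""],
                           stringsAsFactors = FALSE)
    warning(nrow(rejected), " row(s) rejected during validation; see ",
            "attr(, 'rejected')")
    df <- df[problems == "", , drop = FALSE]
  } else {
    rejected <- data.frame(row = integer(0), reason = character(0))
  }
  out <- cohort_table(df, cancer_type = cancer_type)
  attr(out, "rejected") <- rejected
  out
}

#' Join per-segment copy number and per-sample purity onto a cohort
#'
#' Segments use half-open `[start, end)` intervals on the same 1-based
#' coordinates as the mutation table. Mutations falling in no segment keep
#' their existing `tcn`/`ncn` values.
#'
#' @param cohort a `cohort_table`.
#' @param segments data.frame with `sample_id`, `chrom`, `start`, `end`,
#'   `tcn` and optionally `ncn`.
#' @param purity optional data.frame with `sample_id`, `purity`.
#' @return The cohort with `tcn`, `ncn` and `purity` filled in.
#' @export
join_copy_number <- function(cohort, segments, purity = NULL) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "tcn") %in%
                  names(segments)))
  key <- paste(cohort$sample_id, cohort$chrom, sep = "\r")
  seg_key <- paste(segments$sample_id, segments$chrom, sep = "\r")
  seg_split <- split(seq_len(nrow(segments)), seg_key)
  for (i in seq_len(nrow(cohort))) {
    idx <- seg_split[[key[i]]]
    if (is.null(idx)) next
    hit <- idx[segments$start[idx] <= cohort$pos[i] &
                 cohort$pos[i] < segments$end[idx]]
    if (length(hit)) {
      hit <- hit[1L]
      cohort$tcn[i] <- segments$tcn[hit]
      if (!is.null(segments$ncn)) cohort$ncn[i] <- segments$ncn[hit]
    }
  }
  if (!is.null(purity)) {
    m <- match(cohort$sample_id, purity$sample_id)
    cohort$purity <- ifelse(!is.na(m), purity$purity[m], cohort$purity)
  }
  cohort
}

#' Read cancer-gene lists and oncogene/TSG role assignments
#'
#' The CGC file holds one gene symbol per line (or the first column of a
#' TSV). The optional roles file is a TSV with columns `gene`, `role`
#' (`oncogene` or `tsg`) and optionally `cancer_type`; a cancer-specific
#' role for the active cancer type overrides the pan-cancer assignment.
#'
#' @param cgc_path path to the CGC gene list.
#' @param roles_path optional path to the roles TSV.
#' @param cancer_type active cancer type used to resolve role overrides.
#' @return A `gene_annotation` list with `cgc_genes`, `oncogenes`, `tsgs`.
#' @export
read_gene_lists <- function(cgc_path, roles_path = NULL, cancer_type = NULL) {
  lines <- readLines(cgc_path, warn = FALSE)
  lines <- trimws(vapply(strsplit(lines, "\t"), `[`, "", 1L))
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty gene list: ", cgc_path)
  ann <- list(cgc_genes = unique(lines),
              oncogenes = character(0), tsgs = character(0))
  if (!is.null(roles_path)) {
    roles <- utils::read.delim(roles_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               na.strings = c("NA", ".", ""))
    if (!all(c("gene", "role") %in% names(roles)))
      stop("roles file must have columns 'gene' and 'role'")
    roles <- roles[!is.na(roles$role) & roles$role != "", , drop = FALSE]
    roles$role <- tolower(roles$role)
    bad <- setdiff(unique(roles$role), c("oncogene", "tsg"))
    if (length(bad))
      stop("unknown role token(s): ", paste(bad, collapse = ", "))
    if (is.null(roles$cancer_type)) roles$cancer_type <- NA_character_
    specific <- !is.na(roles$cancer_type) & !is.null(cancer_type) &
      roles$cancer_type == (cancer_type %||% "")
    resolved <- roles[is.na(roles$cancer_type), , drop = FALSE]
    if (any(specific)) {
      sp <- roles[specific, , drop = FALSE]
      resolved <- resolved[!resolved$gene %in% sp$gene, , drop = FALSE]
      resolved <- rbind(resolved, sp)
    }
    ann$oncogenes <- unique(resolved$gene[resolved$role == "oncogene"])
    ann$tsgs <- unique(resolved$gene[resolved$role == "tsg"])
  }
  structure(ann, class = "gene_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write gene-level test results to a TSV
#'
#' Rows are ordered by ascending geometric-mean p value, ties broken by gene
#' symbol, so repeated runs produce byte-identical files.
#'
#' @param results a data.frame of gene test results (see
#'   [run_cancer_type()]).
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("no results to write")
  cols <- c("gene", "class_subset", "n_mutations", "effect_size",
            "p_geomean", "q_value", "driver_flag")
  out <- results
  if (is.null(out$n_mutations) && !is.null(out$n_case))
    out$n_mutations <- out$n_case
  miss <- setdiff(cols, names(out))
  if (length(miss))
    stop("results are missing column(s): ", paste(miss, collapse = ", "))
  out <- out[order(out$p_geomean, out$gene), cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path TSV path.
#' @return data.frame of results.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
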