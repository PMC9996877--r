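# Readers/writers for the plain-text formats the pipeline consumes.
# Canonical dialect is TSV; no delimiter autodetection.

VARIANT_CLASSES <- c("missense", "nonsense", "multi_hit", "frameshift_ins",
                     "frameshift_del", "splice_site", "inframe_ins", "inframe_del")

# MAF-style labels accepted on input and mapped to the canonical classes.
VARIANT_SYNONYMS <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Multi_Hit         = "multi_hit",
  Frame_Shift_Ins   = "frameshift_ins",
  Frame_Shift_Del   = "frameshift_del",
  Splice_Site       = "splice_site",
  In_Frame_Ins      = "inframe_ins",
  In_Frame_Del      = "inframe_del"
)

#' Construct an expression matrix
#'
#' A gene x sample numeric matrix carrying its abundance unit. Linear units
#' (`FPKM`, `TPM`) must be non-negative; `log2` values are unrestricted reals.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param unit one of `"FPKM"`, `"TPM"`, `"log2"`.
#' @return a matrix of class `expr_matrix` with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (unit != "log2" && any(values < 0))
    stop("negative values are not allowed under linear unit ", unit)
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

expr_unit <- function(expr) {
  u <- attr(expr, "unit")
  if (is.null(u)) "log2" else u
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Duplicate genes within a set are removed and counted.
#'
#' @param path file path.
#' @return named list of character vectors of class `gene_set_collection`;
#'   attributes `description` (named character) and `n_duplicates_dropped`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  nms <- trimws(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(nms))
    stop("duplicate set name in GMT: ", nms[duplicated(nms)][1L])
  dropped <- 0L
  sets <- lapply(fields, function(f) {
    g <- trimws(f[-(1:2)])
    g <- g[nzchar(g)]
    u <- unique(g)
    dropped <<- dropped + (length(g) - length(u))
    u
  })
  names(sets) <- nms
  if (any(lengths(sets) == 0L))
    stop("empty gene set in GMT: ", nms[lengths(sets) == 0L][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nms
  structure(sets, description = desc, n_duplicates_dropped = dropped,
            class = "gene_set_collection")
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (or a `gene_set_collection`).
#' @param path output path.
#' @param description optional per-set description; defaults to `"."`.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- rep(".", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression TSV
#'
#' First column gene ids, header row sample ids. Rows containing any
#' missing or non-numeric cell are dropped and counted in the
#' `n_rows_dropped` attribute; duplicate gene ids are an error.
#'
#' @param path file path.
#' @param unit abundance unit of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("FPKM", "TPM", "log2")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a gene id column and >= 1 sample")
  gene_ids <- trimws(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  body <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  body <- matrix(body, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  keep <- stats::complete.cases(body)
  dropped <- sum(!keep)
  body <- body[keep, , drop = FALSE]
  out <- expression_matrix(body, unit = unit)
  attr(out, "n_rows_dropped") <- dropped
  out
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Mandatory columns `sample_id`, `os_time_days` (> 0), `os_event` (0/1);
#' optional `age`, `sex`, `stage`, `response`.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time_days", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if (anyNA(df$os_time_days) || any(df$os_time_days <= 0))
    stop("os_time_days must be positive")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event outside {0,1}")
  invisible(df)
}

#' Write a clinical table as TSV
#' @param clinical data.frame from [read_clinical()] or [simulate_cohort()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF-lite mutation table
#'
#' Columns `sample_id`, `gene_id`, `variant_class`, optional `cohort`.
#' Variant classes outside the canonical eight are mapped through a
#' documented synonym table (MAF capitalized labels) or rejected.
#' Cohort sizes come from a sidecar TSV with columns `cohort`, `n_samples`.
#'
#' @param path mutation TSV path.
#' @param cohort_sizes_path optional sidecar path; defaults to
#'   `<path>.cohorts` when that file exists.
#' @return data.frame of class `mutation_table` with a `cohort_sizes`
#'   attribute (named integer).
#' @export
read_maf_lite <- function(path, cohort_sizes_path = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "variant_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "))
  vc <- trimws(df$variant_class)
  syn <- !is.na(match(vc, names(VARIANT_SYNONYMS)))
  vc[syn] <- VARIANT_SYNONYMS[vc[syn]]
  bad <- setdiff(unique(vc), VARIANT_CLASSES)
  if (length(bad))
    stop("unknown variant_class: ", paste(bad, collapse = ", "),
         " (accepted: ", paste(VARIANT_CLASSES, collapse = ", "), ")")
  df$variant_class <- vc
  if (is.null(df$cohort)) df$cohort <- "all"
  sizes <- NULL
  if (is.null(cohort_sizes_path) && file.exists(paste0(path, ".cohorts")))
    cohort_sizes_path <- paste0(path, ".cohorts")
  if (!is.null(cohort_sizes_path)) {
    cs <- utils::read.delim(cohort_sizes_path, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("cohort", "n_samples") %in% colnames(cs)))
      stop("cohort size sidecar needs columns cohort, n_samples")
    sizes <- stats::setNames(as.integer(cs$n_samples), cs$cohort)
  }
  mutation_table(df, cohort_sizes = sizes)
}

mutation_table <- function(df, cohort_sizes = NULL) {
  if (!is.null(cohort_sizes)) {
    obs <- tapply(df$sample_id, df$cohort, function(s) length(unique(s)))
    for (co in names(obs)) {
      if (is.na(cohort_sizes[co]))
        stop("cohort without a declared size: ", co)
      if (obs[[co]] > cohort_sizes[co])
        stop("cohort ", co, " has more mutated samples (", obs[[co]],
             ") than its declared size (", cohort_sizes[co], ")")
    }
  }
  structure(df, cohort_sizes = cohort_sizes,
            class = c("mutation_table", "data.frame"))
}

#' Read a gene-level CNV focal-score matrix (GISTIC-style)
#' @param path TSV path, first column gene ids, header sample ids.
#' @return numeric gene x sample matrix.
#' @export
read_cnv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in CNV matrix")
  if (!is.numeric(m)) stop("non-numeric values in CNV matrix")
  m
}

#' Read an immune cell fraction matrix
#'
#' Cell type x sample; entries must be non-negative and each sample column
#' must sum to 1 within `tol`.
#'
#' @param path TSV path, first column cell types, header sample ids.
#' @param tol tolerance on the per-sample column sum.
#' @return numeric cell_type x sample matrix.
#' @export
read_fractions <- function(path, tol = 1e-6) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  validate_fractions(m, tol = tol)
  m
}

validate_fractions <- function(m, tol = 1e-6) {
  if (any(m < 0)) stop("negative cell fractions")
  cs <- colSums(m)
  off <- which(abs(cs - 1) > tol)
  if (length(off))
    stop("fraction column(s) not summing to 1: ",
         paste(colnames(m)[off], collapse = ", "))
  invisible(m)
}

#' Read a compound signature library
#'
#' Long TSV with columns `compound_id`, `rank`, `gene_id`; rank 1 is the
#' gene most up-regulated by the compound. Every compound must carry a
#' complete permutation of the same gene universe.
#'
#' @param path TSV path.
#' @return named list of class `signature_library`: compound id ->
#'   character vector of gene ids ordered by rank.
#' @export
read_signature_library <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("compound_id", "rank", "gene_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("signature library missing column(s): ",
                         paste(miss, collapse = ", "))
  lib <- lapply(split(df, df$compound_id), function(d) {
    d$gene_id[order(d$rank)]
  })
  signature_library(lib)
}

signature_library <- function(lib) {
  universe <- sort(lib[[1L]])
  for (i in seq_along(lib)) {
    g <- lib[[i]]
    if (anyDuplicated(g) || !identical(sort(g), universe))
      stop("compound ", names(lib)[i],
           " is not a complete permutation of the common gene universe")
  }
  structure(lib, universe = universe, class = "signature_library")
}

#' Write a compound signature library as long TSV
#' @param lib a `signature_library` (named list of rankings).
#' @param path output path.
#' @export
write_signature_library <- function(lib, path) {
  df <- do.call(rbind, lapply(names(lib), function(cp) {
    data.frame(compound_id = cp, rank = seq_along(lib[[cp]]),
               gene_id = lib[[cp]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix (CNV, fractions) as TSV with row-name column
#' @param m matrix.
#' @param path output path.
#' @param id_col name of the first (row id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
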