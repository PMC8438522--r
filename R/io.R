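#' The 24-gene m6A regulator panel
#'
#' The default panel of m6A writers (methyltransferases), erasers
#' (demethylases) and readers (binding proteins) used for regulation-pattern
#' discovery: 8 writers, 2 erasers and 14 readers.
#'
#' @return A tibble with columns `gene` and `role`
#'   (`"writer"`, `"eraser"` or `"reader"`), 24 rows.
#' @export
#' @examples
#' m6a_regulators()
m6a_regulators <- function() {
  tibble::tibble(
    gene = c(
      "WTAP", "KIAA1429", "CBLL1", "RBM15", "RBM15B", "ZC3H13", "METTL3",
      "METTL14",
      "FTO", "ALKBH5",
      "ELAVL1", "FMR1", "HNRNPA2B1", "HNRNPC", "IGF2BP1", "IGF2BP2",
      "IGF2BP3", "LRPPRC", "RBMX", "YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2",
      "YTHDF3"
    ),
    role = rep(c("writer", "eraser", "reader"), c(8L, 2L, 14L))
  )
}

#' The seven marker regulators of the regulation patterns
#'
#' Regulators that jointly discriminate the three m6A regulation patterns and
#' drive the co-expression screen.
#'
#' @return Character vector of 7 gene symbols.
#' @export
coexp_regulators <- function() {
  c("METTL14", "ZC3H13", "IGF2BP1", "KIAA1429", "HNRNPA2B1", "IGF2BP3",
    "YTHDF1")
}

.guess_sep <- function(path, dialect) {
  dialect <- match.arg(dialect, c("auto", "tsv", "csv"))
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene x sample expression matrix
#'
#' Expects a delimited file whose first column holds gene IDs and whose header
#' row holds sample IDs, with a numeric body on log2 scale. Duplicate gene
#' rows are collapsed by their mean (with a warning); rows containing missing
#' values are dropped and counted; duplicate sample IDs are an error.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` after reading (for
#'   raw-count input). Default `FALSE`: values are assumed already log2 scale.
#' @return Numeric matrix (genes x samples) with unique dimnames. The number
#'   of rows dropped for missingness is attached as attribute `"n_dropped"`.
#' @export
read_expression <- function(path, dialect = "auto", log2_transform = FALSE) {
  sep <- .guess_sep(path, dialect)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) abort("expression file needs a gene column plus >=1 sample column")
  genes <- as.character(raw[[1L]])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample IDs: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  body <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- body[[j]]
    if (is.numeric(col)) {
      mat[, j] <- as.numeric(col)
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & !col %in% c("NA", ""))
      if (length(bad)) {
        abort(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                      col[bad[1L]], genes[bad[1L]], samples[j]))
      }
      mat[, j] <- num
    }
  }
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warn(sprintf("collapsing %d duplicated gene ID(s) by mean: %s",
                 length(dups), paste(head(dups, 5L), collapse = ", ")))
    mat <- rowsum(mat, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  keep <- complete.cases(mat)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf("dropped %d gene row(s) with missing values", n_dropped))
    mat <- mat[keep, , drop = FALSE]
  }
  if (any(!is.finite(mat))) abort("expression matrix contains non-finite values")
  if (log2_transform) mat <- log2(mat + 1)
  attr(mat, "n_dropped") <- n_dropped
  mat
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: genes x samples, first column `gene`.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = "auto") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- .guess_sep(path, dialect)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' member IDs within a line are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns `name`, `description` and list-column `genes`;
#'   zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(name = character(), description = character(),
                          genes = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1L]))
  }
  tibble::tibble(
    name = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets in GMT format
#'
#' @param sets Tibble as returned by [read_gmt()] (columns `name`,
#'   `description`, list-column `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a gene-set tibble to a named list
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @return Named list of character vectors.
#' @export
gene_set_list <- function(sets) {
  setNames(sets$genes, sets$name)
}

.response_levels <- c("CR", "PR", "SD", "PD")

#' Read a clinical table
#'
#' Requires columns `sample_id`, `pfs_time` (days, >= 0) and `pfs_event`
#' (0/1). Optional columns (`t_stage`, `n_stage`, `m_stage`, `gleason`,
#' `psa`, `immune_subtype`, `response`) are carried through typed; response
#' strings outside CR/PR/SD/PD become `NA` with a warning.
#'
#' @param path Path to a CSV/TSV clinical file.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return Tibble, one row per sample.
#' @export
read_clinical <- function(path, dialect = "auto") {
  sep <- .guess_sep(path, if (identical(dialect, "auto") &&
                              !grepl("\\.(csv|tsv|txt)$", path, TRUE)) "csv" else dialect)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("sample_id", "pfs_time", "pfs_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) abort(paste0("clinical table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  df <- as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample IDs in clinical table")
  df$pfs_time <- as.numeric(df$pfs_time)
  df$pfs_event <- as.integer(df$pfs_event)
  if (any(is.na(df$pfs_time)) || any(df$pfs_time < 0)) {
    abort("pfs_time must be numeric and >= 0")
  }
  if (!all(df$pfs_event %in% c(0L, 1L))) abort("pfs_event must be 0 or 1")
  if ("response" %in% colnames(df)) {
    resp <- toupper(trimws(as.character(df$response)))
    unknown <- !is.na(resp) & nzchar(resp) & !resp %in% .response_levels
    if (any(unknown)) {
      warn(sprintf("%d unknown response value(s) set to NA: %s",
                   sum(unknown),
                   paste(unique(resp[unknown]), collapse = ", ")))
      resp[unknown] <- NA_character_
    }
    resp[!nzchar(resp)] <- NA_character_
    df$response <- resp
  }
  if ("gleason" %in% colnames(df)) df$gleason <- as.integer(df$gleason)
  if ("psa" %in% colnames(df)) df$psa <- as.numeric(df$psa)
  df
}

#' Join clinical records to the samples of an expression matrix
#'
#' Join is strictly by sample ID, never by position; the realized cohort size
#' after the join is reported because public cohorts routinely lose samples
#' to incomplete annotation.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical tibble with `sample_id`.
#' @return Clinical tibble restricted and reordered to the expression
#'   samples present in both; message reports the post-join size.
#' @export
join_cohort <- function(expr, clinical) {
  common <- intersect(colnames(expr), clinical$sample_id)
  if (!length(common)) abort("no overlapping samples between expression and clinical data")
  inform(sprintf("cohort after expression/clinical join: %d of %d expression samples",
                 length(common), ncol(expr)))
  clinical[match(common, clinical$sample_id), , drop = FALSE]
}
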