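#' Single-sample GSEA enrichment score
#'
#' Ranks the profile's genes by expression (descending; ties broken by gene
#' ID, so the score is deterministic across platforms) and accumulates the
#' difference between the weighted in-set empirical CDF and the unweighted
#' out-of-set CDF over all rank positions. In-set steps are weighted by
#' `|rank statistic|^alpha`, where the rank statistic of position i among N
#' genes is N - i + 1; `alpha = 0` gives the unweighted rank-sum form.
#'
#' @param profile Named numeric vector: one sample's expression.
#' @param genes Character vector, the gene set.
#' @param alpha Weight exponent (default 0.25, the original ssGSEA choice).
#' @return The enrichment score, or `NA` (with a warning) when the set does
#'   not intersect the profile.
#' @export
#' @examples
#' ssgsea_score(c(a = 4, b = 3, c = 2, d = 1), "a", alpha = 0) # 2
ssgsea_score <- function(profile, genes, alpha = 0.25) {
  N <- length(profile)
  if (N < 2L) abort("profile needs >= 2 genes")
  if (is.null(names(profile))) abort("profile must be a named vector")
  members <- intersect(genes, names(profile))
  if (!length(members)) {
    warn("gene set does not intersect the profile; score is NA")
    return(NA_real_)
  }
  if (length(members) == N) {
    abort("gene set covers the whole profile; out-of-set ECDF undefined")
  }
  ord <- order(-profile, names(profile))
  in_set <- names(profile)[ord] %in% members
  r <- N - seq_len(N) + 1
  w <- ifelse(in_set, abs(r)^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (N - length(members))
  sum(p_in - p_out)
}

.sets_as_list <- function(sets) {
  if (is.data.frame(sets)) gene_set_list(sets) else sets
}

#' Score a matrix of samples against immune signatures
#'
#' Applies [ssgsea_score()] per sample and gene set.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sets Gene sets: tibble from [read_gmt()] or a named list of
#'   character vectors.
#' @param alpha Weight exponent.
#' @param normalize If `TRUE`, min-max scale each signature across samples to
#'   \[0, 1\].
#' @return Tibble: `sample_id` plus one numeric column per signature.
#' @export
score_matrix <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  sets <- .sets_as_list(sets)
  if (!length(sets)) abort("no gene sets supplied")
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    prof <- expr[, j]
    names(prof) <- rownames(expr)
    for (s in seq_along(sets)) {
      out[j, s] <- ssgsea_score(prof, sets[[s]], alpha)
    }
  }
  if (normalize) {
    out <- apply(out, 2L, function(v) {
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0) return(rep(0, length(v)))
      (v - rng[1L]) / diff(rng)
    })
  }
  bind_cols(tibble::tibble(sample_id = colnames(expr)),
            as_tibble(out, .name_repair = "minimal"))
}

#' Ingest a precomputed signature-score table
#'
#' For pipelines that consume published per-sample immune signature scores
#' (e.g. CIBERSORT-derived pan-immune tables) instead of recomputing them.
#'
#' @param path CSV/TSV file: one sample column (named `sample_id` or the
#'   first column) plus one numeric column per signature.
#' @param samples Optional character vector of cohort sample IDs; table rows
#'   outside it are dropped (counted), and no overlap is an error.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return Tibble: `sample_id` plus signature columns.
#' @export
ingest_signature_table <- function(path, samples = NULL, dialect = "auto") {
  sep <- .guess_sep(path, dialect)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  id_col <- if ("sample_id" %in% colnames(df)) "sample_id" else colnames(df)[1L]
  df <- as_tibble(df) |> rename(sample_id = all_of(id_col))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicated sample row in signature table")
  for (cn in setdiff(colnames(df), "sample_id")) df[[cn]] <- as.numeric(df[[cn]])
  if (!is.null(samples)) {
    keep <- df$sample_id %in% samples
    if (!any(keep)) abort("no overlapping samples between signature table and cohort")
    if (any(!keep)) {
      inform(sprintf("dropped %d signature-table sample(s) not in the cohort",
                     sum(!keep)))
    }
    df <- df[keep, , drop = FALSE]
  }
  df
}
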