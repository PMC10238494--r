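# Samples x peptides quantification container.

#' Construct a quantification matrix
#'
#' A light container for MRM quantification results: a numeric samples x
#' peptides matrix (peak areas or analyte/IS ratios) plus per-sample
#' metadata. Technical replicates are rows whose `replicate_of` names their
#' parent biological sample.
#'
#' @param values Numeric matrix, rows = samples (rownames = sample ids),
#'   columns = peptide ids.
#' @param sample_meta Data frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"` — other labels are carried but ignored by the
#'   cascade), `replicate_of` and optionally `batch`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample rownames and peptide colnames",
         call. = FALSE)
  }
  req <- c("sample_id", "group", "replicate_of")
  if (!is.data.frame(sample_meta) || !all(req %in% names(sample_meta))) {
    stop("`sample_meta` needs columns sample_id, group, replicate_of",
         call. = FALSE)
  }
  if (!identical(rownames(values), sample_meta$sample_id)) {
    stop("rownames(values) must equal sample_meta$sample_id", call. = FALSE)
  }
  if (is.null(sample_meta$batch)) sample_meta$batch <- NA_character_
  structure(list(values = values, sample_meta = sample_meta),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  n_bio <- length(unique(x$sample_meta$replicate_of))
  cat(sprintf("quant_matrix: %d sample rows (%d biological) x %d peptides\n",
              nrow(x$values), n_bio, ncol(x$values)))
  tab <- table(x$sample_meta$group[!duplicated(x$sample_meta$replicate_of)])
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

peptide_ids <- function(x) colnames(x$values)
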