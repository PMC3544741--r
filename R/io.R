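#' Read and write the pipeline's tab-delimited formats
#'
#' Expression matrices are stored probes-in-rows with a header row of
#' sample ids and probe ids in the first column; compositions are
#' samples x cell types with sample ids in the first column; relapse
#' labels are a two-column table (`sample_id`, `relapse`).
#'
#' @param x matrix or vector to write.
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline_io
#' @export
write_composition_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline_io
#' @export
write_relapse_tsv <- function(x, path) {
  df <- data.frame(sample_id = names(x), relapse = as.integer(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_relapse_tsv <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(as.integer(df$relapse), df$sample_id)
}

#' Write a deconvolution fit table as TSV
#'
#' One row per gene with the intercept, per-cell-type baseline (beta)
#' and relapse-differential (gamma) coefficients, their standard
#' errors, t statistics and two-sided p-values, plus the gene's rank
#' by ascending gamma for each modeled cell type.
#'
#' @param fit a [deconv()] object.
#' @param path file path.
#' @export
write_fit_table <- function(fit, path) {
  stopifnot(inherits(fit, "deconv"))
  co <- fit$coefficients
  nm <- colnames(co)
  clean <- gsub("[():]", "_", gsub("\\(Intercept\\)", "beta0", nm))
  clean <- sub("_RS$", "", clean)
  is_gamma <- grepl(":RS$", nm)
  colnames(co) <- ifelse(is_gamma, paste0("gamma_", clean),
                         ifelse(nm == "(Intercept)", "beta0",
                                paste0("beta_", clean)))
  tab <- data.frame(gene_id = rownames(co), co, check.names = FALSE)
  for (part in c("se", "t", "p")) {
    m <- fit[[part]]
    colnames(m) <- paste0(part, "_", ifelse(is_gamma, paste0("gamma_", clean),
                                            ifelse(nm == "(Intercept)", "beta0",
                                                   paste0("beta_", clean))))
    tab <- cbind(tab, m)
  }
  for (ctype in fit$modeled_types) {
    rk <- rank_by_gamma(fit, ctype)
    tab[[paste0("rank_gamma_", ctype)]] <-
      rk$rank[match(tab$gene_id, rk$gene_id)]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
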