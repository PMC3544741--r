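#' Seed-gene Pearson correlation screen
#'
#' Correlates every probe in an expression matrix with a seed probe
#' across samples, reporting the Pearson coefficient R, its two-sided
#' p-value from the t transform `t = R * sqrt((n - 2) / (1 - R^2))`
#' on `n - 2` degrees of freedom, and the ordinary least-squares slope
#' of the candidate regressed on the seed.  The slope measures how
#' tightly a candidate's expression tracks the seed's on the log2
#' scale.
#'
#' Samples missing in either the seed or a candidate are dropped
#' pairwise; the per-record `n_samples` reflects the pairs actually
#' used.  Zero-variance candidates get `NA` R with `flagged = TRUE`
#' and are excluded by [filter_candidates()].
#'
#' @param expr probes x samples numeric matrix (log2 intensities).
#' @param seed_probe row name of the seed probe.
#' @param annotation optional data.frame with columns `probe_id` and
#'   `gene_symbol` used to attach symbols.
#' @return data.frame with one row per probe (seed included, R = 1):
#'   `probe_id`, `gene_symbol`, `pearson_R`, `p_two_sided`, `slope`,
#'   `n_samples`, `flagged`.
#' @examples
#' x <- rbind(seedg = c(1, 2, 3, 4), cand = c(2, 4, 6, 8))
#' pearson_screen(x, "seedg")
#' @export
pearson_screen <- function(expr, seed_probe, annotation = NULL) {
  expr <- as.matrix(expr)
  if (!seed_probe %in% rownames(expr))
    stop("seed probe '", seed_probe, "' not found")
  if (ncol(expr) < 3) stop("need at least 3 samples")
  s <- expr[seed_probe, ]
  res <- t(apply(expr, 1L, function(y) {
    use <- is.finite(s) & is.finite(y)
    n <- sum(use)
    if (n < 3) return(c(NA, NA, NA, n))
    x <- s[use]; yy <- y[use]
    vx <- stats::var(x); vy <- stats::var(yy)
    if (vx == 0 || vy == 0) return(c(NA, NA, NA, n))
    cxy <- stats::cov(x, yy)
    r <- cxy / sqrt(vx * vy)
    r <- max(-1, min(1, r))
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    }
    c(r, p, cxy / vx, n)
  }))
  out <- data.frame(
    probe_id = rownames(expr),
    pearson_R = res[, 1], p_two_sided = res[, 2],
    slope = res[, 3], n_samples = as.integer(res[, 4]),
    flagged = !is.finite(res[, 1]),
    is_seed = rownames(expr) == seed_probe,
    row.names = NULL)
  out$gene_symbol <- if (!is.null(annotation)) {
    annotation$gene_symbol[match(out$probe_id, annotation$probe_id)]
  } else NA_character_
  out[, c("probe_id", "gene_symbol", "pearson_R", "p_two_sided",
          "slope", "n_samples", "flagged", "is_seed")]
}

#' Filter a correlation screen to seed-correlated candidates
#'
#' Keeps records whose Pearson R is at least `min_R` (positive
#' correlations only) and whose p-value is at most `max_p`; both
#' bounds are inclusive.  The seed probe itself (R exactly 1 against
#' itself) and flagged zero-variance records are excluded.
#'
#' @param records data.frame from [pearson_screen()].
#' @param min_R minimum Pearson correlation (default 0.45).
#' @param max_p maximum two-sided p-value (default 0.001).
#' @return the filtered data.frame, sorted by descending slope.
#' @export
filter_candidates <- function(records, min_R = 0.45, max_p = 0.001) {
  keep <- !records$flagged &
    !is.na(records$pearson_R) &
    records$pearson_R >= min_R &
    records$p_two_sided <= max_p
  if (!is.null(records$is_seed)) keep <- keep & !records$is_seed
  out <- records[keep, , drop = FALSE]
  out[order(-out$slope, out$probe_id), , drop = FALSE]
}

#' Top-k records by correlation p-value
#'
#' Returns the `k` records with the smallest p-values among positively
#' correlated, unflagged probes.  Ties on p are broken by larger R,
#' then by probe id.
#'
#' @inheritParams filter_candidates
#' @param k how many records to keep; if fewer are available all are
#'   returned with a message.
#' @return data.frame of at most `k` rows, ordered by ascending p.
#' @export
top_k_by_p <- function(records, k = 150) {
  pos <- records[!records$flagged & !is.na(records$pearson_R) &
                   records$pearson_R > 0, , drop = FALSE]
  if (!is.null(pos$is_seed)) pos <- pos[!pos$is_seed, , drop = FALSE]
  pos <- pos[order(pos$p_two_sided, -pos$pearson_R, pos$probe_id), , drop = FALSE]
  if (k > nrow(pos)) {
    message("requested k = ", k, " but only ", nrow(pos),
            " positively correlated records; returning all")
    k <- nrow(pos)
  }
  utils::head(pos, k)
}

#' Intersect candidate lists across platforms
#'
#' Collapses each probe list to unique gene symbols through its
#' platform annotation (case-insensitive; a gene counts once however
#' many probes map to it) and reports the symbol-level intersection.
#' Where the two lists share a probe namespace the probe-level
#' intersection is reported as well.  Probes without an annotation row
#' are dropped from the gene-level overlap with a warning.
#'
#' @param list_a,list_b character vectors of probe ids (or data.frames
#'   with a `probe_id` column).
#' @param annotation_a,annotation_b data.frames with `probe_id` and
#'   `gene_symbol` columns for the two platforms.
#' @return list with elements `genes_a`, `genes_b` (sorted unique
#'   symbols), `overlap_genes`, `n_a`, `n_b`, `n_overlap`, and
#'   `overlap_probes` (shared probe ids, possibly empty).
#' @export
cross_platform_overlap <- function(list_a, list_b,
                                   annotation_a, annotation_b) {
  probes <- function(x) if (is.data.frame(x)) x$probe_id else as.character(x)
  pa <- probes(list_a); pb <- probes(list_b)
  to_genes <- function(p, ann, label) {
    sym <- ann$gene_symbol[match(p, ann$probe_id)]
    miss <- is.na(sym) | !nzchar(sym)
    if (any(miss))
      warning(sum(miss), " probe(s) in list ", label,
              " lack annotation; excluded from gene-level overlap")
    sort(unique(toupper(sym[!miss])))
  }
  ga <- to_genes(pa, annotation_a, "A")
  gb <- to_genes(pb, annotation_b, "B")
  ov <- intersect(ga, gb)
  list(genes_a = ga, genes_b = gb, overlap_genes = ov,
       n_a = length(ga), n_b = length(gb), n_overlap = length(ov),
       overlap_probes = sort(intersect(pa, pb)))
}

#' Write a correlation screen as a supplementary-style table
#'
#' Writes probe id, gene symbol, R, p, slope as tab-delimited text,
#' sorted by descending slope.
#'
#' @param records data.frame from [pearson_screen()] or
#'   [filter_candidates()].
#' @param path output file path.
#' @export
write_correlation_table <- function(records, path) {
  out <- records[order(-records$slope, records$probe_id),
                 c("probe_id", "gene_symbol", "pearson_R",
                   "p_two_sided", "slope")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
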