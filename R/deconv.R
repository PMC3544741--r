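#' Build the composition-interaction design matrix
#'
#' Columns are, in order: an intercept, one cell-fraction column per
#' modeled cell type, and one interaction column (fraction times the
#' 0/1 outcome indicator) per modeled cell type.  Interaction columns
#' are named `<type>:RS`.
#'
#' Input compositions on the percentage (0-100) scale are detected by
#' their row sums and rescaled to fractions with a warning.  The design
#' is rank-checked: modeling all compartments of a simplex together
#' with the intercept is exactly collinear and raises an error naming
#' the offending columns.
#'
#' @param composition samples x cell-types fraction (or percentage)
#'   matrix.
#' @param relapse 0/1 outcome vector aligned with the rows.
#' @param modeled_types cell types to model explicitly; must be a
#'   subset of the composition columns.  Leaving one compartment out
#'   (the default drops the last column) keeps the design full rank.
#' @param max_condition condition-number bound above which the design
#'   is declared numerically rank-deficient.
#' @return numeric matrix with `1 + 2 * length(modeled_types)` columns
#'   and attribute `"modeled_types"`.
#' @export
build_design <- function(composition, relapse,
                         modeled_types = head(colnames(composition), -1),
                         max_condition = 1e10) {
  composition <- as.matrix(composition)
  if (nrow(composition) != length(relapse))
    stop("composition rows and relapse labels are misaligned")
  bad <- setdiff(modeled_types, colnames(composition))
  if (length(bad))
    stop("unknown cell types: ", paste(bad, collapse = ", "))
  rs_vals <- unique(as.numeric(relapse))
  if (!all(rs_vals %in% c(0, 1)))
    stop("'relapse' must be coded 0/1")
  sums <- rowSums(composition)
  if (all(abs(sums - 100) < 1)) {
    warning("composition looks like percentages (rows sum to ~100); rescaling to fractions")
    composition <- composition / 100
  }
  P <- composition[, modeled_types, drop = FALSE]
  rs <- as.numeric(relapse)
  X <- cbind(1, P, P * rs)
  colnames(X) <- c("(Intercept)", modeled_types, paste0(modeled_types, ":RS"))
  # condition check on columns that are not identically zero (zero
  # interaction columns are legitimate when no sample relapses and are
  # dropped at fit time)
  live <- colSums(abs(X)) > 0
  kap <- kappa(X[, live, drop = FALSE], exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("design matrix is numerically rank-deficient (condition number ",
         format(kap, digits = 3), "); columns: ",
         paste(colnames(X)[live], collapse = ", "),
         ". Model one fewer compartment.")
  structure(X, modeled_types = modeled_types)
}

# OLS with per-coefficient t inference for one response on a fixed
# design; identically-zero columns are dropped and reported as NA.
.fit_ols <- function(y, X) {
  if (any(!is.finite(y))) stop("non-finite values in expression vector")
  live <- colSums(abs(X)) > 0
  Xl <- X[, live, drop = FALSE]
  n <- nrow(Xl); p <- ncol(Xl)
  df <- n - p
  if (df < 1) stop("underdetermined fit: residual df < 1")
  qr_x <- qr(Xl)
  if (qr_x$rank < p)
    stop("design matrix is rank deficient after zero-column drops")
  coefs <- qr.coef(qr_x, y)
  fitted <- drop(Xl %*% coefs)
  resid <- y - fitted
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  tval <- ifelse(se > 0, coefs / se, ifelse(coefs == 0, 0, Inf))
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  full <- function(v) {
    out <- rep(NA_real_, ncol(X)); names(out) <- colnames(X)
    out[live] <- v; out
  }
  list(coefficients = full(coefs), se = full(se), t = full(tval),
       p = full(pval), df = df, sigma = sqrt(sigma2),
       fitted = fitted, residuals = resid)
}

#' Fit the composition-interaction model for one gene
#'
#' Ordinary least squares of one gene's per-sample expression on a
#' design from [build_design()], with per-coefficient two-sided t-tests
#' on the residual-degrees-of-freedom t distribution.  The interaction
#' coefficients (columns `<type>:RS`) estimate gamma, the change in
#' cell-type-specific expression between outcome groups; their t-test
#' uses the coefficient's own standard error.
#'
#' @param y numeric vector of per-sample expression (log2 scale).
#' @param design design matrix from [build_design()].
#' @return list with elements `coefficients`, `se`, `t`, `p` (each
#'   named by design column; `NA` for dropped all-zero columns), `df`,
#'   `sigma`, `fitted` and `residuals`.
#' @examples
#' spec <- cohort_spec(n_samples = 30, seed = 7)
#' ch <- generate_cohort(spec)
#' X <- build_design(ch$composition, ch$relapse,
#'                   modeled_types = c("tumor", "stroma", "BPH"))
#' y <- drop(X %*% c(0, 1, 0.5, -0.5, -2, 0, 0))
#' fit_gene(y, X)$coefficients
#' @export
fit_gene <- function(y, design) {
  if (length(y) != nrow(design))
    stop("length(y) must equal nrow(design)")
  .fit_ols(as.numeric(y), design)
}

#' Cell-type deconvolution of a bulk expression matrix
#'
#' Fits, for every gene, the multiple linear regression of bulk log2
#' expression on pathologist-assigned cell-type fractions with
#' outcome-interaction terms:
#' \deqn{y_i = \beta_0 + \sum_j \beta_j P_{ij} +
#'       \sum_j \gamma_j P_{ij} RS_i + \varepsilon_i,
#'       \quad \varepsilon_i \sim N(0, \sigma^2).}
#' \eqn{\beta_j} estimates the expression contributed by cell type *j*
#' in non-relapse tissue and \eqn{\gamma_j} the change of that
#' contribution in relapse tissue (relapse minus non-relapse).  All
#' genes share one design, so the factorization is computed once and
#' reused; a genome-scale matrix fits in seconds.
#'
#' @param expr genes x samples numeric matrix of log2 intensities.
#' @param composition samples x cell-types fraction matrix.
#' @param relapse 0/1 outcome vector aligned with samples.
#' @param modeled_types cell types to model; default all composition
#'   columns but the last (the left-out compartment absorbs the
#'   remainder and keeps the design full rank).
#' @param center_samples if `TRUE`, subtract each sample's mean over
#'   all genes before fitting, expressing every coefficient relative to
#'   the array-wide mean.  Off by default; turn on to mimic analyses
#'   that report coefficients relative to the mean of all probe sets.
#' @param keep_response if `TRUE` (default) the (centered) expression
#'   matrix is stored on the fit so that [residuals()] works; set to
#'   `FALSE` to halve memory on genome-scale runs.
#' @return object of class `"deconv"`: a list with matrices
#'   `coefficients`, `se`, `t`, `p` (genes x design columns), vector
#'   `sigma`, scalar `df`, the `design`, and bookkeeping fields.
#' @seealso [rank_by_gamma()], [significant_gamma()], [fit_gene()]
#' @examples
#' ch <- generate_cohort(cohort_spec(n_samples = 60, seed = 3))
#' expr <- simulate_expression(ch$composition, ch$relapse,
#'                             egr_presets(), seed = 3)
#' fit <- deconv(expr, ch$composition, ch$relapse,
#'               modeled_types = c("tumor", "stroma", "BPH"))
#' coef(fit)
#' summary(fit)
#' @export
deconv <- function(expr, composition, relapse,
                   modeled_types = head(colnames(composition), -1),
                   center_samples = FALSE, keep_response = TRUE) {
  cl <- match.call()
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%05d", seq_len(nrow(expr)))
  if (!is.null(colnames(expr)) && !is.null(rownames(composition))) {
    if (!setequal(colnames(expr), rownames(composition)))
      stop("expression and composition sample ids do not match")
    composition <- composition[colnames(expr), , drop = FALSE]
    if (!is.null(names(relapse))) relapse <- relapse[colnames(expr)]
  }
  if (ncol(expr) != nrow(composition))
    stop("expression columns and composition rows are misaligned")
  if (center_samples)
    expr <- sweep(expr, 2L, colMeans(expr))
  X <- build_design(composition, relapse, modeled_types)
  live <- colSums(abs(X)) > 0
  Xl <- X[, live, drop = FALSE]
  n <- nrow(Xl); p <- ncol(Xl)
  df <- n - p
  if (df < 1) stop("underdetermined fit: residual df < 1")
  qr_x <- qr(Xl)
  if (qr_x$rank < p) stop("design matrix is rank deficient")
  ok <- apply(is.finite(expr), 1L, all)
  if (!all(ok))
    warning(sum(!ok), " gene(s) with non-finite values; their fits are NA")
  B <- matrix(NA_real_, ncol(X), nrow(expr),
              dimnames = list(colnames(X), rownames(expr)))
  Bl <- qr.coef(qr_x, t(expr[ok, , drop = FALSE]))
  B[live, ok] <- Bl
  fitted <- Xl %*% Bl
  resid <- t(expr[ok, , drop = FALSE]) - fitted
  sigma2 <- colSums(resid^2) / df
  XtXinv_diag <- pmax(diag(chol2inv(qr.R(qr_x))), 0)
  SE <- matrix(NA_real_, ncol(X), nrow(expr),
               dimnames = dimnames(B))
  SE[live, ok] <- sqrt(outer(XtXinv_diag, sigma2))
  Tm <- B / SE
  Pm <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
  sigma <- rep(NA_real_, nrow(expr)); names(sigma) <- rownames(expr)
  sigma[ok] <- sqrt(sigma2)
  structure(
    list(coefficients = t(B), se = t(SE), t = t(Tm), p = t(Pm),
         sigma = sigma, df = df, design = X,
         modeled_types = attr(X, "modeled_types"),
         n_samples = n, n_failed = sum(!ok),
         center_samples = center_samples,
         response = if (keep_response) expr, call = cl),
    class = "deconv")
}

#' @export
print.deconv <- function(x, ...) {
  cat("Cell-type deconvolution fit (composition-interaction MLR)\n")
  cat("  genes:         ", nrow(x$coefficients),
      if (x$n_failed) sprintf(" (%d failed)", x$n_failed) else "", "\n", sep = "")
  cat("  samples:       ", x$n_samples, "\n", sep = "")
  cat("  modeled types: ", paste(x$modeled_types, collapse = ", "), "\n", sep = "")
  cat("  residual df:   ", x$df, "\n", sep = "")
  invisible(x)
}

#' @export
coef.deconv <- function(object, ...) object$coefficients

#' @export
residuals.deconv <- function(object, ...) {
  if (is.null(object$response))
    stop("fit was made with keep_response = FALSE; residuals unavailable")
  object$response - predict(object)
}

#' Predict bulk expression for new samples
#'
#' Evaluates each gene's fitted linear predictor on a new set of
#' cell-type compositions and outcome labels.
#'
#' @param object a `"deconv"` fit.
#' @param composition samples x cell-types fraction matrix for the new
#'   samples (defaults to the training compositions via the stored
#'   design).
#' @param relapse 0/1 labels for the new samples.
#' @param ... unused.
#' @return genes x samples matrix of predicted log2 intensities.
#' @export
predict.deconv <- function(object, composition = NULL, relapse = NULL, ...) {
  if (is.null(composition)) {
    X <- object$design
  } else {
    X <- build_design(composition, relapse, object$modeled_types)
  }
  B <- object$coefficients
  B[is.na(B)] <- 0
  B %*% t(X)
}

#' Simulate expression from a fitted deconvolution model
#'
#' Draws new expression matrices from the fitted coefficients and
#' residual standard deviations — a parametric bootstrap of the
#' composition-interaction model.
#'
#' @param object a `"deconv"` fit.
#' @param nsim number of simulated matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` genes x samples matrices.
#' @export
simulate.deconv <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  lapply(seq_len(nsim), function(k) {
    mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) * object$sigma
  })
}

#' @export
summary.deconv <- function(object, cell_type = object$modeled_types[1], ...) {
  gcol <- paste0(cell_type, ":RS")
  if (!gcol %in% colnames(object$coefficients))
    stop("unknown cell type: ", cell_type)
  tab <- data.frame(
    gene_id = rownames(object$coefficients),
    beta = object$coefficients[, cell_type],
    gamma = object$coefficients[, gcol],
    se_gamma = object$se[, gcol],
    p_gamma = object$p[, gcol],
    row.names = NULL)
  structure(list(table = tab, cell_type = cell_type,
                 n_samples = object$n_samples, df = object$df,
                 n_genes = nrow(object$coefficients)),
            class = "summary.deconv")
}

#' @export
print.summary.deconv <- function(x, n = 10L, ...) {
  cat("Deconvolution summary for cell type '", x$cell_type, "' (",
      x$n_genes, " genes, ", x$n_samples, " samples, df = ", x$df, ")\n",
      sep = "")
  ord <- order(x$table$gamma)
  cat("Most negative relapse differentials (gamma):\n")
  print(utils::head(x$table[ord, ], n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Volcano plot of relapse differentials
#'
#' Plots each gene's relapse differential (gamma) for one cell type
#' against the -log10 two-sided p-value of its t-test.
#'
#' @param x a `"deconv"` fit.
#' @param cell_type which modeled cell type to display.
#' @param alpha significance level drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deconv <- function(x, cell_type = x$modeled_types[1], alpha = 0.05, ...) {
  gcol <- paste0(cell_type, ":RS")
  g <- x$coefficients[, gcol]
  p <- x$p[, gcol]
  graphics::plot(g, -log10(p),
                 xlab = bquote(gamma[.(cell_type)] ~ "(log2 units)"),
                 ylab = expression(-log[10] ~ p),
                 pch = 20, col = ifelse(p <= alpha & g < 0, "firebrick", "grey40"),
                 ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' Rank genes by their relapse differential
#'
#' Orders the fit table by ascending gamma for one cell type (most
#' negative first), with ties broken lexicographically by gene id.
#'
#' @param fit a `"deconv"` object.
#' @param cell_type modeled cell type whose gamma is ranked.
#' @return data.frame with columns `rank`, `gene_id`, `gamma`,
#'   `se_gamma`, `p_gamma` ordered by ascending gamma.
#' @export
rank_by_gamma <- function(fit, cell_type) {
  stopifnot(inherits(fit, "deconv"))
  gcol <- paste0(cell_type, ":RS")
  if (!gcol %in% colnames(fit$coefficients))
    stop("unknown cell type: ", cell_type)
  g <- fit$coefficients[, gcol]
  ids <- rownames(fit$coefficients)
  ord <- order(g, ids)
  data.frame(rank = seq_along(ord), gene_id = ids[ord], gamma = g[ord],
             se_gamma = fit$se[ord, gcol], p_gamma = fit$p[ord, gcol],
             row.names = NULL)
}

#' Flag genes with a significant negative relapse differential
#'
#' A gene is flagged when its gamma for the given cell type is
#' negative and its two-sided t-test p-value is at or below `alpha` —
#' the criterion used to count outcome-linked genes and to set the
#' background rate of the list-enrichment simulation.
#'
#' @inheritParams rank_by_gamma
#' @param alpha two-sided significance level.
#' @return named logical vector over genes (`NA` for failed fits).
#' @export
significant_gamma <- function(fit, cell_type, alpha = 0.05) {
  stopifnot(inherits(fit, "deconv"))
  gcol <- paste0(cell_type, ":RS")
  if (!gcol %in% colnames(fit$coefficients))
    stop("unknown cell type: ", cell_type)
  out <- fit$coefficients[, gcol] < 0 & fit$p[, gcol] <= alpha
  stats::setNames(out, rownames(fit$coefficients))
}
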