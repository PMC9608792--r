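#' @keywords internal
#' @noRd
new_linear_fit <- function(fit, response, n) {
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- data.frame(term = rownames(ct), beta = ct[, 1L], se = ct[, 2L],
                      t = ct[, 3L], p = ct[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  out <- list(response = response, terms = terms,
              r_squared = sm$r.squared, n = n,
              df_residual = fit$df.residual, fit = fit)
  class(out) <- "linear_fit"
  out
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> %s ~ ... (n = %d, R^2 = %.4f)\n",
              x$response, x$n, x$r_squared))
  print(format(x$terms, digits = 3), row.names = FALSE)
  invisible(x)
}

# shared engine for the divergence ~ Tajima's D interaction models
fit_divergence_model <- function(table, response, model,
                                 include_interaction = TRUE) {
  stopifnot(model %in% c(1L, 2L),
            all(c(response, "D1_std", "D2_std") %in% names(table)))
  df <- data.frame(y = table[[response]],
                   D1 = table$D1_std, D2 = table$D2_std)
  df$D1sq <- df$D1^2
  df$D2sq <- df$D2^2
  if (include_interaction) df$D1xD2 <- df$D1 * df$D2
  if (model == 2L) {
    need <- c("gc_content", "length", "ratio1_log10", "ratio2_log10")
    if (!all(need %in% names(table))) {
      stop("model 2 needs columns: ", paste(need, collapse = ", "))
    }
    df$gc_content <- table$gc_content
    df$gene_length <- table$length
    df$pnps1 <- table$ratio1_log10
    df$pnps2 <- table$ratio2_log10
  }
  ok <- stats::complete.cases(df) & apply(sapply(df, is.finite), 1L, all)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) <= ncol(df)) stop("too few complete rows for the model")
  fit <- lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  new_linear_fit(fit, response, nrow(df))
}

#' Interaction model of relative divergence on within-population Tajima's D
#'
#' Ordinary least squares of logit F_ST for a population pair on the
#' standardized non-synonymous Tajima's D of the two populations, their
#' squares and their interaction (model 1). Model 2 additionally controls
#' for GC content, gene length and the log10 piN/piS of both populations.
#' Rows with any missing term are dropped listwise. A negative interaction
#' coefficient is the footprint of imbalanced selection: genes with
#' sweep-like spectra in one population and balancing-like spectra in the
#' other carry the most relative divergence.
#'
#' @param table per-gene pair table (see [assemble_pair_table()]) with
#'   columns `fst_logit`, `D1_std`, `D2_std` and, for model 2,
#'   `gc_content`, `length`, `ratio1_log10`, `ratio2_log10`.
#' @param model 1 (D terms only) or 2 (adds covariates).
#' @param include_interaction set `FALSE` to fit the nested model without
#'   `D1 x D2` (used for effect-size computations).
#' @return a `linear_fit`: term table (beta, se, t, p), R-squared, n.
#' @export
fit_fst_model <- function(table, model = 1L, include_interaction = TRUE) {
  fit_divergence_model(table, "fst_logit", model, include_interaction)
}

#' Interaction model of absolute divergence on within-population Tajima's D
#'
#' As [fit_fst_model()] with response `dxy_log10`. For d_XY the signal
#' expected under drift-dominated absolute divergence is negative
#' quadratic terms (genes with near-zero D in both populations diverge
#' most) rather than the interaction.
#'
#' @inheritParams fit_fst_model
#' @return a `linear_fit`.
#' @export
fit_dxy_model <- function(table, model = 1L, include_interaction = TRUE) {
  fit_divergence_model(table, "dxy_log10", model, include_interaction)
}

#' Cohen's f-squared for a dropped term
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`; the local effect size of
#' the term(s) distinguishing a full model from a nested reduced model.
#'
#' @param fit_full,fit_reduced `linear_fit` objects, reduced nested in full.
#' @return f-squared (numeric scalar).
#' @export
cohens_f2 <- function(fit_full, fit_reduced) {
  r2f <- fit_full$r_squared
  r2r <- fit_reduced$r_squared
  if (r2f >= 1) stop("cohens_f2: R^2 of the full model must be < 1")
  (r2f - r2r) / (1 - r2f)
}

#' Regression of a PC1 score on gene-level covariates
#'
#' Covariates are standardized to unit variance so the reported
#' coefficients are standardized betas.
#'
#' @param pc1 numeric vector of PC1 scores.
#' @param covariates data.frame of numeric covariates (e.g. gene length,
#'   GC content, optionally FPKM), aligned with `pc1`.
#' @return a `linear_fit` with standardized coefficients.
#' @export
pc1_regression <- function(pc1, covariates) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(pc1))
  df <- data.frame(y = pc1, lapply(covariates, function(x) {
    x <- as.numeric(x)
    (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  }))
  ok <- stats::complete.cases(df) & apply(sapply(df, is.finite), 1L, all)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) <= ncol(df)) stop("too few complete rows for the model")
  fit <- lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  new_linear_fit(fit, "pc1", nrow(df))
}

#' Pearson correlation over complete pairs
#'
#' @param a,b numeric vectors of equal length; pairs with any missing or
#'   non-finite entry are dropped.
#' @return Pearson r; `NaN` if either vector has zero variance.
#' @export
correlate <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("correlate: need >= 3 complete pairs")
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NaN)
  cor(a, b)
}
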