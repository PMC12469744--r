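#' @importFrom stats ks.test wilcox.test as.formula model.matrix glm
#'   Gamma binomial coef median sd setNames
NULL

#' Compare metric distributions of two grid runs
#'
#' Two-sample Kolmogorov-Smirnov test on a chosen metric (e.g. `prauc_test`
#' or `class_diff`) of two sets of model records, or directly on two numeric
#' vectors -- the comparison used between experimental variants (spiked vs
#' non-spiked, upstream-only vs both regions, ...).
#'
#' @param records_a,records_b `model_records` lists, data.frames, or numeric
#'   vectors.
#' @param metric column/field to compare when records are given.
#' @return list: ks_statistic, p_value, n_a, n_b.
#' @export
compare_distributions <- function(records_a, records_b, metric = "prauc_test") {
  pull <- function(r) {
    if (is.numeric(r)) return(r)
    df <- if (is.data.frame(r)) r else as.data.frame.model_records(r)
    v <- df[[metric]]
    if (is.null(v)) stop("unknown metric '", metric, "'")
    v[!is.na(v)]
  }
  a <- pull(records_a)
  b <- pull(records_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 records per side")
  kt <- suppressWarnings(ks.test(a, b))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}

.effect_formulas <- list(
  class_diff = "class_diff ~ cl * dl + pl + du + (1 | fl)",
  prauc_test = "prauc_test ~ cl * dl * pl + dr + (1 | fl)"
)

#' Mixed-effects model of hyperparameter effects
#'
#' Fits the comparative models of grid performance: for the class-accuracy
#' difference, `diff ~ cl * dl + pl + du + (1|fl)` with Gamma errors; for the
#' test prAUC, `prauc ~ cl * dl * pl + dr + (1|fl)` with binomial errors --
#' plus a beta-family alternative (via glmmTMB) since a binomial family for a
#' continuous proportion is unusual. `cl`/`dl` are the numbers of
#' convolutional/dense layers, `pl` the pool stride, `du` the dense units,
#' `dr` the dropout rate; the first convolutional layer's filter count `fl`
#' is the random intercept. When the random effect is inestimable (or lme4
#' fails), a fixed-effects-only GLM is fitted instead and flagged.
#'
#' @param records `model_records` or a data.frame with columns cl, dl, pl,
#'   du, dr, fl and the response.
#' @param response `"class_diff"` or `"prauc_test"`.
#' @param family `"gamma"`, `"binomial"` or `"beta"`. Defaults to the family
#'   matching the response (gamma for class_diff, binomial for prauc_test).
#' @return an `effect_model` list: coefficients (estimate, p-value from a
#'   type-II analysis-of-deviance where available), family, fallback flag,
#'   and the fitted object.
#' @export
fit_effect_model <- function(records,
                             response = c("class_diff", "prauc_test"),
                             family = NULL) {
  response <- match.arg(response)
  df <- if (is.data.frame(records)) records
        else as.data.frame.model_records(records)
  need <- c("cl", "dl", "pl", "du", "dr", "fl", response)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  if (is.null(family))
    family <- if (response == "class_diff") "gamma" else "binomial"
  family <- match.arg(family, c("gamma", "binomial", "beta"))

  fixed_rhs <- if (response == "class_diff") "cl * dl + pl + du"
               else "cl * dl * pl + dr"
  mm <- model.matrix(as.formula(paste("~", fixed_rhs)), df)
  if (qr(mm)$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr(mm)$pivot[-seq_len(qr(mm)$rank)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  y <- df[[response]]
  note <- NULL
  if (family == "gamma" && any(y <= 0)) {
    # Gamma needs a strictly positive response; a class difference of
    # exactly zero is nudged to half the smallest positive value
    eps <- min(y[y > 0], 1) / 2
    df[[response]][y <= 0] <- eps
    note <- sprintf("%d non-positive responses shifted to %.3g for the Gamma fit",
                    sum(y <= 0), eps)
  }
  fam_obj <- switch(family,
                    gamma = Gamma(link = "log"),
                    binomial = binomial(),
                    beta = NULL)
  full_formula <- as.formula(paste(response, "~", fixed_rhs, "+ (1 | fl)"))

  fit <- NULL
  fallback <- FALSE
  if (family == "beta") {
    if (!requireNamespace("glmmTMB", quietly = TRUE))
      stop("family = 'beta' requires the glmmTMB package")
    yb <- pmin(pmax(df[[response]], 1e-4), 1 - 1e-4)
    df[[response]] <- yb
    fit <- try(glmmTMB::glmmTMB(full_formula, data = df,
                                family = glmmTMB::beta_family()),
               silent = TRUE)
  } else {
    fit <- try(suppressWarnings(suppressMessages(
      lme4::glmer(full_formula, data = df, family = fam_obj))),
      silent = TRUE)
    if (!inherits(fit, "try-error") && lme4::isSingular(fit))
      note <- c(note, "random-effect variance estimated at zero (singular fit)")
  }
  if (inherits(fit, "try-error") || is.null(fit)) {
    fallback <- TRUE
    fit <- suppressWarnings(glm(
      as.formula(paste(response, "~", fixed_rhs)), data = df,
      family = if (family == "beta") binomial() else fam_obj))
    note <- c(note, "mixed model inestimable; fixed-effects-only GLM fitted")
  }
  est <- if (inherits(fit, "glmmTMB")) glmmTMB::fixef(fit)$cond
         else if (fallback) coef(fit) else lme4::fixef(fit)
  pvals <- tryCatch({
    an <- suppressWarnings(car::Anova(fit, type = 2))
    setNames(an[["Pr(>Chisq)"]], rownames(an))
  }, error = function(e) NULL)
  structure(list(coefficients = est, anova_p = pvals, family = family,
                 formula = full_formula, fallback = fallback, note = note,
                 fit = fit),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>", deparse(x$formula), "| family:", x$family,
      if (x$fallback) "(fixed-effects fallback)" else "", "\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$anova_p)) {
    cat("type-II p-values:\n")
    print(signif(x$anova_p, 3))
  }
  for (n in x$note) cat("note:", n, "\n")
  invisible(x)
}

#' Rank-sum comparison of motif counts by prediction correctness
#'
#' Two-sided Wilcoxon rank-sum test of the per-gene discovered-motif counts
#' of correctly vs incorrectly predicted genes.
#'
#' @param correct_counts,incorrect_counts numeric vectors of per-gene counts.
#' @return list: statistic, p_value, note (set when the input is
#'   ties-only/degenerate).
#' @export
rank_sum_motif_comparison <- function(correct_counts, incorrect_counts) {
  if (!length(correct_counts) || !length(incorrect_counts))
    stop("both groups must be nonempty")
  note <- NULL
  if (length(unique(c(correct_counts, incorrect_counts))) == 1L)
    note <- "all counts tied; test degenerate, p reported as 1"
  wt <- suppressWarnings(wilcox.test(correct_counts, incorrect_counts,
                                     alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p, note = note)
}
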