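# Phenotype models of hybrid dysgenesis: multinomial ovary-count and
# Poisson ovariole regressions, likelihood-ratio and type-III term tests,
# stepwise simplification, Fisher-Pitman permutation inference, deviance
# explained (D-squared) and bootstrap model comparison.

#' Round half away from zero / round up
#'
#' Rounding used for non-integer mean ovariole counts before Poisson
#' fitting: `"nearest"` rounds half-up, `"up"` takes the ceiling.
#'
#' @param x Numeric vector.
#' @param mode `"nearest"` or `"up"`.
#' @return Integer vector.
#' @export
round_ovarioles <- function(x, mode = c("nearest", "up")) {
  mode <- match.arg(mode)
  as.integer(if (mode == "nearest") floor(x + 0.5) else ceiling(x))
}

new_hd_fit <- function(family, formula, fit, null_deviance, n,
                       separation = FALSE) {
  ll <- as.numeric(logLik(fit))
  edf <- attr(logLik(fit), "df")
  structure(list(
    family = family, formula = formula,
    terms = attr(terms(formula), "term.labels"),
    coefficients = coef(fit),
    log_likelihood = ll, edf = edf,
    null_deviance = null_deviance,
    residual_deviance = fit$deviance,
    df_residual = n - edf, n = n,
    converged = if (!is.null(fit$converged)) fit$converged else
      is.null(fit$convergence) || fit$convergence == 0,
    separation = separation, fit = fit), class = "hd_fit")
}

#' @export
print.hd_fit <- function(x, ...) {
  cat(x$family, "fit:", deparse(x$formula), "\n")
  cat("  n =", x$n, " logLik =", round(x$log_likelihood, 2),
      " deviance =", round(x$residual_deviance, 2),
      "(null", paste0(round(x$null_deviance, 2), ")"), "\n")
  if (x$separation) cat("  note: separation detected; ridge-penalised fit\n")
  if (!x$converged) cat("  warning: fit did not converge\n")
  invisible(x)
}

prepare_pheno <- function(records) {
  df <- as.data.frame(records)
  if (!is.null(df$ovary_count))
    df$ovary_count <- factor(as.character(df$ovary_count),
                             levels = c("2", "0", "1"))
  if (is.null(df$cross) && !is.null(df$mother_genotype) &&
      !is.null(df$father_pe_cn))
    df$cross <- paste0(df$mother_genotype, "x",
                       ifelse(df$father_pe_cn >= 0.5, "P", "M"))
  df
}

#' Fit a 3-category multinomial ovary-count model
#'
#' Maximum-likelihood multinomial logistic regression of the number of
#' ovaries (0/1/2) with reference category "2 ovaries" (healthy), so
#' negative logit shifts read as dysgenesis. Complete separation (for
#' example every P-mother female having two ovaries) is detected from
#' exploding coefficients and handled by refitting with a small ridge
#' penalty; the fit is flagged, never silently dropped. Non-convergence is
#' likewise flagged rather than raised.
#'
#' @param records Phenotype data.frame (`ovary_count` in 0/1/2).
#' @param formula Model formula, e.g.
#'   `ovary_count ~ mother_genotype * father_pe_cn`.
#' @param ridge Ridge (weight decay) used for the separation fallback.
#' @return An object of class `hd_fit`.
#' @export
fit_multinomial <- function(records, formula, ridge = 1e-4) {
  df <- prepare_pheno(records)
  resp <- all.vars(formula)[1]
  if (!all(levels(df[[resp]]) %in% c("2", "0", "1")))
    stop("multinomial response must be ovary counts in {0,1,2}")
  n <- nrow(df)
  df$.w <- 1
  degenerate <- length(unique(df[[resp]])) < 2
  if (degenerate) {
    # all females in one category (e.g. every P-mother female with two
    # ovaries): complete separation by construction. Anchor the remaining
    # categories with near-zero-weight pseudo-records so the penalised
    # fit exists; flagged below.
    pseudo <- df[rep(1L, nlevels(df[[resp]])), , drop = FALSE]
    pseudo[[resp]] <- factor(levels(df[[resp]]), levels = levels(df[[resp]]))
    pseudo$.w <- 1e-3
    df <- rbind(df, pseudo)
  }
  fit <- nnet::multinom(formula, data = df, weights = .w, trace = FALSE,
                        maxit = 500, Hess = TRUE)
  separation <- degenerate || any(abs(coef(fit)) > 15)
  if (separation)
    fit <- nnet::multinom(formula, data = df, weights = .w, trace = FALSE,
                          maxit = 500, Hess = TRUE, decay = ridge)
  null_fit <- nnet::multinom(
    update(formula, . ~ 1), data = df, weights = .w, trace = FALSE,
    maxit = 500)
  new_hd_fit("multinomial", formula, fit,
             null_deviance = null_fit$deviance, n = n,
             separation = separation)
}

#' Fit a log-link Poisson ovariole model
#'
#' Poisson regression of the rounded mean number of ovarioles per ovary.
#' Females with both ovaries atrophied carry no ovariole information and
#' are excluded (missing response), matching their treatment as missing
#' data in ovariole models while remaining full data for ovary-count
#' models.
#'
#' @param records Phenotype data.frame.
#' @param formula Model formula with `mean_ovarioles` (rounded internally)
#'   or any integer response on the left.
#' @param rounding Rounding mode for non-integer mean ovarioles
#'   ([round_ovarioles()]).
#' @return An object of class `hd_fit`.
#' @export
fit_poisson <- function(records, formula, rounding = c("nearest", "up")) {
  rounding <- match.arg(rounding)
  df <- prepare_pheno(records)
  resp <- all.vars(formula)[1]
  if (is.null(df[[resp]])) stop("response ", resp, " not found")
  df <- df[!is.na(df[[resp]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no usable records (all responses missing)")
  df[[resp]] <- round_ovarioles(df[[resp]], rounding)
  fit <- glm(formula, data = df, family = poisson())
  out <- new_hd_fit("poisson", formula, fit,
                    null_deviance = fit$null.deviance, n = nrow(df))
  if (all(df[[resp]] == 0)) out$converged <- FALSE
  out
}

#' Likelihood-ratio test of nested model fits
#'
#' `chi2 = 2 * (logLik(full) - logLik(reduced))` with degrees of freedom
#' equal to the parameter-count difference and the P value from the
#' upper chi-squared tail. Identical models give chi2 = 0, P = 1.
#'
#' @param full,reduced Nested `hd_fit` objects on the same records.
#' @return An object of class `hd_lrt`: list(chi2, df, p).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "hd_fit"), inherits(reduced, "hd_fit"))
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested (reduced terms not a subset)")
  if (full$n != reduced$n)
    stop("models were fitted to different numbers of records")
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$edf - reduced$edf
  p <- if (df <= 0) {
    if (chi2 <= 1e-8) 1 else 0
  } else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "hd_lrt")
}

#' @export
print.hd_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, P = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Type-III term tests by likelihood ratio
#'
#' Tests each model term by comparing the full model against the model
#' with that term deleted, respecting marginality: a main effect is never
#' deleted while one of its interactions remains, so non-deletable terms
#' are reported with `deletable = FALSE` and a missing P value.
#'
#' @param records Phenotype data.frame.
#' @param formula Full model formula.
#' @param family `"multinomial"` or `"poisson"`.
#' @param ... Passed to the fitter.
#' @return A data.frame: term, chi2, df, p, deletable.
#' @export
type3_terms <- function(records, formula,
                        family = c("poisson", "multinomial"), ...) {
  family <- match.arg(family)
  fitter <- if (family == "poisson") fit_poisson else fit_multinomial
  full <- fitter(records, formula, ...)
  labels <- attr(terms(formula), "term.labels")
  deletable <- drop.scope(formula)
  rows <- lapply(labels, function(tm) {
    if (!tm %in% deletable)
      return(data.frame(term = tm, chi2 = NA_real_, df = NA_integer_,
                        p = NA_real_, deletable = FALSE))
    red <- fitter(records, update(formula, paste0(". ~ . - ", tm)), ...)
    lr <- lrt(full, red)
    data.frame(term = tm, chi2 = lr$chi2, df = lr$df, p = lr$p,
               deletable = TRUE)
  })
  do.call(rbind, rows)
}

#' Stepwise maximum-likelihood model simplification
#'
#' Starting from the full model, repeatedly deletes the least significant
#' deletable term (highest-order interactions first, by marginality) whose
#' deletion P value exceeds `alpha`, refitting after each deletion, until
#' every remaining deletable term is significant.
#'
#' @param records Phenotype data.frame.
#' @param formula Full hierarchical model formula.
#' @param family `"multinomial"` or `"poisson"`.
#' @param alpha Retention threshold.
#' @param ... Passed to the fitter.
#' @return The final `hd_fit`, with a `history` attribute listing dropped
#'   terms and their P values.
#' @export
stepwise_simplify <- function(records, formula,
                              family = c("poisson", "multinomial"),
                              alpha = 0.05, ...) {
  family <- match.arg(family)
  fitter <- if (family == "poisson") fit_poisson else fit_multinomial
  current <- formula
  history <- data.frame(term = character(), p = numeric())
  repeat {
    fit <- fitter(records, current, ...)
    scope <- drop.scope(current)
    if (length(scope) == 0) break
    ps <- vapply(scope, function(tm) {
      red <- fitter(records, update(current, paste0(". ~ . - ", tm)), ...)
      lrt(fit, red)$p
    }, 0)
    worst <- which.max(ps)
    if (ps[worst] <= alpha) break
    history <- rbind(history,
                     data.frame(term = scope[worst], p = ps[worst]))
    current <- update(current, paste0(". ~ . - ", scope[worst]))
  }
  final <- fitter(records, current, ...)
  attr(final, "history") <- history
  final
}

# Standardised linear permutation statistic for group-label permutation of
# scores `a` with group-1 indicator of size n1.
perm_zstat <- function(a, idx1) {
  N <- length(a); n1 <- length(idx1)
  T1 <- sum(a[idx1])
  mu <- n1 * mean(a)
  v <- n1 * (N - n1) / (N * (N - 1)) * sum((a - mean(a))^2)
  if (v <= 0) return(0)
  (T1 - mu) / sqrt(v)
}

#' Two-sample Fisher-Pitman permutation test
#'
#' Permutation test of equality of distributions based on the standardised
#' difference of group sums under random relabelling. With 10 or fewer
#' observations in total all label assignments are enumerated exactly;
#' otherwise a Monte-Carlo sample of permutations is used, with the
#' add-one P estimate. The Bonferroni-adjusted threshold for the six
#' pairwise cross comparisons is exported as [HD_ALPHA] and applied by the
#' caller.
#'
#' @param x,y Numeric samples.
#' @param n_permutations Monte-Carlo permutations (ignored for exact
#'   enumeration; must be at least 100 otherwise).
#' @param seed Optional RNG seed.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default: exact iff `length(x) + length(y) <= 10`.
#' @return An object of class `hd_perm`: list(statistic = observed Z,
#'   n_permutations, p, method).
#' @export
fisher_pitman <- function(x, y, n_permutations = 10000, seed = NULL,
                          exact = NULL) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (!is.null(seed)) set.seed(seed)
  a <- c(x, y)
  N <- length(a); n1 <- length(x)
  if (is.null(exact)) exact <- N <= 10
  z_obs <- perm_zstat(a, seq_len(n1))
  eps <- 1e-12
  if (exact) {
    sets <- combn(N, n1)
    zs <- apply(sets, 2, function(ix) perm_zstat(a, ix))
    p <- mean(abs(zs) >= abs(z_obs) - eps)
    method <- "exact"
    B <- ncol(sets)
  } else {
    if (n_permutations < 100)
      stop("n_permutations must be at least 100 for Monte-Carlo mode")
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (abs(perm_zstat(a, sample.int(N, n1))) >= abs(z_obs) - eps)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_permutations + 1)
    method <- "monte-carlo"
    B <- n_permutations
  }
  structure(list(statistic = z_obs, n_permutations = B, p = min(p, 1),
                 method = method), class = "hd_perm")
}

#' @export
print.hd_perm <- function(x, ...) {
  cat(sprintf("permutation test (%s, B = %d): Z = %.3f, P = %.4g\n",
              x$method, x$n_permutations, x$statistic, x$p))
  invisible(x)
}

#' Compare reproductive-senescence models with and without an age-by-cross
#' interaction
#'
#' Fits two Poisson models of rounded mean ovarioles - `~ age + cross`
#' and `~ age * cross` - and tests the age-by-cross interaction (whether
#' crosses differ in their rate of ovariole loss with age) by likelihood
#' ratio. Per-cross slopes and intercepts are reported as contrasts
#' against the reference cross.
#'
#' @param records Phenotype data.frame spanning at least 2 crosses and 2
#'   ages; a `cross` column is derived from `mother_genotype` and paternal
#'   copy number when absent.
#' @param rounding Rounding mode for mean ovarioles.
#' @return A list: `model1` (with interaction), `model2` (without),
#'   `lrt`, and `slopes` - data.frame of per-cross age slopes and
#'   intercepts on the log scale.
#' @export
senescence_compare <- function(records, rounding = "nearest") {
  df <- prepare_pheno(records)
  if (is.null(df$cross)) stop("records need a cross column (or mother_genotype + father_pe_cn)")
  if (length(unique(df$cross)) < 2) stop("need at least 2 crosses")
  if (length(unique(df$age)) < 2) stop("need at least 2 ages")
  m1 <- fit_poisson(df, mean_ovarioles ~ age * cross, rounding = rounding)
  m2 <- fit_poisson(df, mean_ovarioles ~ age + cross, rounding = rounding)
  lr <- lrt(m1, m2)
  cf <- coef(m1$fit)
  crosses <- sort(unique(df$cross))
  ref <- crosses[1]
  pick <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  slopes <- data.frame(
    cross = crosses,
    intercept = vapply(crosses, function(cc)
      cf[["(Intercept)"]] +
        if (cc == ref) 0 else pick(paste0("cross", cc)), 0),
    slope = vapply(crosses, function(cc)
      cf[["age"]] +
        if (cc == ref) 0 else pick(paste0("age:cross", cc)), 0),
    row.names = NULL)
  list(model1 = m1, model2 = m2, lrt = lr, slopes = slopes)
}

#' Deviance explained (D-squared)
#'
#' GLM analogue of R-squared:
#' `(null deviance - residual deviance) / null deviance`.
#'
#' @param fit An `hd_fit`.
#' @return Fraction in [0, 1]; `NA` (with a warning) when the null
#'   deviance is zero.
#' @export
dsquared <- function(fit) {
  stopifnot(inherits(fit, "hd_fit"))
  if (fit$null_deviance <= 0) {
    warning("null deviance is zero; D-squared undefined")
    return(NA_real_)
  }
  (fit$null_deviance - fit$residual_deviance) / fit$null_deviance
}

#' Bootstrap D-squared distributions and compare two models
#'
#' Resamples each dataset with replacement (`n_boot` times, original
#' sample size), refits its model, and collects the D-squared values; the
#' two bootstrap distributions are then compared with a two-sided
#' permutation Wilcoxon rank-sum test (rank statistic, label
#' permutation).
#'
#' @param records_a,records_b Phenotype data.frames.
#' @param formula_a,formula_b Model formulas.
#' @param family `"poisson"` or `"multinomial"` (applies to both models).
#' @param n_boot Bootstrap replicates per model (at least 100).
#' @param n_permutations Label permutations for the rank test.
#' @param seed Optional RNG seed.
#' @return An `hd_perm` with extra elements `d2_a` and `d2_b` (bootstrap
#'   distributions) and `observed = median difference`.
#' @export
bootstrap_r2_compare <- function(records_a, formula_a, records_b, formula_b,
                                 family = c("poisson", "multinomial"),
                                 n_boot = 500, n_permutations = 2000,
                                 seed = NULL) {
  family <- match.arg(family)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  fitter <- if (family == "poisson") fit_poisson else fit_multinomial
  boot_d2 <- function(records, formula) {
    n <- nrow(records)
    vapply(seq_len(n_boot), function(b) {
      res <- records[sample.int(n, n, replace = TRUE), , drop = FALSE]
      dsquared(fitter(res, formula))
    }, 0)
  }
  d2_a <- boot_d2(records_a, formula_a)
  d2_b <- boot_d2(records_b, formula_b)
  a <- rank(c(d2_a, d2_b))
  N <- length(a); n1 <- length(d2_a)
  z_obs <- perm_zstat(a, seq_len(n1))
  hits <- 0L
  for (b in seq_len(n_permutations))
    if (abs(perm_zstat(a, sample.int(N, n1))) >= abs(z_obs) - 1e-12)
      hits <- hits + 1L
  out <- structure(list(statistic = z_obs, n_permutations = n_permutations,
                        p = (hits + 1) / (n_permutations + 1),
                        method = "permutation-wilcoxon",
                        d2_a = d2_a, d2_b = d2_b,
                        observed = median(d2_a) - median(d2_b)),
                   class = "hd_perm")
  out
}

#' Per-cross summary of dysgenesis phenotypes
#'
#' For every (maternal cytotype, paternal element class, temperature)
#' combination: the 0/1/2 ovary-count distribution, the dysgenic fraction
#' (females with at least one atrophied ovary), and the mean and SD of
#' mean ovarioles among females with at least one functional ovary.
#'
#' @param records Phenotype data.frame.
#' @return A data.frame with one row per cross condition.
#' @export
hd_summary <- function(records) {
  df <- prepare_pheno(records)
  df$father_class <- if (is.null(df$father_pe_cn)) "unknown" else
    ifelse(df$father_pe_cn >= 0.5, "P", "M")
  key <- interaction(df$mother_genotype, df$father_class, df$temperature,
                     drop = TRUE, sep = "|")
  rows <- lapply(levels(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    oc <- as.integer(as.character(g$ovary_count))
    data.frame(mother_genotype = parts[1], father_class = parts[2],
               temperature = as.numeric(parts[3]), n = nrow(g),
               n_ovary0 = sum(oc == 0), n_ovary1 = sum(oc == 1),
               n_ovary2 = sum(oc == 2),
               dysgenic_fraction = mean(oc <= 1),
               mean_ovarioles = mean(g$mean_ovarioles, na.rm = TRUE),
               sd_ovarioles = sd(g$mean_ovarioles, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
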