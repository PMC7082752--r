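# All-subsets OLS of cluster dispersion on Big Five traits: BIC model
# selection plus two Monte Carlo null procedures (min-BIC over the
# model family, and same-model BIC) yielding p_FWER(all) and p(same).

#' z-score a vector
#'
#' Centers and scales to sample mean 0, sample SD 1 (n - 1
#' denominator).
#'
#' @param v Numeric vector, length >= 2, positive variance.
#' @return The standardized vector.
#' @export
zscore <- function(v) {
  if (length(v) < 2L) stop_invalid("zscore needs length >= 2")
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop_invalid("zscore: zero variance")
  (v - mean(v)) / s
}

#' Enumerate all nonempty predictor subsets
#'
#' All `2^m - 1` nonempty subsets of the factor labels, in canonical
#' order: by subset size, then lexicographically in the given factor
#' order.  For the five Big Five factors this yields 31 candidate
#' models.
#'
#' @param factors Character vector of predictor labels.
#' @return List of character vectors.
#' @export
enumerate_subsets <- function(factors = big_five_factors()) {
  m <- length(factors)
  out <- list()
  for (size in seq_len(m)) {
    combos <- utils::combn(m, size)
    out <- c(out, lapply(seq_len(ncol(combos)),
                         function(j) factors[combos[, j]]))
  }
  out
}

# Minimal OLS on a prepared design (z-scored y, z-scored predictor
# columns, intercept added here).  Returns the pieces every caller
# needs; used by both the reporting fit and the Monte Carlo loops.
.ols_core <- function(yz, Xz) {
  X <- cbind(`(Intercept)` = 1, Xz)
  fit <- .lm.fit(X, yz)
  if (fit$rank < ncol(X)) stop_invalid("collinear predictors: design is rank deficient")
  coef <- fit$coefficients
  coef[fit$pivot] <- coef # undo any pivoting
  list(coef = coef, rss = sum(fit$residuals^2), X = X)
}

# Gaussian concentrated-likelihood BIC: n*log(rss/n) + p*log(n), with
# p = number of regression coefficients including the intercept.  Any
# affine-consistent BIC convention produces the same model ranking,
# which is all the selection procedure uses.
.bic <- function(rss, n, n_coef) {
  if (rss <= 0) stop_invalid("BIC undefined: residual sum of squares is 0")
  n * log(rss / n) + n_coef * log(n)
}

#' BIC of a fitted model
#'
#' Gaussian concentrated-likelihood form `n*log(rss/n) + p*log(n)`
#' with `p = |subset| + 1` (the intercept is counted).
#'
#' @param fit A `model_fit` from [fit_ols()].
#' @return The BIC (lower is better).
#' @export
bic_of <- function(fit) {
  .bic(fit$rss, fit$n, length(fit$subset) + 1L)
}

#' Fit one predictor subset by OLS
#'
#' Regresses the z-scored outcome on the z-scored selected predictors
#' plus an intercept.  Coefficient standard errors, t statistics and
#' two-sided p-values use `n - |subset| - 1` degrees of freedom.
#'
#' @param y Outcome vector (z-scored internally).
#' @param predictors Numeric matrix or data.frame with named columns
#'   (z-scored internally).
#' @param subset Character vector of predictor names to include.
#' @return List of class `model_fit`: `subset`, `intercept`, `betas`,
#'   `std_errors`, `t_stats`, `p_values`, `rss`, `n`, `df`, `bic`.
#' @export
fit_ols <- function(y, predictors, subset) {
  X <- as.matrix(as.data.frame(predictors)[, subset, drop = FALSE])
  n <- length(y)
  if (!length(subset)) stop_invalid("subset must be nonempty")
  if (n != nrow(X)) stop_invalid("y and predictors must have equal length")
  if (n <= length(subset) + 1L) {
    stop_invalid("need n > number of parameters")
  }
  yz <- zscore(y)
  Xz <- apply(X, 2L, zscore)
  core <- .ols_core(yz, Xz)
  n_coef <- length(subset) + 1L
  df <- n - n_coef
  sigma2 <- core$rss / df
  XtX_inv <- solve(crossprod(core$X))
  se <- sqrt(sigma2 * diag(XtX_inv))
  betas <- core$coef
  t_stats <- betas / se
  p_values <- 2 * pt(-abs(t_stats), df)
  fit <- list(subset = subset,
              intercept = unname(betas[1L]),
              betas = setNames(betas[-1L], subset),
              std_errors = setNames(se[-1L], subset),
              t_stats = setNames(t_stats[-1L], subset),
              p_values = setNames(p_values[-1L], subset),
              rss = core$rss, n = n, df = df)
  fit$bic <- .bic(core$rss, n, n_coef)
  class(fit) <- "model_fit"
  fit
}

# Fast path used inside the Monte Carlo loops: BICs of many subsets on
# an already z-scored design, skipping SE/t/p bookkeeping.
.bic_all_subsets <- function(yz, Xz, subsets) {
  n <- length(yz)
  vapply(subsets, function(s) {
    fit <- .lm.fit(cbind(1, Xz[, s, drop = FALSE]), yz)
    .bic(sum(fit$residuals^2), n, length(s) + 1L)
  }, numeric(1L))
}

.trait_design <- function(traits, factors) {
  validate_trait_table(traits)
  X <- as.matrix(traits[factors])
  apply(X, 2L, zscore)
}

#' Select the minimum-BIC predictor subset
#'
#' Fits all `2^m - 1` subsets of the trait factors on z-scored data
#' and returns the fit with the lowest BIC.  Exact ties are broken in
#' favor of the smaller subset, then canonical order.
#'
#' @param y Dispersion vector (one value per participant).
#' @param traits Trait table aligned with `y`.
#' @param factors Predictor labels (default the five Big Five
#'   factors).
#' @return List with `optimal` (a `model_fit`) and `fits` (all
#'   subsets, canonical order).
#' @export
select_optimal <- function(y, traits, factors = big_five_factors()) {
  subsets <- enumerate_subsets(factors)
  fits <- lapply(subsets, function(s) fit_ols(y, traits[factors], s))
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  list(optimal = fits[[which.min(bics)]], fits = fits)
}

# One randomization of the outcome under the null: a uniform random
# permutation (breaks the trait link, preserves both marginals), or a
# parametric Gaussian resample with the sample mean and SD.
.randomize_y <- function(y, method) {
  if (method == "permute") sample(y) else rnorm(length(y), mean(y), sd(y))
}

#' Null distribution of minimum BIC over the model family
#'
#' Randomizes the outcome, fits all subsets, and stores the minimum
#' BIC regardless of which model attains it; repeated `n_iter` times.
#' Comparing an observed optimal BIC against this distribution
#' controls the family-wise error inflated by having searched the
#' whole model family (p_FWER(all)).
#'
#' @param y Dispersion vector.
#' @param traits Trait table aligned with `y`.
#' @param n_iter Number of Monte Carlo iterations (>= 1).
#' @param seed Integer seed.
#' @param method `"permute"` (default) or `"parametric"`.
#' @param factors Predictor labels.
#' @return Numeric vector of `n_iter` minimum BICs.
#' @export
null_min_bic <- function(y, traits, n_iter = 1000L, seed = NULL,
                         method = c("permute", "parametric"),
                         factors = big_five_factors()) {
  method <- match.arg(method)
  if (n_iter < 1L) stop_invalid("n_iter must be >= 1")
  Xz <- .trait_design(traits, factors)
  subsets <- enumerate_subsets(factors)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_iter), function(i) {
    yz <- zscore(.randomize_y(y, method))
    min(.bic_all_subsets(yz, Xz, subsets))
  }, numeric(1L))
}

#' Null distribution of one model's BIC
#'
#' As [null_min_bic()], but each randomization refits only the given
#' predictor subset (typically the observed optimal model), yielding
#' the null distribution behind p(same).
#'
#' @inheritParams null_min_bic
#' @param subset Character vector naming the predictors of the model.
#' @return Numeric vector of `n_iter` BICs.
#' @export
null_same_model <- function(y, traits, subset, n_iter = 1000L,
                            seed = NULL,
                            method = c("permute", "parametric"),
                            factors = big_five_factors()) {
  method <- match.arg(method)
  if (n_iter < 1L) stop_invalid("n_iter must be >= 1")
  if (!length(subset) || !all(subset %in% factors)) {
    stop_invalid("subset must name predictors among: %s",
                 paste(factors, collapse = ", "))
  }
  Xz <- .trait_design(traits, factors)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_iter), function(i) {
    yz <- zscore(.randomize_y(y, method))
    .bic_all_subsets(yz, Xz, list(subset))
  }, numeric(1L))
}

#' Empirical p-value of an observed BIC
#'
#' Lower BIC is better, so the rejection region is the lower tail:
#' `p = (1 + #\{null <= observed\}) / (1 + n_iter)` with the default
#' add-one correction (which avoids p = 0); without it,
#' `p = #\{null <= observed\} / n_iter`.
#'
#' @param observed_bic Observed BIC.
#' @param null Numeric vector of null BICs.
#' @param add_one Apply the add-one correction (default TRUE).
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed_bic, null, add_one = TRUE) {
  if (!length(null)) stop_invalid("null distribution must be nonempty")
  hits <- sum(null <= observed_bic)
  if (add_one) (1 + hits) / (1 + length(null)) else hits / length(null)
}

#' Full model-selection report for one cluster
#'
#' Runs the all-subsets BIC selection and both Monte Carlo null
#' procedures, reporting the optimal model with p_FWER(all) (against
#' the min-BIC null) and p(same) (against the same-model null).  Both
#' null procedures use the same seed, hence identical randomization
#' streams, which makes p_FWER(all) >= p(same) hold replicate by
#' replicate.
#'
#' @param y Dispersion vector.
#' @param traits Trait table aligned with `y`.
#' @param cluster_label Label carried into the report.
#' @param n_iter Monte Carlo iterations per null (default 1000).
#' @param seed Integer seed.
#' @param method Randomization scheme, `"permute"` or `"parametric"`.
#' @param add_one Add-one correction for the empirical p-values.
#' @return List of class `selection_report`.
#' @export
trait_model_selection <- function(y, traits, cluster_label = "cluster",
                                  n_iter = 1000L, seed = NULL,
                                  method = c("permute", "parametric"),
                                  add_one = TRUE) {
  method <- match.arg(method)
  sel <- select_optimal(y, traits)
  null_all <- null_min_bic(y, traits, n_iter = n_iter, seed = seed,
                           method = method)
  null_same <- null_same_model(y, traits, sel$optimal$subset,
                               n_iter = n_iter, seed = seed,
                               method = method)
  structure(list(
    cluster_label = cluster_label,
    fits = sel$fits,
    optimal = sel$optimal,
    null_min_bic = null_all,
    null_same_model_bic = null_same,
    p_fwer_all = empirical_p(sel$optimal$bic, null_all, add_one),
    p_same = empirical_p(sel$optimal$bic, null_same, add_one),
    n_iter = n_iter, method = method, seed = seed
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model selection for %s (n = %d, %d models)\n",
              x$cluster_label, x$optimal$n, length(x$fits)))
  cat(sprintf("  optimal subset: {%s}, BIC = %.3f\n",
              paste(x$optimal$subset, collapse = ", "), x$optimal$bic))
  for (f in x$optimal$subset) {
    cat(sprintf("    %s: beta = %.3f, SE = %.3f, t = %.2f, p = %.4g\n",
                f, x$optimal$betas[[f]], x$optimal$std_errors[[f]],
                x$optimal$t_stats[[f]], x$optimal$p_values[[f]]))
  }
  cat(sprintf("  p_FWER(all) = %.4g, p(same) = %.4g  [%s null, %d iter]\n",
              x$p_fwer_all, x$p_same, x$method, x$n_iter))
  invisible(x)
}
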