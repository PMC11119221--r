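#' Akaike and Schwarz information criteria
#'
#' `AIC = -2 LL + 2 k` and `BIC = -2 LL + k ln(N)` for a maximized
#' log-likelihood `LL`, parameter count `k` and `N` observations. Lower is
#' better; for `N > e^2` (about 7.39) the BIC penalty per parameter exceeds
#' the AIC penalty, making BIC the more stringent criterion.
#'
#' @param loglik Maximized log-likelihood (nats).
#' @param n_params Number of estimated parameters, `>= 1`.
#' @param n_obs Number of observations, `>= 1`.
#' @return A list with components `aic` and `bic`; both `NA` when `loglik`
#'   is not finite.
#' @examples
#' informationCriteria(-100, 3, 100)
#' @export
informationCriteria <- function(loglik, n_params, n_obs) {
  if (n_params < 1 || n_obs < 1)
    stop("n_params and n_obs must be >= 1", call. = FALSE)
  if (!is.finite(loglik)) return(list(aic = NA_real_, bic = NA_real_))
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(n_obs))
}

# Select the model's columns, coerce character/logical predictors to factors
# (treatment coding, reference = first level in sorted order), and listwise
# delete. Used once per exploration so all candidates see identical rows.
prepareData <- function(data, vars) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- data[, vars, drop = FALSE]
  for (v in names(d)) {
    if (is.character(d[[v]]) || is.logical(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.factor(d[[v]])) d[[v]] <- droplevels(d[[v]])
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no complete rows left after listwise deletion", call. = FALSE)
  rownames(d) <- NULL
  d
}

# fixed-effect design matrix of a candidate (intercept always included)
.fixed_design <- function(m, data) {
  rhs <- if (length(m$term_order)) paste(m$term_order, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("~", rhs), env = globalenv())
  stats::model.matrix(fml, data = data)
}

.new_fit <- function(m, loglik, n_params, n_obs, converged, singular,
                     message = "") {
  ic <- informationCriteria(loglik, n_params, n_obs)
  structure(
    list(model = m, formula = renderFormula(m), loglik = loglik,
         n_params = n_params, n_obs = n_obs, aic = ic$aic, bic = ic$bic,
         converged = converged, singular = singular, message = message),
    class = "mlm_fit"
  )
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("<mlm_fit> ", x$formula, "\n", sep = "")
  cat(sprintf("  logLik %.4f  AIC %.4f  BIC %.4f  (k = %d, N = %d)\n",
              x$loglik, x$aic, x$bic, x$n_params, x$n_obs))
  if (!x$converged) cat("  ** did not converge: ", x$message, "\n", sep = "")
  if (x$singular) cat("  ** singular fit (variance component at boundary)\n")
  invisible(x)
}

#' Maximum-likelihood fit of a fixed-effects-only candidate
#'
#' Ordinary least squares gives the ML solution for a Gaussian linear model:
#' `sigma^2` is estimated with the ML divisor `N` (not `N - p`), and the
#' maximized log-likelihood is `-(N/2) (ln(2 pi sigma^2) + 1)`. The parameter
#' count is `p + 1` (fixed coefficients after categorical expansion,
#' including the intercept, plus the residual variance).
#'
#' @param m A `mlm_formula` without a random part.
#' @param data Observation table; rows with missing values in the model's
#'   variables are dropped.
#' @return A `mlm_fit` (fields: `loglik`, `n_params`, `n_obs`, `aic`, `bic`,
#'   `converged`, `singular`, `message`).
#' @export
fitFixedOnly <- function(m, data) {
  validateModelFormula(m)
  if (m$has_random_intercept || length(m$random_slopes))
    stop("model has a random part; use fitLMM()", call. = FALSE)
  d <- prepareData(data, setdiff(.model_vars(m), NULL))
  X <- .fixed_design(m, d)
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient fixed-effect design matrix", call. = FALSE)
  if (n <= p)
    stop("not enough observations (N = ", n, ") for ", p,
         " fixed-effect coefficients", call. = FALSE)
  fit <- stats::lm(.as_r_formula(m), data = d)
  rss <- sum(stats::residuals(fit)^2)
  if (rss / n <= 1e-12 * max(1, mean(d[[m$response]]^2)))
    stop("zero residual variance (perfect fit); log-likelihood is unbounded",
         call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  .new_fit(m, loglik = ll, n_params = p + 1L, n_obs = n,
           converged = TRUE, singular = FALSE)
}

#' Maximum-likelihood fit of a linear mixed-effects candidate
#'
#' Maximizes the Gaussian marginal log-likelihood, with the random effects
#' integrated out: per-group covariance `Z_g Psi Z_g' + sigma^2 I`, `Psi`
#' unstructured (correlated intercept and slopes). Fitting is delegated to
#' [lme4::lmer()] with `REML = FALSE`, which profiles out the fixed effects
#' and `sigma^2` and optimizes the relative covariance factor; the fit is
#' deterministic for given data.
#'
#' The parameter count is `p + q(q+1)/2 + 1`: fixed coefficients after
#' categorical expansion (including the intercept), the free elements of the
#' `q x q` random-effect covariance (`q = 1 + ` number of slopes), and the
#' residual variance.
#'
#' A fit on the boundary of the variance-component space (a random-effect
#' variance estimated at zero, or a correlation at +/-1) is flagged
#' `singular = TRUE` using tolerance `1e-4` on the relative covariance
#' factor. Non-convergence is reported via `converged = FALSE` rather than
#' an error, so an exploration sweep never aborts.
#'
#' @param m A `mlm_formula` with a random part.
#' @param data Observation table.
#' @param reml Use REML instead of ML. REML log-likelihoods are not
#'   comparable across different fixed-effect sets; ranking under REML emits
#'   a warning in [exploreModels()].
#' @param control A [lme4::lmerControl()] object.
#' @return A `mlm_fit`.
#' @export
fitLMM <- function(m, data, reml = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")) {
  validateModelFormula(m)
  if (!m$has_random_intercept)
    stop("model has no random part; use fitFixedOnly()", call. = FALSE)
  d <- prepareData(data, .model_vars(m))
  d[[m$group]] <- factor(d[[m$group]])
  n_groups <- nlevels(d[[m$group]])
  if (n_groups < 2L)
    stop("grouping variable '", m$group, "' has fewer than 2 groups",
         call. = FALSE)
  X <- .fixed_design(m, d)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design matrix", call. = FALSE)
  p <- ncol(X)
  q <- 1L + length(m$random_slopes)
  min_g <- min(table(d[[m$group]]))
  if (min_g < q)
    warning("a group has fewer observations (", min_g,
            ") than random-effect dimensions (", q, ")", call. = FALSE)

  n_params <- as.integer(p + q * (q + 1L) / 2L + 1L)
  fit <- NULL
  msg <- ""
  withCallingHandlers(
    fit <- tryCatch(
      lme4::lmer(.as_r_formula(m), data = d, REML = reml, control = control),
      error = function(e) {
        msg <<- conditionMessage(e)
        NULL
      }
    ),
    warning = function(w) {
      msg <<- paste(msg, conditionMessage(w), sep = if (nzchar(msg)) "; " else "")
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit))
    return(.new_fit(m, loglik = NA_real_, n_params = n_params,
                    n_obs = nrow(d), converged = FALSE, singular = FALSE,
                    message = msg))
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 && length(conv_msgs) == 0L
  if (!converged && length(conv_msgs))
    msg <- paste(c(msg, unlist(conv_msgs)), collapse = "; ")
  .new_fit(m, loglik = as.numeric(stats::logLik(fit)), n_params = n_params,
           n_obs = nrow(d), converged = converged,
           singular = lme4::isSingular(fit, tol = 1e-4), message = msg)
}

#' Fit one candidate model (dispatching on its random part)
#'
#' @param m A `mlm_formula`.
#' @param data Observation table.
#' @param reml Passed to [fitLMM()]; ignored for fixed-only models.
#' @return A `mlm_fit`.
#' @export
fitCandidate <- function(m, data, reml = FALSE) {
  if (m$has_random_intercept) fitLMM(m, data, reml = reml)
  else fitFixedOnly(m, data)
}
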