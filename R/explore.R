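#' Fit and tabulate every candidate model
#'
#' The complete exploration sweep: rows with missingness in any variable of
#' the *full* model are dropped once, so every candidate is fit to identical
#' observations (information criteria are otherwise incomparable); candidates
#' are enumerated with [enumerateCandidates()] and each is fit by maximum
#' likelihood ([fitFixedOnly()] / [fitLMM()]). A failed or non-converged fit
#' never aborts the sweep; it is kept in the table with its flags set and
#' missing criteria.
#'
#' Work is partitioned by candidate index over `workers` processes and
#' reassembled in enumeration order, so the result is identical for any
#' worker count: parallelism is an implementation contract, not a semantics
#' change.
#'
#' @param data Observation table (data.frame) with the outcome, predictor and
#'   grouping columns.
#' @param full Full-model `mlm_formula` (see [parseFormula()]).
#' @param workers Number of worker processes, `>= 1`.
#' @param reml Fit by REML instead of ML. Criterion-based ranking across
#'   different fixed-effect sets is invalid under REML, so a warning is
#'   emitted.
#' @param ceiling,override Candidate-count guard, see
#'   [enumerateCandidates()].
#'
#' @return A `mlm_exploration`: a data.frame with one row per candidate in
#'   enumeration order (columns `formula`, `logLik`, `AIC`, `BIC`,
#'   `n_params`, `converged`, `singular`) and a `meta` attribute (full-model
#'   spec, N, group count, candidate count, worker count, elapsed seconds,
#'   package version).
#' @seealso [sortResult()], [bestModels()], [writeExploration()]
#' @export
exploreModels <- function(data, full, workers = 1L, reml = FALSE,
                          ceiling = 10000L, override = FALSE) {
  validateModelFormula(full)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("workers must be a positive integer", call. = FALSE)
  if (reml)
    warning("ranking models with different fixed effects by REML criteria ",
            "is statistically invalid; interpret with care", call. = FALSE)

  d <- prepareData(data, .model_vars(full))
  if (!is.null(full$group)) {
    d[[full$group]] <- factor(d[[full$group]])
    if (nlevels(d[[full$group]]) < 2L)
      stop("grouping variable '", full$group, "' is constant; random ",
           "effects need at least 2 groups", call. = FALSE)
  }
  cs <- enumerateCandidates(full, ceiling = ceiling, override = override)
  n_cand <- length(cs$candidates)

  fit_one <- function(i) {
    m <- cs$candidates[[i]]
    tryCatch(
      suppressWarnings(fitCandidate(m, d, reml = reml)),
      error = function(e) .new_fit(m, loglik = NA_real_,
                                   n_params = NA_integer_, n_obs = nrow(d),
                                   converged = FALSE, singular = FALSE,
                                   message = conditionMessage(e))
    )
  }

  t0 <- proc.time()[["elapsed"]]
  use_fork <- workers > 1L && .Platform$OS.type != "windows"
  fits <- if (use_fork) {
    parallel::mclapply(seq_len(n_cand), fit_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_cand), fit_one)
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  tab <- data.frame(
    formula   = vapply(fits, `[[`, character(1), "formula"),
    logLik    = vapply(fits, `[[`, numeric(1), "loglik"),
    AIC       = vapply(fits, `[[`, numeric(1), "aic"),
    BIC       = vapply(fits, `[[`, numeric(1), "bic"),
    n_params  = vapply(fits, function(x) as.integer(x$n_params), integer(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    singular  = vapply(fits, `[[`, logical(1), "singular"),
    stringsAsFactors = FALSE
  )
  n_obs <- unique(vapply(fits, `[[`, integer(1) + 0, "n_obs"))
  stopifnot(length(n_obs) == 1L)  # identical rows for every candidate

  attr(tab, "meta") <- list(
    full_formula = renderFormula(full),
    forced = full$forced,
    slope_candidates = full$random_slopes,
    group = full$group,
    n_obs = n_obs,
    n_groups = if (is.null(full$group)) 0L else nlevels(d[[full$group]]),
    n_candidates = n_cand,
    workers = workers,
    reml = reml,
    elapsed_sec = elapsed,
    version = as.character(utils::packageVersion("mlmexplore")),
    sorted_by = NA_character_
  )
  class(tab) <- c("mlm_exploration", "data.frame")
  tab
}

#' Exploration metadata
#'
#' @param t A `mlm_exploration`.
#' @return The meta list (full model, N, group count, candidate count,
#'   workers, elapsed time, version).
#' @export
explorationMeta <- function(t) attr(t, "meta")

.criterion_ok <- c("BIC", "AIC", "LL")

#' Sort an exploration table by an information criterion
#'
#' Ascending for AIC and BIC (lower is better), descending for the
#' log-likelihood. Rows whose criterion is missing (failed fits) are placed
#' last. Ties are broken by fewer parameters, then by the canonical formula
#' string; the sort is otherwise stable. The default criterion is BIC, the
#' more stringent of the two and the usual proxy for a Bayes factor.
#'
#' @param t A `mlm_exploration`.
#' @param criterion One of `"BIC"`, `"AIC"`, `"LL"`.
#' @return The sorted `mlm_exploration`.
#' @export
sortResult <- function(t, criterion = "BIC") {
  stopifnot(inherits(t, "mlm_exploration"), nrow(t) > 0L)
  criterion <- match.arg(toupper(criterion), .criterion_ok)
  key <- switch(criterion, BIC = t$BIC, AIC = t$AIC, LL = -t$logLik)
  ord <- order(is.na(key), key, t$n_params, t$formula)
  out <- t[ord, , drop = FALSE]
  rownames(out) <- NULL
  meta <- attr(t, "meta")
  meta$sorted_by <- criterion
  attr(out, "meta") <- meta
  class(out) <- class(t)
  out
}

#' Top-ranked candidate models
#'
#' The first `k` rows of [sortResult()]; `k` larger than the table simply
#' returns the whole sorted table.
#'
#' @param t A `mlm_exploration`.
#' @param k Number of models to return.
#' @param criterion Ranking criterion, see [sortResult()].
#' @return A `mlm_exploration` with at most `k` rows.
#' @export
bestModels <- function(t, k = 1L, criterion = "BIC") {
  stopifnot(k >= 1L)
  s <- sortResult(t, criterion)
  utils::head(s, min(k, nrow(s)))
}

#' @export
print.mlm_exploration <- function(x, digits = 4, max_rows = 20L, ...) {
  meta <- attr(x, "meta")
  cat("<mlm_exploration> ", nrow(x), " candidate models",
      if (!is.na(meta$sorted_by)) paste0(", sorted by ", meta$sorted_by),
      "\n", sep = "")
  cat("  full model: ", meta$full_formula, "\n", sep = "")
  cat("  N = ", meta$n_obs,
      if (meta$n_groups > 0L) paste0(", groups = ", meta$n_groups),
      "\n\n", sep = "")
  print.data.frame(utils::head(x, max_rows), digits = digits, row.names = TRUE)
  if (nrow(x) > max_rows) cat("  ... ", nrow(x) - max_rows, " more rows\n")
  invisible(x)
}

#' Write an exploration table to CSV (plus a JSON metadata sidecar)
#'
#' Criteria are written with six decimal places so result files are stable
#' across platforms.
#'
#' @param t A `mlm_exploration`.
#' @param csv_path Output CSV path.
#' @param meta_path Optional JSON sidecar path for the metadata.
#' @return `csv_path`, invisibly.
#' @export
writeExploration <- function(t, csv_path, meta_path = NULL) {
  stopifnot(inherits(t, "mlm_exploration"))
  out <- as.data.frame(t)
  for (col in c("logLik", "AIC", "BIC"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.6f", out[[col]]))
  utils::write.csv(out, csv_path, row.names = FALSE, quote = TRUE)
  if (!is.null(meta_path)) {
    meta <- attr(t, "meta")
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read an exploration table written by [writeExploration()]
#'
#' @param csv_path CSV path.
#' @param meta_path Optional JSON sidecar path.
#' @return A `mlm_exploration` (values at the six-decimal precision of the
#'   file).
#' @export
readExploration <- function(csv_path, meta_path = NULL) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = c(formula = "character"))
  for (col in c("logLik", "AIC", "BIC")) tab[[col]] <- as.numeric(tab[[col]])
  tab$n_params <- as.integer(tab$n_params)
  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(full_formula = NA_character_, n_obs = NA_integer_,
                    n_groups = NA_integer_, n_candidates = nrow(tab),
                    workers = NA_integer_, sorted_by = NA_character_)
  attr(tab, "meta") <- meta
  class(tab) <- c("mlm_exploration", "data.frame")
  tab
}
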