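#' Ground-truth generative specification for synthetic multi-group data
#'
#' Describes a linear mixed-effects data-generating process: per-group
#' random effects `b_g ~ N(0, Psi)` (intercept first, then slopes),
#' predictors drawn per `predictor_model`, and
#' `y = X beta + Z_g b_g + eps`, `eps ~ N(0, sigma^2)`. Used to emulate the
#' structure of multi-country survey datasets so the whole exploration
#' pipeline is testable without external downloads.
#'
#' @param n_groups Number of groups (e.g. countries), `>= 1`.
#' @param group_sizes Observations per group; a single count or a vector of
#'   length `n_groups`.
#' @param beta Named list (or numeric vector) of true coefficients. Must
#'   include `"(Intercept)"`. A numeric (standardized) predictor has a
#'   scalar coefficient; a categorical predictor has a vector of
#'   `levels - 1` coefficients (treatment coding against the first sorted
#'   level).
#' @param psi Random-effect covariance matrix (`q x q`, symmetric positive
#'   semi-definite) with dimnames `"(Intercept)"` followed by slope terms,
#'   or `NULL` for no random part. Slope terms must be numeric predictors
#'   named in `beta`.
#' @param sigma Residual standard deviation, `>= 0`.
#' @param predictor_model Named list giving each predictor's distribution:
#'   `list(type = "normal")` (standard normal, the default for any
#'   predictor not listed) or
#'   `list(type = "categorical", levels = ..., probs = ...)`.
#' @param response Name of the outcome column (default `"y"`).
#' @param group Name of the grouping column (default `"group"`, `NULL` for
#'   single-level data).
#' @param forced Names of the always-included covariates among the
#'   predictors (metadata for building the full model).
#' @param seed Integer seed; [simulateDataset()] is deterministic given it.
#' @param metadata Optional free-form list (e.g. the participant counts of
#'   the study a shape mirrors).
#'
#' @return A `mlm_simspec` object.
#' @seealso [simulateDataset()], [studyShapedSpec()], [simFullModel()]
#' @export
simSpec <- function(n_groups, group_sizes, beta, psi = NULL, sigma = 1,
                    predictor_model = list(), response = "y",
                    group = "group", forced = character(), seed = 1L,
                    metadata = list()) {
  beta <- as.list(beta)
  if (!"(Intercept)" %in% names(beta))
    stop("beta must include an '(Intercept)' coefficient", call. = FALSE)
  if (n_groups < 1L) stop("n_groups must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(group_sizes) == 1L) group_sizes <- rep(group_sizes, n_groups)
  if (length(group_sizes) != n_groups)
    stop("group_sizes must have length 1 or n_groups", call. = FALSE)
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  predictors <- setdiff(names(beta), "(Intercept)")
  if (!is.null(psi)) {
    psi <- as.matrix(psi)
    if (is.null(group)) stop("psi given but no grouping column", call. = FALSE)
    if (nrow(psi) != ncol(psi) || max(abs(psi - t(psi))) > 1e-10)
      stop("psi must be a symmetric matrix", call. = FALSE)
    ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("psi is not positive semi-definite", call. = FALSE)
    if (is.null(rownames(psi)))
      stop("psi needs dimnames: '(Intercept)' then slope terms", call. = FALSE)
    if (rownames(psi)[1] != "(Intercept)")
      stop("psi's first dimension must be '(Intercept)'", call. = FALSE)
    extra <- setdiff(rownames(psi)[-1], predictors)
    if (length(extra))
      stop("psi slope term(s) not among beta's predictors: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in names(predictor_model)) {
    pm <- predictor_model[[nm]]
    if (!nm %in% predictors)
      stop("predictor_model entry for unknown predictor: ", nm, call. = FALSE)
    if (!pm$type %in% c("normal", "categorical"))
      stop("unknown predictor distribution type: ", pm$type, call. = FALSE)
    if (pm$type == "categorical") {
      k <- length(pm$levels)
      if (k < 2L) stop("categorical predictor needs >= 2 levels", call. = FALSE)
      if (length(pm$probs) != k || abs(sum(pm$probs) - 1) > 1e-8)
        stop("categorical level probabilities must sum to 1", call. = FALSE)
      if (length(beta[[nm]]) != k - 1L)
        stop("beta for categorical '", nm, "' must have levels - 1 = ",
             k - 1L, " coefficients", call. = FALSE)
      if (!is.null(psi) && nm %in% rownames(psi))
        stop("categorical predictors cannot carry random slopes here: ", nm,
             call. = FALSE)
    }
  }
  if (!length(forced)) forced <- character(0)
  bad_forced <- setdiff(forced, predictors)
  if (length(bad_forced))
    stop("forced covariate(s) not among beta's predictors: ",
         paste(bad_forced, collapse = ", "), call. = FALSE)
  structure(
    list(n_groups = as.integer(n_groups),
         group_sizes = as.integer(group_sizes),
         beta = beta, psi = psi, sigma = sigma,
         predictor_model = predictor_model,
         response = response, group = group, forced = forced,
         seed = as.integer(seed), metadata = metadata),
    class = "mlm_simspec"
  )
}

#' @export
print.mlm_simspec <- function(x, ...) {
  q <- if (is.null(x$psi)) 0L else nrow(x$psi)
  cat("<mlm_simspec> ", x$n_groups, " groups, ",
      sum(x$group_sizes), " observations total\n", sep = "")
  cat("  predictors: ", paste(setdiff(names(x$beta), "(Intercept)"),
                              collapse = ", "), "\n", sep = "")
  if (length(x$forced))
    cat("  forced: ", paste(x$forced, collapse = ", "), "\n", sep = "")
  cat("  random-effect dimension q = ", q, ", sigma = ", x$sigma,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# PSD-safe multivariate normal draws (rows are draws)
.rmvnorm_psd <- function(n, sigma_mat) {
  q <- nrow(sigma_mat)
  e <- eigen(sigma_mat, symmetric = TRUE)
  sdv <- sqrt(pmax(e$values, 0))
  z <- matrix(stats::rnorm(n * q), n, q)
  z %*% (t(e$vectors) * sdv) |> unname()
}

#' Draw a synthetic multi-group dataset from a `mlm_simspec`
#'
#' Deterministic given `seed`: the same spec and seed always produce an
#' identical table. With `sigma = 0` and `psi = 0` the outcome equals
#' `X beta` exactly.
#'
#' @param spec A `mlm_simspec`.
#' @param seed Overrides `spec$seed` when given.
#' @return A data.frame with the group column (factor), the predictors and
#'   the outcome.
#' @export
simulateDataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "mlm_simspec"))
  if (is.null(seed)) seed <- spec$seed
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  n <- sum(spec$group_sizes)
  gid <- rep(seq_len(spec$n_groups), times = spec$group_sizes)
  predictors <- setdiff(names(spec$beta), "(Intercept)")

  d <- data.frame(row.names = seq_len(n))
  eta <- rep(spec$beta[["(Intercept)"]], n)
  for (nm in predictors) {
    pm <- spec$predictor_model[[nm]]
    if (is.null(pm) || pm$type == "normal") {
      x <- stats::rnorm(n)
      d[[nm]] <- x
      eta <- eta + spec$beta[[nm]] * x
    } else {
      lev <- sort(pm$levels)
      x <- factor(sample(pm$levels, n, replace = TRUE, prob = pm$probs),
                  levels = lev)
      d[[nm]] <- x
      # treatment coding: reference is the first sorted level
      coefs <- c(0, spec$beta[[nm]])
      eta <- eta + coefs[as.integer(x)]
    }
  }
  if (!is.null(spec$psi)) {
    b <- .rmvnorm_psd(spec$n_groups, spec$psi)
    ran_terms <- rownames(spec$psi)
    eta <- eta + b[gid, 1]
    for (j in seq_along(ran_terms)[-1])
      eta <- eta + b[gid, j] * d[[ran_terms[j]]]
  }
  eps <- if (spec$sigma > 0) stats::rnorm(n, sd = spec$sigma) else 0
  d[[spec$response]] <- eta + eps
  if (!is.null(spec$group)) {
    width <- nchar(as.character(spec$n_groups))
    d[[spec$group]] <- factor(sprintf("G%0*d", width, gid))
  }
  # group first, outcome last-but-one convention: group, predictors, y
  d <- d[, c(spec$group, predictors, spec$response), drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Full-model specification implied by a `mlm_simspec`
#'
#' Builds the `mlm_formula` of the full model over the spec's predictors:
#' all non-forced predictors as free fixed effects, the forced covariates,
#' and (by default) every numeric free predictor as a random-slope
#' candidate when a grouping column exists.
#'
#' @param spec A `mlm_simspec`.
#' @param slopes Random-slope candidates; default all numeric free
#'   predictors (when grouped).
#' @return A `mlm_formula`.
#' @export
simFullModel <- function(spec, slopes = NULL) {
  stopifnot(inherits(spec, "mlm_simspec"))
  predictors <- setdiff(names(spec$beta), "(Intercept)")
  free <- setdiff(predictors, spec$forced)
  if (is.null(slopes)) {
    slopes <- if (is.null(spec$group)) character(0) else {
      is_cat <- vapply(free, function(nm) {
        pm <- spec$predictor_model[[nm]]
        !is.null(pm) && pm$type == "categorical"
      }, logical(1))
      free[!is_cat]
    }
  }
  modelFormula(
    response = spec$response,
    fixed_free = free,
    forced = spec$forced,
    group = spec$group,
    random_slopes = slopes,
    has_random_intercept = !is.null(spec$group),
    term_order = predictors
  )
}

#' Simulation specs shaped like three multi-country survey studies
#'
#' Returns a `mlm_simspec` whose column roles mirror one of three published
#' multi-country COVID-19 survey designs:
#'
#' * `"blackburn"` - vaccine intent on conspiratorial beliefs and trust in
#'   governments (2 free predictors, 6 forced demographic covariates,
#'   43 countries); candidate space of size 13.
#' * `"ntontis"` - perceived stress on primary/secondary stressors, group
#'   identity and perceived social support (4 free predictors, 2 forced,
#'   43 countries); candidate space of size 97.
#' * `"han"` - compliance on trust in seven domains (7 free predictors,
#'   3 forced, 62 countries); candidate space of size 2315.
#'
#' Group sizes default to 100 observations per group (the studies' own
#' samples of roughly 15-20 thousand participants are carried in
#' `metadata` only, so test runs stay fast). Free predictors are standard
#' normal ("standardized"); `gender` is categorical. True coefficients are
#' arbitrary documented defaults: intercept 0, free predictors 0.5, forced
#' covariates 0.2, random-intercept variance 1, random-slope variances
#' 0.25, residual SD 1.
#'
#' @param shape One of `"blackburn"`, `"ntontis"`, `"han"`.
#' @param group_size Observations per group.
#' @param seed Seed stored in the spec.
#' @return A `mlm_simspec`.
#' @export
studyShapedSpec <- function(shape = c("blackburn", "ntontis", "han"),
                            group_size = 100L, seed = 1L) {
  shape <- match.arg(shape)
  cfg <- switch(shape,
    blackburn = list(
      response = "vaccine_intent",
      free = c("conspiratorial_beliefs", "trust_governments"),
      forced = c("gender", "age", "education", "employment",
                 "relationship", "ses"),
      n_groups = 43L,
      metadata = list(study = "blackburn", participants = 15740L,
                      countries = 43L)
    ),
    ntontis = list(
      response = "perceived_stress",
      free = c("primary_stressors", "secondary_stressors",
               "group_identity", "social_support"),
      forced = c("gender", "ses"),
      n_groups = 43L,
      metadata = list(study = "ntontis", participants = 14600L,
                      countries = 43L)
    ),
    han = list(
      response = "compliance",
      free = paste0("trust", 1:7),
      forced = c("gender", "age", "education"),
      n_groups = 62L,
      metadata = list(study = "han", participants = 20601L, countries = 62L)
    )
  )
  beta <- c(list("(Intercept)" = 0),
            stats::setNames(as.list(rep(0.5, length(cfg$free))), cfg$free),
            stats::setNames(as.list(rep(0.2, length(cfg$forced))), cfg$forced))
  q <- 1L + length(cfg$free)
  psi <- diag(c(1, rep(0.25, length(cfg$free))))
  dimnames(psi) <- list(c("(Intercept)", cfg$free), c("(Intercept)", cfg$free))
  simSpec(
    n_groups = cfg$n_groups, group_sizes = group_size, beta = beta,
    psi = psi, sigma = 1,
    predictor_model = list(gender = list(type = "categorical",
                                         levels = c("female", "male"),
                                         probs = c(0.5, 0.5))),
    response = cfg$response, group = "country", forced = cfg$forced,
    seed = seed, metadata = cfg$metadata
  )
}

#' Serialize a `mlm_simspec` to a plain-text (JSON) file
#'
#' @param spec A `mlm_simspec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSimSpec <- function(spec, path) {
  stopifnot(inherits(spec, "mlm_simspec"))
  x <- unclass(spec)
  if (!is.null(x$psi)) {
    x$psi_terms <- rownames(x$psi)
    x$psi <- unname(as.matrix(x$psi))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a `mlm_simspec` written by [writeSimSpec()]
#'
#' @param path JSON path.
#' @return A `mlm_simspec`.
#' @export
readSimSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  psi <- NULL
  if (!is.null(x$psi)) {
    psi <- as.matrix(x$psi)
    dimnames(psi) <- list(x$psi_terms, x$psi_terms)
  }
  pm <- lapply(x$predictor_model, function(e) {
    e <- as.list(e)
    if (!is.null(e$levels)) e$levels <- as.character(e$levels)
    if (!is.null(e$probs)) e$probs <- as.numeric(e$probs)
    e
  })
  simSpec(n_groups = x$n_groups, group_sizes = x$group_sizes,
          beta = x$beta, psi = psi, sigma = x$sigma,
          predictor_model = pm, response = x$response,
          group = if (is.null(x$group)) NULL else x$group,
          forced = unlist(x$forced) %||% character(0),
          seed = x$seed, metadata = as.list(x$metadata))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
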