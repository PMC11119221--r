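#' Structured description of one candidate mixed-effects model
#'
#' A `mlm_formula` object captures everything the exploration machinery needs
#' to know about one model: the response, the free fixed-effect terms (those
#' the enumerator may drop), the forced covariates (always included, e.g. a
#' demographics block), whether a random intercept is present, which random
#' slopes are present, and the grouping factor.
#'
#' Admissibility rules enforced by the validator:
#' * a random slope requires a random intercept (`(0 + x | g)` structures are
#'   inadmissible here);
#' * every random slope must also appear among the model's fixed terms;
#' * without a grouping factor there is no random part at all;
#' * forced covariates and free fixed effects are disjoint, and forced
#'   covariates can never be random slopes.
#'
#' @param response Name of the outcome column.
#' @param fixed_free Character vector of free fixed-effect terms, in
#'   declaration order.
#' @param forced Character vector of always-included covariates.
#' @param group Name of the grouping column, or `NULL` for a fixed-effects-only
#'   model.
#' @param random_slopes Character vector of random-slope terms (subset of the
#'   model's fixed terms).
#' @param has_random_intercept Logical; must be `TRUE` whenever slopes are
#'   present and `FALSE` whenever `group` is absent.
#' @param term_order Character vector giving the rendering order of all fixed
#'   terms (free and forced interleaved as declared). Defaults to
#'   `c(fixed_free, forced)`.
#'
#' @return An object of class `mlm_formula`.
#' @seealso [parseFormula()], [renderFormula()]
#' @export
modelFormula <- function(response, fixed_free = character(), forced = character(),
                         group = NULL,
                         random_slopes = character(),
                         has_random_intercept = !is.null(group),
                         term_order = NULL) {
  if (is.null(term_order)) term_order <- c(fixed_free, forced)
  m <- structure(
    list(
      response = as.character(response),
      fixed_free = as.character(fixed_free),
      forced = as.character(forced),
      term_order = as.character(term_order),
      has_random_intercept = isTRUE(has_random_intercept),
      random_slopes = as.character(random_slopes),
      group = if (is.null(group)) NULL else as.character(group)
    ),
    class = "mlm_formula"
  )
  validateModelFormula(m)
  m
}

#' Validate a `mlm_formula`
#'
#' Checks the admissibility invariants listed under [modelFormula()] and stops
#' with a descriptive error on the first violation.
#'
#' @param m A `mlm_formula`.
#' @return `m`, invisibly.
#' @export
validateModelFormula <- function(m) {
  stopifnot(inherits(m, "mlm_formula"))
  if (length(m$response) != 1L || !nzchar(m$response))
    stop("model formula must have exactly one response variable", call. = FALSE)
  all_fixed <- c(m$fixed_free, m$forced)
  if (anyDuplicated(all_fixed))
    stop("duplicate terms in model formula: ",
         paste(unique(all_fixed[duplicated(all_fixed)]), collapse = ", "),
         call. = FALSE)
  if (length(intersect(m$fixed_free, m$forced)))
    stop("forced covariates must be disjoint from free fixed effects",
         call. = FALSE)
  if (!setequal(m$term_order, all_fixed) || length(m$term_order) != length(all_fixed))
    stop("term_order must be a permutation of the fixed terms", call. = FALSE)
  if (is.null(m$group)) {
    if (m$has_random_intercept)
      stop("a random intercept requires a grouping variable", call. = FALSE)
    if (length(m$random_slopes))
      stop("random slopes require a grouping variable", call. = FALSE)
  }
  if (length(m$random_slopes)) {
    if (!m$has_random_intercept)
      stop("random slopes without a random intercept are inadmissible",
           call. = FALSE)
    missing_fx <- setdiff(m$random_slopes, all_fixed)
    if (length(missing_fx))
      stop("random slope(s) without a matching fixed effect: ",
           paste(missing_fx, collapse = ", "), call. = FALSE)
    in_forced <- intersect(m$random_slopes, m$forced)
    if (length(in_forced))
      stop("forced covariates cannot be random slopes: ",
           paste(in_forced, collapse = ", "), call. = FALSE)
    if (anyDuplicated(m$random_slopes))
      stop("duplicate random slopes", call. = FALSE)
  }
  if (!is.null(m$group) && m$group %in% c(m$response, all_fixed))
    stop("grouping variable cannot also be the response or a fixed term",
         call. = FALSE)
  invisible(m)
}

# Split an additive right-hand side into simple term names; rejects
# interactions, transformations, and anything that is not a bare column name.
.split_terms <- function(rhs) {
  rhs <- trimws(rhs)
  if (!nzchar(rhs)) stop("malformed formula: empty right-hand side", call. = FALSE)
  terms <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(terms)))
    stop("malformed formula: empty term (check '+' placement)", call. = FALSE)
  terms <- terms[terms != "1"]
  bad <- terms[!grepl("^[.A-Za-z][.A-Za-z0-9_]*$", terms)]
  if (length(bad))
    stop("unsupported term(s) (only additive column names are allowed, ",
         "no interactions or transformations): ",
         paste(bad, collapse = ", "), call. = FALSE)
  terms
}

#' Parse a mixed-model formula string into a `mlm_formula`
#'
#' Accepts Wilkinson-style notation `"Y ~ X1 + X2 + X3"` with an optional
#' single parenthesized random term `"(1 + X1 + X2 | G)"`. Only additive
#' bare-column terms are supported; interactions, transformations, nested or
#' multiple grouping factors are rejected.
#'
#' The random part may be given either inline in `text` or through the
#' `group` / `slopes` arguments (the calling convention of a full-model
#' specification: formula, group, slope candidates, forced covariates). When
#' both are given they must agree.
#'
#' @param text Formula as a string or a `formula` object.
#' @param group Grouping column name, or `NULL`.
#' @param slopes Character vector of random-slope terms.
#' @param forced Character vector of forced covariates; each must be a term of
#'   `text`.
#'
#' @return A `mlm_formula`.
#' @examples
#' parseFormula("Y ~ X1 + X2 + X3", group = "G",
#'              slopes = c("X1", "X2"), forced = "X3")
#' parseFormula("Y ~ X1 + X3 + (1 + X1 | G)", forced = "X3")
#' @export
parseFormula <- function(text, group = NULL, slopes = character(),
                         forced = character()) {
  if (inherits(text, "formula"))
    text <- paste(deparse(text, width.cutoff = 500L), collapse = " ")
  if (!is.character(text) || length(text) != 1L)
    stop("malformed formula: expected a single formula string", call. = FALSE)
  parts <- strsplit(text, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed formula: expected exactly one '~'", call. = FALSE)
  response <- trimws(parts[1])
  if (!grepl("^[.A-Za-z][.A-Za-z0-9_]*$", response))
    stop("malformed formula: response must be a single column name",
         call. = FALSE)
  rhs <- parts[2]

  # extract an inline random term "( 1 + s1 + ... | g )", at most one
  ran_matches <- gregexpr("\\(([^()|]*)\\|([^()|]*)\\)", rhs)[[1]]
  if (ran_matches[1] != -1L && length(ran_matches) > 1L)
    stop("multiple random-effect terms are not supported (single grouping ",
         "factor only)", call. = FALSE)
  if (ran_matches[1] != -1L) {
    ran_txt <- regmatches(rhs, ran_matches)[1]
    rhs <- sub(ran_txt, "", rhs, fixed = TRUE)
    rhs <- gsub("\\+\\s*$", "", trimws(rhs))
    inner <- sub("^\\(", "", sub("\\)$", "", ran_txt))
    bar <- strsplit(inner, "|", fixed = TRUE)[[1]]
    g_inline <- trimws(bar[2])
    lhs_terms <- trimws(strsplit(bar[1], "+", fixed = TRUE)[[1]])
    if (!"1" %in% lhs_terms)
      stop("random-effect term must include the intercept '1' ",
         "(random slopes without an intercept are inadmissible)", call. = FALSE)
    s_inline <- lhs_terms[lhs_terms != "1"]
    if (!is.null(group) && !identical(group, g_inline))
      stop("grouping variable given twice and inconsistently ('", g_inline,
           "' in the formula, '", group, "' as argument)", call. = FALSE)
    if (length(slopes) && !setequal(slopes, s_inline))
      stop("random slopes given twice and inconsistently", call. = FALSE)
    group <- g_inline
    slopes <- s_inline
  }
  if (!is.null(group) && !grepl("^[.A-Za-z][.A-Za-z0-9_]*$", group))
    stop("malformed grouping variable name: ", group, call. = FALSE)

  term_order <- .split_terms(rhs)
  if (anyDuplicated(term_order))
    stop("duplicate terms in formula: ",
         paste(unique(term_order[duplicated(term_order)]), collapse = ", "),
         call. = FALSE)
  missing_forced <- setdiff(forced, term_order)
  if (length(missing_forced))
    stop("forced covariate(s) not present in the formula: ",
         paste(missing_forced, collapse = ", "), call. = FALSE)
  not_term <- setdiff(slopes, term_order)
  if (length(not_term))
    stop("random slope(s) not present as fixed-effect terms: ",
         paste(not_term, collapse = ", "), call. = FALSE)
  slope_forced <- intersect(slopes, forced)
  if (length(slope_forced))
    stop("forced covariates cannot be random slope candidates: ",
         paste(slope_forced, collapse = ", "), call. = FALSE)
  if (is.null(group) && length(slopes))
    stop("random slopes require a grouping variable", call. = FALSE)

  modelFormula(
    response = response,
    fixed_free = setdiff(term_order, forced),
    forced = forced[order(match(forced, term_order))],
    group = group,
    random_slopes = slopes[order(match(slopes, term_order))],
    has_random_intercept = !is.null(group),
    term_order = term_order
  )
}

#' Render a `mlm_formula` as its canonical formula string
#'
#' Fixed terms appear in declaration order; when a random part exists it is
#' appended as `"(1 + s1 + ... | G)"`. The rendering is deterministic and
#' round-trips through [parseFormula()].
#'
#' @param m A `mlm_formula`.
#' @return A single string, e.g. `"Y ~ X1 + X2 + X3 + (1 + X1 + X2 | G)"`.
#' @export
renderFormula <- function(m) {
  validateModelFormula(m)
  fixed <- if (length(m$term_order)) paste(m$term_order, collapse = " + ") else "1"
  out <- paste(m$response, "~", fixed)
  if (m$has_random_intercept) {
    ran <- paste(c("1", m$random_slopes), collapse = " + ")
    out <- paste0(out, " + (", ran, " | ", m$group, ")")
  }
  out
}

#' @export
format.mlm_formula <- function(x, ...) renderFormula(x)

#' @export
print.mlm_formula <- function(x, ...) {
  cat("<mlm_formula> ", renderFormula(x), "\n", sep = "")
  if (length(x$forced))
    cat("  forced: ", paste(x$forced, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`==.mlm_formula` <- function(e1, e2) {
  identical(renderFormula(e1), renderFormula(e2)) &&
    setequal(e1$forced, e2$forced)
}

# stats::formula object for the fitting backends
.as_r_formula <- function(m) {
  stats::as.formula(renderFormula(m), env = globalenv())
}

# all data columns a model refers to
.model_vars <- function(m) {
  c(m$response, m$term_order, m$group)
}
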