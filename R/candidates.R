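#' Enumerate every admissible candidate model from a full model
#'
#' From a full-model specification this builds the complete, ordered list of
#' admissible candidates, stratified exactly as the exploration workflow
#' reports them:
#'
#' 1. **fixed_only** - every subset of the free fixed effects (each candidate
#'    also carries all forced covariates), no random part;
#' 2. **random_intercept** - the same subsets with `(1 | G)`, when a grouping
#'    variable is present;
#' 3. **random_slope** - for every fixed subset `S`, every nonempty subset of
#'    the slope candidates contained in `S`, always with a random intercept.
#'
#' Within each stratum, subsets are ordered by increasing size with ties
#' broken by declaration order; in the slope stratum the fixed subset varies
#' slowest. Slopes whose fixed effect is absent from the candidate are
#' inadmissible and never generated, and forced covariates are never slope
#' candidates.
#'
#' The number of candidates grows exponentially in the number of free
#' predictors (`2^f + 2^(f-s) 3^s` with a grouping factor), so a guard
#' refuses to enumerate past `ceiling` models unless `override = TRUE`.
#'
#' @param full A `mlm_formula` describing the full model (see
#'   [parseFormula()]); its `random_slopes` are the slope candidates.
#' @param ceiling Maximum candidate count enumerated without an override.
#' @param override Set `TRUE` to enumerate past the ceiling.
#'
#' @return A `mlm_candidates` object: list with `candidates` (list of
#'   `mlm_formula`), `strata` (parallel character vector), and `full_spec`.
#' @examples
#' full <- parseFormula("Y ~ X1 + X2 + X3", group = "G",
#'                      slopes = c("X1", "X2"), forced = "X3")
#' cs <- enumerateCandidates(full)
#' length(cs$candidates)  # 13
#' @export
enumerateCandidates <- function(full, ceiling = 10000L, override = FALSE) {
  validateModelFormula(full)
  f <- length(full$fixed_free)
  s <- length(full$random_slopes)
  n_total <- countCandidates(f, s, has_group = !is.null(full$group))
  if (n_total > ceiling && !override)
    stop("enumeration would generate ", n_total, " candidate models, above ",
         "the ceiling of ", ceiling, "; the model space grows exponentially ",
         "in the number of free predictors. Reduce the free predictors or ",
         "slope candidates, or pass override = TRUE to proceed.",
         call. = FALSE)

  # all subsets of the free fixed effects, by increasing size then
  # declaration order (indices lexicographic within a size)
  subsets <- list(integer(0))
  if (f > 0) {
    for (k in seq_len(f)) {
      cols <- utils::combn(f, k)
      subsets <- c(subsets, lapply(seq_len(ncol(cols)), function(j) cols[, j]))
    }
  }

  mk <- function(idx, slopes, random_intercept) {
    free <- full$fixed_free[idx]
    keep <- c(free, full$forced)
    modelFormula(
      response = full$response,
      fixed_free = free,
      forced = full$forced,
      group = if (random_intercept) full$group else NULL,
      random_slopes = slopes,
      has_random_intercept = random_intercept,
      term_order = full$term_order[full$term_order %in% keep]
    )
  }

  candidates <- list()
  strata <- character(0)
  for (idx in subsets) {
    candidates[[length(candidates) + 1L]] <- mk(idx, character(0), FALSE)
    strata <- c(strata, "fixed_only")
  }
  if (!is.null(full$group)) {
    for (idx in subsets) {
      candidates[[length(candidates) + 1L]] <- mk(idx, character(0), TRUE)
      strata <- c(strata, "random_intercept")
    }
    if (s > 0) {
      slope_pool <- full$random_slopes
      for (idx in subsets) {
        avail <- intersect(full$fixed_free[idx], slope_pool)
        a <- length(avail)
        if (a == 0) next
        for (k in seq_len(a)) {
          cols <- utils::combn(a, k)
          for (j in seq_len(ncol(cols))) {
            sl <- avail[cols[, j]]
            candidates[[length(candidates) + 1L]] <- mk(idx, sl, TRUE)
            strata <- c(strata, "random_slope")
          }
        }
      }
    }
  }

  stopifnot(length(candidates) == n_total)
  structure(
    list(candidates = candidates, strata = strata, full_spec = full),
    class = "mlm_candidates"
  )
}

#' Closed-form size of the candidate model space
#'
#' With `f` free fixed-effect predictors and no grouping variable the space
#' holds the `2^f` fixed-effects-only models. With a grouping variable it
#' holds `2^f` fixed-only models, `2^f` random-intercept models, and
#' `2^(f-s) 3^s - 2^f` random-slope models for `s` slope candidates (each of
#' the `s` slope candidates is absent, fixed-only, or fixed-plus-slope;
#' subtracting the slope-free configurations), for a total of
#' `2^f + 2^(f-s) 3^s`.
#'
#' @param f Number of free fixed-effect predictors.
#' @param s Number of random-slope candidates (`0 <= s <= f`).
#' @param has_group Whether a grouping variable is present.
#' @return Integer-valued count (as a double; the space can be large).
#' @examples
#' countCandidates(2, 2) # 13
#' countCandidates(4, 4) # 97
#' countCandidates(7, 7) # 2315
#' @export
countCandidates <- function(f, s = 0L, has_group = TRUE) {
  if (length(f) != 1L || length(s) != 1L || f < 0 || s < 0 ||
      f != round(f) || s != round(s))
    stop("f and s must be single non-negative integers", call. = FALSE)
  if (s > f)
    stop("more slope candidates (", s, ") than free predictors (", f, ")",
         call. = FALSE)
  if (!has_group) return(2^f)
  2^f + 2^(f - s) * 3^s
}

#' @export
print.mlm_candidates <- function(x, ...) {
  cat("<mlm_candidates> ", length(x$candidates), " candidate models from full model\n  ",
      renderFormula(x$full_spec), "\n", sep = "")
  tab <- table(factor(x$strata,
                      levels = c("fixed_only", "random_intercept", "random_slope")))
  for (nm in names(tab)) cat(sprintf("  %-17s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
length.mlm_candidates <- function(x) length(x$candidates)

#' Rendered formula strings of a candidate set
#'
#' @param cs A `mlm_candidates` object.
#' @return Character vector of canonical formula strings, in enumeration
#'   order.
#' @export
candidateFormulas <- function(cs) {
  stopifnot(inherits(cs, "mlm_candidates"))
  vapply(cs$candidates, renderFormula, character(1))
}
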