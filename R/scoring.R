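# Pathogenicity classification. Truncating consequences are definitely
# pathogenic outright; UCVs (missense, noncanonical splice, inframe indels)
# receive an integer Variant Score (VS) summing in-silico and population
# evidence, and the VS maps to four classes:
#   highly likely pathogenic  VS >= 11
#   likely pathogenic         5 <= VS <= 10
#   indeterminate             0 <= VS <= 4
#   highly likely neutral     VS <= -1
# The published component table for the two-gene scoring system is not fully
# reproduced anywhere we can read it offline, so the evidence rules ship as a
# documented default configuration; cohort fixture records carry their
# printed (curated) classes for concordance testing.

#' Default Variant Score configuration
#'
#' Integer-point evidence rules (feature name -> points) plus the four VS
#' class thresholds. Points are configuration, not data: swap in a different
#' rule table with [scoring_config()] to emulate another scheme.
#'
#' @return a `scoring_config` object.
#' @export
default_scoring_config <- function() {
  scoring_config(rules = data.frame(
    name = c("conservation_strong", "conservation_moderate",
             "grantham_radical", "grantham_moderate",
             "splice_predictor_loss", "absent_in_controls",
             "cosegregation", "benign_cosegregation",
             "present_in_controls"),
    points = c(5L, 2L, 4L, 2L, 4L, 2L, 3L, -3L, -3L),
    stringsAsFactors = FALSE
  ))
}

#' Build a Variant Score configuration
#'
#' @param rules data frame with `name` (unique feature names) and integer
#'   `points` columns.
#' @param thresholds named integer vector with elements `highly_likely_min`
#'   (default 11), `likely_min` (5) and `indeterminate_min` (0); every
#'   integer VS below `indeterminate_min` is highly likely neutral, so the
#'   classes partition the integers completely.
#' @return a `scoring_config` object.
#' @export
scoring_config <- function(rules,
                           thresholds = c(highly_likely_min = 11L,
                                          likely_min = 5L,
                                          indeterminate_min = 0L)) {
  stopifnot(all(c("name", "points") %in% names(rules)))
  abort_if(anyDuplicated(rules$name) > 0, "duplicate evidence rule names")
  abort_if(any(rules$points != as.integer(rules$points)),
           "VS points must be integers")
  need <- c("highly_likely_min", "likely_min", "indeterminate_min")
  abort_if(!all(need %in% names(thresholds)), "thresholds must name %s",
           paste(need, collapse = ", "))
  thresholds <- thresholds[need]
  abort_if(any(thresholds != as.integer(thresholds)) ||
             !all(diff(rev(thresholds)) > 0),
           "VS thresholds must be strictly increasing integers")
  cfg <- list(rules = rules,
              thresholds = vapply(thresholds, as.integer, 1L))
  class(cfg) <- "scoring_config"
  cfg
}

#' Compute a Variant Score
#'
#' Sums the points of the evidence rules whose feature is satisfied. Every
#' rule in the configuration must be answered (TRUE/FALSE); a missing
#' feature is an error naming it, so silent partial scores cannot occur.
#'
#' @param features named logical vector, one element per configured rule.
#' @param cfg a [scoring_config()].
#' @return list with `components` (named integer points of satisfied rules)
#'   and `vs_total`.
#' @export
compute_variant_score <- function(features, cfg = default_scoring_config()) {
  stopifnot(inherits(cfg, "scoring_config"))
  missing <- setdiff(cfg$rules$name, names(features))
  abort_if(length(missing) > 0, "scoring feature(s) missing: %s",
           paste(missing, collapse = ", "))
  sat <- vapply(cfg$rules$name, function(nm) isTRUE(features[[nm]]), TRUE)
  components <- setNames(as.integer(cfg$rules$points[sat]),
                         cfg$rules$name[sat])
  list(components = components, vs_total = sum(components))
}

#' Map a Variant Score to a pathogenicity class
#'
#' @param vs integer VS (non-integers are rejected; the class boundaries only
#'   partition the integers).
#' @param cfg a [scoring_config()] supplying the thresholds.
#' @return one of `"highly_likely_pathogenic"`, `"likely_pathogenic"`,
#'   `"indeterminate"`, `"highly_likely_neutral"`.
#' @export
vs_to_class <- function(vs, cfg = default_scoring_config()) {
  abort_if(any(vs != round(vs)), "VS must be integer, got %s",
           paste(vs, collapse = ", "))
  th <- cfg$thresholds
  unname(ifelse(vs >= th["highly_likely_min"], "highly_likely_pathogenic",
  ifelse(vs >= th["likely_min"], "likely_pathogenic",
  ifelse(vs >= th["indeterminate_min"], "indeterminate",
         "highly_likely_neutral"))))
}

#' Classify a variant
#'
#' Truncating consequences are definitely pathogenic regardless of any score.
#' UCVs use their VS class; fixture records whose score features are not
#' available use the curated (printed) class instead. A UCV with neither a
#' score nor a curated class is an error.
#'
#' @param consequence consequence kind string or [classify_consequence()] result.
#' @param score a [compute_variant_score()] result, its `vs_total`, or `NULL`.
#' @param curated_class curated class label or `NA`.
#' @param cfg a [scoring_config()].
#' @return pathogenicity class string.
#' @export
classify_variant <- function(consequence, score = NULL,
                             curated_class = NA_character_,
                             cfg = default_scoring_config()) {
  if (is_truncating(consequence)) return("definitely_pathogenic")
  if (!is.null(score)) {
    vs <- if (is.list(score)) score$vs_total else score
    return(vs_to_class(vs, cfg))
  }
  if (!is.na(curated_class)) {
    abort_if(!curated_class %in% VALID_CLASSES,
             "unknown curated class '%s'", curated_class)
    return(curated_class)
  }
  kind <- if (is.list(consequence)) consequence$kind else consequence
  # synonymous / deep intronic / intergenic changes are a priori non-pathogenic
  if (!is_ucv(kind)) return("highly_likely_neutral")
  stop(sprintf("UCV of kind '%s' has neither a Variant Score nor a curated class",
               kind), call. = FALSE)
}

#' Is a pathogenicity class reportable?
#'
#' Reported (diagnostic) mutations are the definitely, highly likely and
#' likely pathogenic classes; indeterminate and neutral UCVs are not reported.
#'
#' @param class pathogenicity class string vector.
#' @return logical vector.
#' @export
is_reportable <- function(class) {
  class %in% c("definitely_pathogenic", "highly_likely_pathogenic",
               "likely_pathogenic")
}
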