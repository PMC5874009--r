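#' Summarize a set of 87Sr/86Sr measurements
#'
#' Arithmetic mean and twice the sample standard deviation (the 2-sigma
#' dispersion conventionally reported for bioavailable strontium
#' baselines).
#'
#' @param ratios numeric vector of 87Sr/86Sr ratios, length >= 2.
#' @return a list with `mean`, `two_sigma` and `n`.
#' @examples
#' bone <- c(0.708733, 0.708685, 0.708701, 0.708691, 0.708826)
#' summarize_ratios(bone)
#' @export
summarize_ratios <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) < 2 || any(is.na(ratios))) {
    stop("need at least two non-missing ratios to estimate dispersion")
  }
  list(mean = mean(ratios), two_sigma = 2 * stats::sd(ratios), n = length(ratios))
}

#' Construct the local bioavailable strontium range
#'
#' The local range is the union span of one or more source intervals: each
#' component is either a `(mean, two_sigma)` summary (e.g. from local human
#' bone via [summarize_ratios()]) or explicit `(lower, upper)` bounds (e.g.
#' a published faunal baseline).  Taking the broadest interval across
#' sources avoids over-calling non-locals when baselines from different
#' tissues disagree slightly.
#'
#' @param components a list of components; each a named numeric vector or
#'   list with either `mean` and `two_sigma` or `lower` and `upper`.
#'   Optional `label` elements are carried through.
#' @return an object of class `local_range`: list with inclusive `lower`
#'   and `upper` bounds and the component intervals.
#' @examples
#' estimate_local_range(list(
#'   list(label = "human bone", mean = 0.7087, two_sigma = 0.0001),
#'   list(label = "pig enamel", mean = 0.7089, two_sigma = 0.0001)
#' ))
#' @export
estimate_local_range <- function(components) {
  if (!length(components)) stop("need at least one component interval")
  if (!is.null(names(components)) || is.numeric(components)) {
    # allow a single bare component
    if (is.numeric(components)) components <- list(components)
  }
  comp <- lapply(components, function(cm) {
    cm <- as.list(cm)
    if (!is.null(cm$mean) && !is.null(cm$two_sigma)) {
      lower <- cm$mean - cm$two_sigma
      upper <- cm$mean + cm$two_sigma
    } else if (!is.null(cm$lower) && !is.null(cm$upper)) {
      lower <- cm$lower
      upper <- cm$upper
    } else {
      stop("component needs either mean/two_sigma or lower/upper")
    }
    if (lower > upper) stop("component bounds out of order")
    list(label = if (is.null(cm$label)) NA_character_ else cm$label,
         lower = lower, upper = upper)
  })
  local_range(min(vapply(comp, `[[`, 0, "lower")),
              max(vapply(comp, `[[`, 0, "upper")),
              components = comp)
}

#' Define a local range from explicit bounds
#'
#' @param lower,upper inclusive 87Sr/86Sr bounds, `lower < upper`.
#' @param components optional list of source intervals (see
#'   [estimate_local_range()]).
#' @return a `local_range` object.
#' @examples
#' local_range(0.7086, 0.7090)
#' @export
local_range <- function(lower, upper, components = NULL) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1, lower < upper)
  structure(list(lower = lower, upper = upper, components = components),
            class = "local_range")
}

#' @export
print.local_range <- function(x, ...) {
  cat(sprintf("local 87Sr/86Sr range [%.4f, %.4f] (inclusive)\n", x$lower, x$upper))
  invisible(x)
}

# position of a ratio relative to an inclusive range
range_position <- function(ratio, range) {
  ifelse(ratio < range$lower, "below_range",
         ifelse(ratio > range$upper, "above_range", "within"))
}

#' Classify individuals as local or non-local
#'
#' For each individual the available enamel tooth with the *earliest*
#' mineralization rank (see [tooth_rank()]) carries the childhood residence
#' signal and is tested for containment in the local range.  Bounds are
#' inclusive and ratios are compared at full precision, without rounding.
#' Individuals represented only by bone (which remodels through life and
#' cannot fix a childhood signal) are returned as `indeterminate`.
#'
#' @param samples an `isotope_table` (see [read_isotope_table()]) or a
#'   data.frame with columns `individual_id`, `material`, `tooth`, `ratio`.
#' @param range a `local_range`.
#' @return a data.frame of class `provenance_calls` with one row per
#'   individual: `individual_id`, `status` (`local`, `nonlocal`,
#'   `indeterminate`), `basis_tooth`, `ratio`, `direction` (`within`,
#'   `above_range`, `below_range`), and `single_tooth` flagging calls that
#'   rest on the only sampled tooth (which may be a late-mineralizing one,
#'   a weaker childhood proxy).
#' @examples
#' iso <- read_isotope_table(np_extdata("table2_isotopes.csv"))
#' calls <- classify_provenance(iso, local_range(0.7086, 0.7090))
#' table(calls$status)
#' @export
classify_provenance <- function(samples, range) {
  stopifnot(inherits(range, "local_range"))
  df <- as.data.frame(samples)
  if (!"rank" %in% names(df)) df$rank <- tooth_rank(df$tooth)
  out <- lapply(split(df, df$individual_id), function(d) {
    en <- d[d$material == "enamel" & !is.na(d$rank), , drop = FALSE]
    if (!nrow(en)) {
      return(data.frame(
        individual_id = d$individual_id[1], status = "indeterminate",
        basis_tooth = NA_character_, ratio = NA_real_,
        direction = NA_character_, single_tooth = NA,
        stringsAsFactors = FALSE
      ))
    }
    en <- en[order(en$rank), , drop = FALSE]
    pos <- range_position(en$ratio[1], range)
    data.frame(
      individual_id = d$individual_id[1],
      status = if (pos == "within") "local" else "nonlocal",
      basis_tooth = en$tooth[1], ratio = en$ratio[1], direction = pos,
      single_tooth = nrow(en) == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("provenance_calls", "data.frame")
  out
}

#' Type intra-individual mobility from a pair of teeth
#'
#' Two enamel samples with different mineralization ranks bracket an
#' individual's childhood: the early tooth records the place of birth and
#' infancy, the late tooth a later childhood residence.  Categories follow
#' from where each ratio falls relative to the local range:
#'
#' * both within: `stable_local` (movement inside the local range is not
#'   detectable);
#' * both above: `stable_nonlocal` (arrived at some point in childhood from
#'   the same non-local region);
#' * early above, late within or below: `arrived_in_childhood` (moved to
#'   the local area in late childhood);
#' * early within, late above: `outbound_return` (left the local area in
#'   childhood and returned later, since burial is local);
#' * early below the range: `distinct_origin` (a source region different
#'   from both the local range and the main non-local signature).
#'
#' The absolute difference between the two ratios is also compared against
#' `delta_threshold` (by default the dispersion of the local baseline) and
#' reported as the flag `delta_exceeds`; pairs in the same position class
#' with a large delta still reflect movement between isotopically similar
#' areas that the range cannot resolve.
#'
#' @param samples an `isotope_table` restricted to one or more individuals.
#' @param range a `local_range`.
#' @param delta_threshold dimensionless ratio difference regarded as
#'   analytically meaningful (default `1e-4`).
#' @return a data.frame of class `mobility_calls`, one row per individual
#'   with two ranked teeth: tooth codes, ratios, `delta`, `delta_exceeds`
#'   and `category`.  Individuals with fewer than two distinct ranks are
#'   dropped with a warning directing callers to [classify_provenance()].
#' @examples
#' iso <- read_isotope_table(np_extdata("table2_isotopes.csv"))
#' mob <- infer_mobility(iso, local_range(0.7086, 0.7090))
#' table(mob$category)
#' @export
infer_mobility <- function(samples, range, delta_threshold = 1e-4) {
  stopifnot(inherits(range, "local_range"), delta_threshold > 0)
  df <- as.data.frame(samples)
  if (!"rank" %in% names(df)) df$rank <- tooth_rank(df$tooth)
  dropped <- character()
  out <- lapply(split(df, df$individual_id), function(d) {
    en <- d[d$material == "enamel" & !is.na(d$rank), , drop = FALSE]
    if (nrow(en) < 2 || length(unique(en$rank)) < 2) {
      dropped <<- c(dropped, d$individual_id[1])
      return(NULL)
    }
    en <- en[order(en$rank), , drop = FALSE]
    early <- en[1, ]
    late <- en[nrow(en), ]
    pe <- range_position(early$ratio, range)
    pl <- range_position(late$ratio, range)
    category <- if (pe == "below_range") {
      "distinct_origin"
    } else if (pe == "within" && pl == "within") {
      "stable_local"
    } else if (pe == "above_range" && pl == "above_range") {
      "stable_nonlocal"
    } else if (pe == "above_range") {
      "arrived_in_childhood"
    } else {
      "outbound_return"
    }
    delta <- abs(early$ratio - late$ratio)
    data.frame(
      individual_id = d$individual_id[1],
      early_tooth = early$tooth, late_tooth = late$tooth,
      early_ratio = early$ratio, late_ratio = late$ratio,
      delta = delta, delta_exceeds = delta >= delta_threshold,
      category = category, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (length(dropped)) {
    warning("individual(s) without two ranked teeth dropped (classify with ",
            "classify_provenance instead): ", paste(dropped, collapse = ", "))
  }
  if (is.null(out)) {
    stop("no individual has two enamel teeth of different mineralization ",
         "rank; use classify_provenance() for single-tooth individuals")
  }
  rownames(out) <- NULL
  class(out) <- c("mobility_calls", "data.frame")
  out
}
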