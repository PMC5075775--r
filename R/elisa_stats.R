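# Plate-level ELISA statistics: dispersity, descriptive statistics, Welch
# t-test, one-way ANOVA, OLS comparison, boxplot/outlier conventions and
# cut-off positivity tables.

#' Absorbance plate container
#'
#' @param absorbance samples x antigens numeric matrix (A450 readings,
#'   non-negative).
#' @param sample_labels,antigen_labels row/column labels (defaults taken from
#'   dimnames).
#' @param group_of_antigen named character vector mapping each antigen to a
#'   group, e.g. \code{"LNA"}, \code{"DNA"}, \code{"control"}.
#' @param replicate_index optional integer replicate tag.
#' @return object of class \code{plate_data}.
#' @export
plate_data <- function(absorbance, sample_labels = rownames(absorbance),
                       antigen_labels = colnames(absorbance),
                       group_of_antigen = NULL, replicate_index = 1L) {
  absorbance <- as.matrix(absorbance)
  if (any(absorbance < 0)) stop("absorbance values must be non-negative")
  if (is.null(sample_labels)) sample_labels <- paste0("S", seq_len(nrow(absorbance)))
  if (is.null(antigen_labels)) antigen_labels <- paste0("Ag", seq_len(ncol(absorbance)))
  if (length(sample_labels) != nrow(absorbance) ||
      length(antigen_labels) != ncol(absorbance))
    stop("label lengths do not match the matrix dimensions")
  rownames(absorbance) <- sample_labels
  colnames(absorbance) <- antigen_labels
  if (!is.null(group_of_antigen) &&
      !all(antigen_labels %in% names(group_of_antigen)))
    stop("every antigen needs a group assignment")
  structure(list(absorbance = absorbance, sample_labels = sample_labels,
                 antigen_labels = antigen_labels,
                 group_of_antigen = group_of_antigen,
                 replicate_index = replicate_index),
            class = "plate_data")
}

antigens_in_group <- function(plate, group) {
  if (is.null(plate$group_of_antigen)) stop("plate carries no antigen groups")
  names(plate$group_of_antigen)[plate$group_of_antigen %in% group]
}

#' Per-sample dispersity over an antigen subset
#'
#' Dispersity is the difference between the highest and lowest absorbance a
#' sample shows across the stated antigens; wide dispersity means the sample
#' discriminates strongly among antigens.
#'
#' @param plate a \code{plate_data}.
#' @param sample sample label or row index.
#' @param antigen_subset antigen labels to range over (explicit, never
#'   implicit).
#' @return non-negative numeric.
#' @export
dispersity <- function(plate, sample, antigen_subset) {
  stopifnot(inherits(plate, "plate_data"))
  if (!length(antigen_subset)) stop("antigen subset must be non-empty")
  v <- plate$absorbance[sample, antigen_subset]
  max(v) - min(v)
}

#' Group dispersity report
#'
#' Dispersity of every sample within each antigen group, with the group-wise
#' mean and sample SD of those dispersities.
#'
#' @param plate a \code{plate_data} with antigen groups.
#' @param groups group names to report (default: all).
#' @return list with \code{per_sample} (samples x groups matrix) and
#'   \code{summary} (data.frame: group, mean, sd, n).
#' @export
dispersity_report <- function(plate, groups = unique(plate$group_of_antigen)) {
  per <- sapply(groups, function(g) {
    ags <- antigens_in_group(plate, g)
    vapply(plate$sample_labels, function(s) dispersity(plate, s, ags), 0)
  })
  per <- matrix(per, nrow = length(plate$sample_labels),
                dimnames = list(plate$sample_labels, groups))
  list(per_sample = per,
       summary = data.frame(group = groups,
                            mean = colMeans(per),
                            sd = apply(per, 2L, stats::sd),
                            n = nrow(per), row.names = NULL))
}

#' Descriptive statistics of a sample
#' @param values numeric vector (n >= 1).
#' @return list with \code{mean}, \code{sd} (sample SD, 0 for n = 1),
#'   \code{min}, \code{max}, \code{n}.
#' @export
group_descriptives <- function(values) {
  if (!length(values)) stop("empty sample")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       min = min(values), max = max(values), n = length(values))
}

#' Welch two-sample t-test (unequal variances)
#'
#' @param x,y numeric vectors, each n >= 2.
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite, fractional),
#'   \code{p} (two-sided).
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples are constant with different means; t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares decomposition with a pooled error term; for
#' two groups F equals the square of the pooled-variance t statistic.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with \code{f}, \code{df_between}, \code{df_within}, \code{p}.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::var(v) == 0) return(list(f = 0, df_between = length(groups) - 1L,
                                      df_within = length(v) - length(groups), p = 1))
  a <- stats::anova(stats::lm(v ~ g))
  list(f = a[1, "F value"], df_between = a[1, "Df"], df_within = a[2, "Df"],
       p = a[1, "Pr(>F)"])
}

#' Simple OLS comparison of two assays
#'
#' Ordinary least squares regression of \code{y} on \code{x} with the slope
#' test, used to ask whether one assay's readings track another's.
#'
#' @param x,y numeric vectors of equal length (n >= 3); \code{x} must vary.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_slope}.
#' @export
ols_compare <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0) stop("x is constant; slope is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients[2, 4])
}

#' Boxplot statistics with 1.5 IQR arms
#'
#' Quartiles use the linear-interpolation convention (type 7); the whisker
#' arms sit at Q1 - 1.5 IQR and Q3 + 1.5 IQR and values outside them are the
#' outliers.
#'
#' @param values numeric vector, n >= 4.
#' @return list (class \code{box_stats}) with \code{median}, \code{q1},
#'   \code{q3}, \code{iqr}, \code{lower_arm}, \code{upper_arm},
#'   \code{outliers}.
#' @export
boxplot_stats <- function(values) {
  if (length(values) < 4L) stop("need n >= 4 for quartile statistics")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[3] + 1.5 * iqr
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 lower_arm = lower, upper_arm = upper,
                 outliers = values[values < lower | values > upper]),
            class = "box_stats")
}

#' Positivity calls over a plate
#'
#' Calls each (sample, antigen) cell positive when its absorbance strictly
#' exceeds the cut-off. The cut-off is either fixed
#' (\code{list(type = "fixed", value = )}) or control-based
#' (\code{list(type = "control", sample = )}: per-antigen cut-off at the
#' control sample's reading).
#'
#' @param plate a \code{plate_data}.
#' @param cutoff_rule cut-off specification (see Details).
#' @return list with \code{calls} (logical matrix, control row dropped for
#'   control-based rules), \code{positives_per_antigen},
#'   \code{positives_per_sample}.
#' @export
positivity_table <- function(plate, cutoff_rule) {
  stopifnot(inherits(plate, "plate_data"))
  ab <- plate$absorbance
  if (identical(cutoff_rule$type, "fixed")) {
    cut <- rep(cutoff_rule$value, ncol(ab))
  } else if (identical(cutoff_rule$type, "control")) {
    if (is.null(cutoff_rule$sample) || !cutoff_rule$sample %in% rownames(ab))
      stop("control sample missing for control-based cut-off")
    cut <- ab[cutoff_rule$sample, ]
    ab <- ab[setdiff(rownames(ab), cutoff_rule$sample), , drop = FALSE]
  } else stop("cutoff_rule$type must be \"fixed\" or \"control\"")
  calls <- sweep(ab, 2L, cut, `>`)
  list(calls = calls,
       positives_per_antigen = colSums(calls),
       positives_per_sample = rowSums(calls))
}

#' Write / read a plate as CSV (first column sample id)
#' @param plate a \code{plate_data}.
#' @param path file path.
#' @export
write_plate_csv <- function(plate, path) {
  d <- data.frame(sample = plate$sample_labels, plate$absorbance,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @param group_of_antigen optional antigen group map for the read plate.
#' @export
read_plate_csv <- function(path, group_of_antigen = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  plate_data(m, group_of_antigen = group_of_antigen)
}
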