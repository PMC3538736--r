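#' Paired left/right perfusion measurements
#'
#' One row per subject and method: cortical renal blood flow of the left and
#' right kidney, plus which side (if any) carries the induced injury. A
#' subject with `diseased_side = "none"` contributes both kidneys to the
#' healthy group and is excluded from paired healthy-vs-diseased contrasts.
#'
#' @param subject_ids subject labels.
#' @param left_values,right_values cortical RBF, ml/100 g/min (> 0).
#' @param method `"ASL"` or `"DCE"`.
#' @param diseased_side per subject, one of `"left"`, `"right"`, `"none"`.
#' @return object of class `paired_comparison` (a data.frame).
#' @export
paired_comparison <- function(subject_ids, left_values, right_values,
                              method = c("ASL", "DCE"),
                              diseased_side) {
  method <- match.arg(method)
  n <- length(subject_ids)
  if (length(left_values) != n || length(right_values) != n ||
      length(diseased_side) != n)
    stop("all fields must have one entry per subject", call. = FALSE)
  if (any(left_values <= 0) || any(right_values <= 0))
    stop("RBF values must be positive", call. = FALSE)
  if (!all(diseased_side %in% c("left", "right", "none")))
    stop("`diseased_side` must be 'left', 'right' or 'none'", call. = FALSE)
  structure(data.frame(subject = subject_ids, method = method,
                       left = as.numeric(left_values),
                       right = as.numeric(right_values),
                       diseased_side = diseased_side,
                       stringsAsFactors = FALSE),
            class = c("paired_comparison", "data.frame"))
}

#' Read a per-animal RBF table
#'
#' Reads a CSV with columns `subject, method, left_rbf, right_rbf,
#' diseased_side` and returns one [paired_comparison()] per method. The
#' packaged fixture `table1.csv` carries the study's per-animal cortical
#' RBF values for both modalities.
#'
#' @param path CSV path; default is the packaged per-animal table.
#' @return named list of `paired_comparison` objects (one per method).
#' @export
read_rbf_table <- function(path = system.file("extdata", "table1.csv",
                                              package = "renperf")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "method", "left_rbf", "right_rbf", "diseased_side")
  if (!all(need %in% names(df)))
    stop("RBF table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  lapply(split(df, df$method), function(d)
    paired_comparison(d$subject, d$left_rbf, d$right_rbf,
                      method = d$method[1], diseased_side = d$diseased_side))
}

#' Read a repeated-measurement RBF table
#'
#' CSV with columns `subject, kidney, measurement, rbf`; the packaged
#' fixture `table2.csv` carries repeated ASL scans of two animals.
#'
#' @param path CSV path; default is the packaged repeats table.
#' @return named list of numeric repeat vectors, one per `subject.kidney`.
#' @export
read_repeats_table <- function(path = system.file("extdata", "table2.csv",
                                                  package = "renperf")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "kidney", "measurement", "rbf")
  if (!all(need %in% names(df)))
    stop("repeats table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$subject, df$kidney, df$measurement), ]
  split(df$rbf, interaction(df$subject, df$kidney, drop = TRUE, lex.order = TRUE))
}

sd_ddof <- function(x, ddof) {
  n <- length(x)
  if (ddof == 1) stats::sd(x) else sqrt(sum((x - mean(x))^2) / n)
}

#' Mean and standard deviation of a group of RBF values
#'
#' @param values numeric vector (n >= 2).
#' @param ddof degrees-of-freedom correction for the SD: 1 (sample SD, used
#'   for group summaries) or 0 (population SD, used for difference and
#'   repeatability summaries).
#' @return named list `mean`, `sd`, `n`.
#' @export
group_summary <- function(values, ddof = 1) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (!ddof %in% c(0, 1)) stop("`ddof` must be 0 or 1", call. = FALSE)
  list(mean = mean(values), sd = sd_ddof(values, ddof), n = length(values))
}

#' Split paired measurements into diseased and healthy groups
#'
#' The diseased group holds the injured-side value of each subject with a
#' unilateral injury. The healthy group holds the contralateral values plus
#' both kidneys of any all-healthy subject.
#'
#' @param pc a [paired_comparison()].
#' @return list of numeric vectors `diseased`, `healthy`.
#' @export
split_by_condition <- function(pc) {
  stopifnot(inherits(pc, "paired_comparison"))
  diseased <- healthy <- numeric(0)
  for (i in seq_len(nrow(pc))) {
    side <- pc$diseased_side[i]
    if (side == "none") {
      healthy <- c(healthy, pc$left[i], pc$right[i])
    } else {
      diseased <- c(diseased, if (side == "left") pc$left[i] else pc$right[i])
      healthy <- c(healthy, if (side == "left") pc$right[i] else pc$left[i])
    }
  }
  list(diseased = diseased, healthy = healthy)
}

#' Per-subject healthy-minus-diseased RBF differences
#'
#' Subjects without a diseased side are excluded.
#'
#' @param pc a [paired_comparison()].
#' @return numeric vector of differences, ml/100 g/min.
#' @export
paired_differences <- function(pc) {
  stopifnot(inherits(pc, "paired_comparison"))
  sel <- pc$diseased_side != "none"
  if (!any(sel)) stop("no subjects with a diseased side", call. = FALSE)
  d <- pc[sel, ]
  ifelse(d$diseased_side == "left", d$right - d$left, d$left - d$right)
}

#' Paired sample t-test on healthy-minus-diseased differences
#'
#' Two-sided one-sample t-test of the differences against zero,
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom
#' (delegates to [stats::t.test()]).
#'
#' @param diffs numeric difference vector (n >= 2, not all equal).
#' @param alternative passed to [stats::t.test()]; two-sided by default.
#' @return list `t_stat`, `df`, `p_two_sided`.
#' @export
paired_t_test <- function(diffs, alternative = "two.sided") {
  if (length(diffs) < 2) stop("need at least two differences", call. = FALSE)
  if (sd_ddof(diffs, 1) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(diffs, mu = 0, alternative = alternative)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value)
}

#' Bland-Altman summary of paired differences
#'
#' Mean difference, population standard deviation (ddof 0) and limits of
#' agreement `mean +/- 1.96 * sd`.
#'
#' @param diffs numeric difference vector (n >= 2).
#' @return list `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(diffs) {
  if (length(diffs) < 2) stop("need at least two differences", call. = FALSE)
  m <- mean(diffs); s <- sd_ddof(diffs, 0)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Left/right cortical RBF ratios
#'
#' @param pc a [paired_comparison()].
#' @param digits decimal places for reporting (default 2; `NULL` for
#'   unrounded).
#' @return numeric vector of left/right ratios, one per subject.
#' @export
lr_ratio <- function(pc, digits = 2) {
  stopifnot(inherits(pc, "paired_comparison"))
  if (any(pc$right == 0)) stop("zero right-kidney RBF: ratio undefined", call. = FALSE)
  r <- pc$left / pc$right
  if (!is.null(digits)) r <- round(r, digits)
  stats::setNames(r, pc$subject)
}

#' Repeatability summary of repeated measurements
#'
#' Mean and population SD (ddof 0) per kidney across repeated scans.
#'
#' @param repeated named list of numeric repeat vectors (>= 2 repeats each).
#' @return data.frame with columns `kidney`, `mean`, `sd`, `n`.
#' @export
repeatability_summary <- function(repeated) {
  stopifnot(is.list(repeated), length(repeated) >= 1)
  if (any(vapply(repeated, length, 1L) < 2))
    stop("each kidney needs at least two repeats", call. = FALSE)
  data.frame(
    kidney = names(repeated),
    mean = vapply(repeated, mean, numeric(1)),
    sd = vapply(repeated, sd_ddof, numeric(1), ddof = 0),
    n = vapply(repeated, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Full statistical report from per-animal tables
#'
#' Reproduces the study's printed summaries from a per-animal RBF table and
#' an optional repeats table: group means/SDs (sample SD, ddof 1),
#' healthy-minus-diseased paired differences with Bland-Altman limits
#' (population SD, ddof 0), two-sided paired t-tests, left/right ratios, and
#' per-kidney repeatability (ddof 0).
#'
#' @param comparisons named list of [paired_comparison()] objects (as
#'   returned by [read_rbf_table()]).
#' @param repeats optional named list of repeat vectors (see
#'   [read_repeats_table()]).
#' @return nested list, one entry per method plus optional `repeatability`.
#' @export
table_report <- function(comparisons, repeats = NULL) {
  out <- lapply(comparisons, function(pc) {
    grp <- split_by_condition(pc)
    diffs <- paired_differences(pc)
    list(
      diseased = group_summary(grp$diseased, ddof = 1),
      healthy = group_summary(grp$healthy, ddof = 1),
      differences = diffs,
      bland_altman = bland_altman(diffs),
      t_test = paired_t_test(diffs),
      lr_ratios = lr_ratio(pc)
    )
  })
  if (!is.null(repeats)) out$repeatability <- repeatability_summary(repeats)
  out
}
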