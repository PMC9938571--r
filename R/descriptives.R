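#' Chi-square test of independence for a contingency table
#'
#' Pearson chi-square with Yates continuity correction for 2x2 tables
#' (per-cell |O - E| reduced by 0.5, clamped at 0) and the plain Pearson
#' statistic for larger tables; df = (r-1)(c-1), p from the upper tail.
#'
#' @param counts r x c matrix of non-negative integer counts (r, c >= 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(
    stats::chisq.test(counts, correct = all(dim(counts) == 2L)))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Printed descriptive counts by relationship group (fixture)
#'
#' The published two-group descriptive table of the cohort the package's
#' synthetic generator emulates, as printed counts: baseline
#' characteristics cross-tabulated by downward versus two-way
#' multi-generational relationship. Used as an exact fixture for the
#' descriptive statistics.
#'
#' @return data frame with columns `variable`, `level`, `downward`,
#'   `twoway`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "morbstate")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Chi-square statistics for every variable of a grouped count table
#'
#' @param counts long data frame as from [table1_counts()].
#' @return data frame: variable, statistic, df, p.
#' @export
grouped_chi_square <- function(counts) {
  out <- lapply(split(counts, counts$variable), function(d) {
    res <- chi_square_test(as.matrix(d[, c("downward", "twoway")]))
    data.frame(variable = d$variable[1L], statistic = res$statistic,
               df = res$df, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Baseline descriptive table by a binary group
#'
#' Counts and column percentages of each covariate level by group, with a
#' chi-square test per covariate (Yates for 2x2, plain Pearson otherwise).
#' Single-level covariates are flagged and carry no test. Statistics are
#' symmetric in the group labels.
#'
#' @param panel panel data frame; only baseline records
#'   (`years_since_baseline == 0`) are used.
#' @param group_variable name of the binary group column.
#' @param covariates covariate columns to tabulate; numeric columns with
#'   more than 6 distinct values are skipped.
#' @return data frame: variable, level, count and percentage per group
#'   level, chi-square statistic, df, p (repeated on each level row).
#' @export
cohort_characteristics_table <- function(panel, group_variable,
                                         covariates) {
  base <- panel[panel$years_since_baseline == 0, , drop = FALSE]
  if (!group_variable %in% names(base))
    stop("missing group column: ", group_variable)
  g <- base[[group_variable]]
  if (length(unique(g)) != 2L) stop("group variable must be binary")
  glev <- sort(unique(g))
  rows <- list()
  for (cn in covariates) {
    if (!cn %in% names(base)) stop("missing covariate column: ", cn)
    v <- base[[cn]]
    if (is.numeric(v) && length(unique(v)) > 6L) next
    tab <- table(v, g)
    if (nrow(tab) < 2L) {
      rows[[cn]] <- data.frame(variable = cn, level = rownames(tab),
                               n1 = tab[, 1L], n2 = tab[, 2L],
                               pct1 = 100, pct2 = 100,
                               statistic = NA_real_, df = NA_real_,
                               p = NA_real_, note = "single level",
                               stringsAsFactors = FALSE)
      next
    }
    res <- chi_square_test(unclass(tab))
    rows[[cn]] <- data.frame(
      variable = cn, level = rownames(tab),
      n1 = as.integer(tab[, 1L]), n2 = as.integer(tab[, 2L]),
      pct1 = round(100 * tab[, 1L] / sum(tab[, 1L]), 1),
      pct2 = round(100 * tab[, 2L] / sum(tab[, 2L]), 1),
      statistic = res$statistic, df = res$df, p = res$p, note = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "n1"] <- paste0("n_", glev[1L])
  names(out)[names(out) == "n2"] <- paste0("n_", glev[2L])
  names(out)[names(out) == "pct1"] <- paste0("pct_", glev[1L])
  names(out)[names(out) == "pct2"] <- paste0("pct_", glev[2L])
  out
}

#' Apply cohort inclusion criteria with an attrition log
#'
#' Applies, in order: (a) responded to more than two surveys, (b) baseline
#' age >= 45, (c) at least one living parent or parent-in-law, (d) at
#' least one living child, (e) weekly contact with children; then drops
#' respondents flagged for abnormal follow-up outcome data and finally
#' those with missing covariate data. Each step is logged with the number
#' excluded.
#'
#' @param raw one row per respondent with logical/integer columns
#'   `n_surveys`, `age_baseline`, `living_parent`, `living_child`,
#'   `weekly_contact_children`, `abnormal_outcome`, `missing_covariate`.
#' @return list with `retained` (filtered data frame) and `attrition`
#'   (data frame: criterion, n_before, n_excluded, n_after).
#' @export
apply_inclusion_criteria <- function(raw) {
  steps <- list(
    list("responded to more than two surveys", function(d) d$n_surveys > 2),
    list("baseline age >= 45", function(d) d$age_baseline >= 45),
    list("at least one living parent or parent-in-law",
         function(d) as.logical(d$living_parent)),
    list("at least one living child", function(d) as.logical(d$living_child)),
    list("weekly contact with children",
         function(d) as.logical(d$weekly_contact_children)),
    list("abnormal follow-up outcome data",
         function(d) !as.logical(d$abnormal_outcome)),
    list("missing covariate data", function(d) !as.logical(d$missing_covariate))
  )
  need <- c("n_surveys", "age_baseline", "living_parent", "living_child",
            "weekly_contact_children", "abnormal_outcome", "missing_covariate")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing flag column(s): ", paste(miss, collapse = ", "))
  log <- list()
  for (s in steps) {
    keep <- s[[2]](raw)
    log[[length(log) + 1L]] <- data.frame(
      criterion = s[[1]], n_before = nrow(raw),
      n_excluded = sum(!keep), n_after = sum(keep),
      stringsAsFactors = FALSE)
    raw <- raw[keep, , drop = FALSE]
  }
  list(retained = raw, attrition = do.call(rbind, log))
}

#' Synthetic respondent-flag table reproducing the published attrition flow
#'
#' Deterministically constructs a 25,586-respondent flag table in which
#' 6,799 respondents satisfy the five inclusion criteria, 23 of them are
#' flagged for abnormal follow-up outcomes and a further 8 for missing
#' covariates, so [apply_inclusion_criteria()] retains 6,768. Only the
#' attrition counts are meaningful; all other structure is synthetic.
#'
#' @return data frame of respondent flags.
#' @export
attrition_fixture <- function() {
  n_total <- 25586L; n_eligible <- 6799L
  n_rest <- n_total - n_eligible
  d <- data.frame(
    respondent = seq_len(n_total),
    n_surveys = 3L, age_baseline = 60, living_parent = 1L,
    living_child = 1L, weekly_contact_children = 1L,
    abnormal_outcome = 0L, missing_covariate = 0L)
  # ineligible remainder: spread failures over the five criteria
  idx <- n_eligible + seq_len(n_rest)
  fail <- rep(1:5, length.out = n_rest)
  d$n_surveys[idx[fail == 1]] <- 2L
  d$age_baseline[idx[fail == 2]] <- 40
  d$living_parent[idx[fail == 3]] <- 0L
  d$living_child[idx[fail == 4]] <- 0L
  d$weekly_contact_children[idx[fail == 5]] <- 0L
  d$abnormal_outcome[1:23] <- 1L
  d$missing_covariate[24:31] <- 1L
  d
}
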