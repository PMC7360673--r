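#' Clinical-table group statistics
#'
#' Demographic / functional tables are compared between groups with
#' Fisher's exact test (categorical variables) and the Mann-Whitney U test
#' (continuous variables), and summarised as "median [IQR]" or "n [%]",
#' mirroring the layout of a typical two-group clinical characteristics
#' table.
#'
#' @name clinical_stats
NULL

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Probability-mass convention: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within a small relative tolerance
#' for ties).
#'
#' @param table 2x2 matrix of non-negative integer counts; both row and both
#'   column margins must be positive.
#' @return two-sided p-value.
#' @export
#' @examples
#' # gender by group: 21/34 vs 15/20 female
#' fisher_exact_2x2(matrix(c(21, 13, 15, 5), 2, byrow = TRUE))  # 0.381
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a table margin is zero")
  fisher.test(table)$p.value
}

#' Mann-Whitney U test
#'
#' Exact mode enumerates the permutation distribution of U over all
#' `choose(m + n, m)` assignments of the pooled (mid-ranked) observations,
#' which is feasible for `m + n <= 14` and handles ties exactly. Approximate
#' mode uses the normal approximation with tie and continuity corrections.
#' The default picks exact for `m + n <= 14`.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(c(x, y))) == 1)
    return(list(U = U, p = 1))
  if (mode == "auto") mode <- if (m + n <= 14) "exact" else "normal_approx"
  if (mode == "exact") {
    splits <- combn(m + n, m)
    Us <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
    dev <- abs(Us - m * n / 2)
    p <- mean(dev >= abs(U - m * n / 2) - 1e-9)
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  list(U = U, p = min(1, p))
}

#' Assemble a typed clinical table
#'
#' @param data data.frame with columns `subject_id`, `group` and one column
#'   per clinical variable.
#' @param types named character vector mapping each variable to
#'   `"categorical"` or `"continuous"`.
#' @return object of class `plv_clinical`.
#' @export
clinical_table <- function(data, types) {
  stopifnot(is.data.frame(data), all(c("subject_id", "group") %in% names(data)))
  vars <- setdiff(names(data), c("subject_id", "group"))
  if (length(vars) == 0) stop("table has no clinical variables")
  missing_t <- setdiff(vars, names(types))
  if (length(missing_t))
    stop("untyped variable(s): ", paste(missing_t, collapse = ", "))
  bad <- !types[vars] %in% c("categorical", "continuous")
  if (any(bad))
    stop("unknown variable type for: ",
         paste(vars[bad], collapse = ", "))
  g <- as.factor(data$group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  if (any(table(g) < 1)) stop("both groups need at least one subject")
  structure(list(data = data, types = types[vars], vars = vars,
                 group_levels = levels(g)),
            class = "plv_clinical")
}

iqr_text <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  sprintf("%.2f [%.2f, %.2f]", q[1], q[2], q[3])
}

#' Summarise a clinical table with group comparisons
#'
#' Continuous variables: per-group "median [25th, 75th percentile]" (linear
#' interpolation between order statistics) and a Mann-Whitney p. Categorical
#' variables: per-group "count [percent]" of the reference (first) level and
#' a Fisher p (2x2 for binary variables, the generalised exact test
#' otherwise).
#'
#' @param table a [clinical_table()].
#' @param mw_mode Mann-Whitney mode, see [mann_whitney_u()].
#' @return data.frame of class `plv_clinical_summary`: one row per variable
#'   with columns `variable`, `type`, per-group summaries, `test`, `p`.
#' @export
summarize_clinical <- function(table, mw_mode = "auto") {
  stopifnot(inherits(table, "plv_clinical"))
  g <- as.factor(table$data$group)
  lv <- table$group_levels
  rows <- lapply(table$vars, function(v) {
    val <- table$data[[v]]
    ok <- !is.na(val)
    if (table$types[[v]] == "continuous") {
      x <- val[ok & g == lv[1]]; y <- val[ok & g == lv[2]]
      p <- mann_whitney_u(x, y, mode = mw_mode)$p
      data.frame(variable = v, type = "continuous",
                 group1 = iqr_text(x), group2 = iqr_text(y),
                 test = "mann_whitney_u", p = p,
                 stringsAsFactors = FALSE)
    } else {
      f <- as.factor(val[ok])
      tab <- table(f, droplevels(g[ok]))
      p <- if (nrow(tab) == 2) fisher_exact_2x2(t(tab)) else
        fisher.test(tab)$p.value
      ref <- levels(f)[1]
      cnt <- tab[ref, lv]
      tot <- colSums(tab)[lv]
      data.frame(variable = v, type = "categorical",
                 group1 = sprintf("%d [%.2f]", cnt[1], 100 * cnt[1] / tot[1]),
                 group2 = sprintf("%d [%.2f]", cnt[2], 100 * cnt[2] / tot[2]),
                 test = "fisher_exact", p = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(lv, c("", ""))
  class(out) <- c("plv_clinical_summary", "data.frame")
  out
}

#' Read a clinical table (TSV + JSON typing sidecar)
#'
#' @param tsv_path tab-separated table with `subject_id` and `group` columns.
#' @param types_path JSON object mapping variable names to types.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(tsv_path, types_path) {
  dat <- read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE)
  types <- unlist(jsonlite::fromJSON(types_path))
  clinical_table(dat, types)
}
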