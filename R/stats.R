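#' Chi-squared test and fold enrichment for a 2x2 table
#'
#' Pearson chi-squared test on the table `rbind(c(a, b), c(c, d))` with rows
#' = groups (e.g. reporter-active vs nonactive TLs) and columns = feature
#' present/absent. Fold enrichment is the ratio of presence proportions,
#' `(a/(a+b)) / (c/(c+d))`. Yates continuity correction is off by default
#' and available as a flag.
#'
#' @param a,b Present/absent counts in group 1.
#' @param c,d Present/absent counts in group 2.
#' @param correction Apply Yates continuity correction (default FALSE).
#' @return One-row tibble: counts, `statistic`, `p_value`,
#'   `fold_enrichment`, `correction`.
#' @examples
#' chi2_2x2(20, 10, 10, 20)
#' @export
chi2_2x2 <- function(a, b, c, d, correction = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) abort("chi2_2x2: negative count")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("chi2_2x2: zero row or column margin, p undefined")
  }
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = correction))
  tibble(
    a = a, b = b, c = c, d = d,
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    fold_enrichment = (a / (a + b)) / (c / (c + d)),
    correction = correction
  )
}

#' Wilcoxon rank-sum test (midranks, exact or normal approximation)
#'
#' Two-sided test of location shift between two samples. The reported
#' statistic is the rank-sum of `x` (midranks under ties). The p-value is
#' exact (from the null rank-sum distribution) when both samples have at
#' most `exact_max_n` observations and there are no ties; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used. Identical constant samples give p = 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max_n Largest per-group size for the exact method
#'   (default 10).
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n_x`, `n_y`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 10) {
  if (length(x) == 0 || length(y) == 0) abort("wilcoxon_rank_sum: empty group")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && m <= exact_max_n && n <= exact_max_n) {
    U <- W - m * (m + 1) / 2
    p <- 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- m * (m + n + 1) / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approx"
  }
  tibble(statistic = W, p_value = p, method = method, n_x = m, n_y = n)
}

#' Enrichment test of one feature between active and nonactive TLs
#'
#' Binary features are tested by 2x2 chi-squared (presence/absence by
#' label, with fold enrichment); numeric features by the Wilcoxon rank-sum
#' test. Rows with `label` outside active/nonactive and rows missing the
#' feature are dropped; the sizes actually compared are reported.
#'
#' @param table Feature-table tibble with a `label` column.
#' @param feature Feature column name.
#' @param kind `"auto"` (logical/two-valued-integer columns are binary),
#'   `"binary"` or `"numeric"`.
#' @param correction Yates correction for the chi-squared branch.
#' @return One-row tibble: `feature`, `kind`, `statistic`, `p_value`,
#'   `fold_enrichment` (NA for numeric), `n_active`, `n_nonactive`.
#' @export
enrichment_report <- function(table, feature, kind = c("auto", "binary", "numeric"),
                              correction = FALSE) {
  kind <- match.arg(kind)
  if (!feature %in% names(table)) {
    abort(sprintf("enrichment_report: no feature column '%s'", feature))
  }
  x <- table |>
    filter(.data$label %in% c("active", "nonactive"), !is.na(.data[[feature]]))
  if (length(unique(x$label)) < 2) {
    abort("enrichment_report: need both active and nonactive rows")
  }
  v <- x[[feature]]
  if (kind == "auto") {
    kind <- if (is.logical(v) || all(v %in% c(0, 1, TRUE, FALSE))) "binary" else "numeric"
  }
  act <- x$label == "active"
  if (kind == "binary") {
    v <- as.logical(v)
    res <- chi2_2x2(sum(v[act]), sum(!v[act]), sum(v[!act]), sum(!v[!act]),
                    correction = correction)
    tibble(feature = feature, kind = "binary",
           statistic = res$statistic, p_value = res$p_value,
           fold_enrichment = res$fold_enrichment,
           n_active = sum(act), n_nonactive = sum(!act))
  } else {
    res <- wilcoxon_rank_sum(v[act], v[!act])
    tibble(feature = feature, kind = "numeric",
           statistic = res$statistic, p_value = res$p_value,
           fold_enrichment = NA_real_,
           n_active = sum(act), n_nonactive = sum(!act))
  }
}

#' Enrichment battery over all feature columns
#'
#' Applies [enrichment_report()] to every feature column (everything except
#' `tl_id`, `label`, `hyperconserved`), auto-detecting binary vs numeric.
#'
#' @param table Feature-table tibble.
#' @param features Optional character vector restricting the columns tested.
#' @return Tibble with one row per feature, ordered by p-value.
#' @export
enrichment_battery <- function(table, features = NULL) {
  candidates <- setdiff(names(table), c("tl_id", "label", "hyperconserved"))
  if (!is.null(features)) candidates <- intersect(features, candidates)
  rows <- lapply(candidates, function(f) {
    n_ok <- sum(!is.na(table[[f]]) & table$label %in% c("active", "nonactive"))
    if (n_ok == 0) return(NULL)
    v <- table[[f]][!is.na(table[[f]])]
    if (length(unique(v)) < 2) return(NULL) # constant: no test possible
    enrichment_report(table, f)
  })
  list_rbind(rows[!vapply(rows, is.null, logical(1))]) |>
    arrange(.data$p_value)
}
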