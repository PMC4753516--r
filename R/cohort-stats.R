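# Cohort-level statistics: nonparametric group comparisons and the
# tertile-coded multiple linear regression with the dual-model
# (univariate AND multivariate) significance rule.

GROUP_LEVELS <- c("SHF", "HFpEF", "non-HF")

#' Compare one variable across cohort groups
#'
#' Continuous variables: Kruskal-Wallis omnibus test with pairwise
#' Mann-Whitney (Wilcoxon rank-sum) post-hoc comparisons, summarized as
#' medians and interquartile ranges. Categorical variables: chi-square test
#' on the contingency table, summarized as percentages.
#'
#' @param table Cohort data frame.
#' @param variable Name of the column to compare (string).
#' @param group Name of the grouping column (default `"group"`).
#' @return A `group_comparison` list: `variable`, `type`, `summary` (tibble
#'   per group), `omnibus` (tibble: method, statistic, p.value), `pairwise`
#'   (tibble of post-hoc p-values; continuous only).
#' @export
compare_groups <- function(table, variable, group = "group") {
  stopifnot(is.data.frame(table), variable %in% names(table),
            group %in% names(table))
  g <- factor(table[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) < 3L)) stop("each group needs at least 3 subjects", call. = FALSE)
  x <- table[[variable]]

  if (is.numeric(x)) {
    if (diff(range(x)) == 0) {
      stop(sprintf("`%s` is constant; nothing to compare", variable), call. = FALSE)
    }
    kw <- stats::kruskal.test(x, g)
    summary_tbl <- tibble::tibble(group = levels(g)) |>
      dplyr::mutate(
        n = as.integer(table(g)[.data$group]),
        median = vapply(.data$group, function(l) stats::median(x[g == l]), numeric(1)),
        q1 = vapply(.data$group, function(l) unname(stats::quantile(x[g == l], 0.25)), numeric(1)),
        q3 = vapply(.data$group, function(l) unname(stats::quantile(x[g == l], 0.75)), numeric(1))
      )
    pairs <- utils::combn(levels(g), 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(pairs, function(p) {
      w <- suppressWarnings(stats::wilcox.test(x[g == p[1]], x[g == p[2]]))
      tibble::tibble(group1 = p[1], group2 = p[2], p.value = w$p.value)
    })
    out <- list(variable = variable, type = "continuous", summary = summary_tbl,
                omnibus = tibble::tibble(method = "Kruskal-Wallis",
                                         statistic = unname(kw$statistic),
                                         p.value = kw$p.value),
                pairwise = pairwise)
  } else {
    xf <- factor(x)
    if (nlevels(xf) < 2L) {
      stop(sprintf("`%s` is constant; nothing to compare", variable), call. = FALSE)
    }
    tab <- base::table(xf, g)
    cs <- suppressWarnings(stats::chisq.test(tab))
    summary_tbl <- tibble::as_tibble(prop.table(tab, margin = 2) * 100,
                                     .name_repair = "minimal")
    names(summary_tbl) <- c("level", "group", "pct")
    out <- list(variable = variable, type = "categorical", summary = summary_tbl,
                omnibus = tibble::tibble(method = "Chi-square",
                                         statistic = unname(cs$statistic),
                                         p.value = cs$p.value),
                pairwise = NULL)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): %s p = %.4g\n", x$variable, x$type,
              x$omnibus$method, x$omnibus$p.value))
  print(x$summary)
  invisible(x)
}

#' Encode a continuous column into tertiles
#'
#' Rank-based thirds with boundary ties assigned to the lower tertile; for
#' columns without ties the three groups differ in size by at most one.
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @return Factor with levels `T1`, `T2`, `T3` and attribute `cuts`, the two
#'   upper boundaries of T1 and T2.
#' @export
tertile_encode <- function(x) {
  if (!is.numeric(x)) stop("tertile encoding needs a numeric column", call. = FALSE)
  if (length(unique(x)) < 3L) {
    stop("fewer than 3 distinct values; tertiles are undefined", call. = FALSE)
  }
  n <- length(x)
  s <- sort(x)
  cuts <- c(s[ceiling(n / 3)], s[ceiling(2 * n / 3)])
  f <- cut(x, breaks = c(-Inf, cuts, Inf), labels = c("T1", "T2", "T3"),
           right = TRUE)  # ties at a boundary fall in the lower tertile
  attr(f, "cuts") <- cuts
  f
}

# Table-3-style covariate coding: age and LVEF bands, tertiles for LVMi,
# LVEDVi and ECV, binary flags otherwise. Band edges are exposed because the
# source bands are configurable.
code_covariates <- function(table, age_bands = c(60, 75), lvef_bands = c(35, 50)) {
  need <- c("age_years", "gender", "htn", "dm", "etiology", "lge",
            "lvmi", "lvedvi", "lvef", "ecv_pct")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    age_band = cut(table$age_years, c(-Inf, age_bands, Inf),
                   labels = c(sprintf("<%g", age_bands[1]),
                              sprintf("%g-%g", age_bands[1], age_bands[2]),
                              sprintf(">=%g", age_bands[2])), right = FALSE),
    gender = factor(table$gender, levels = c("female", "male")),
    htn = as.integer(table$htn),
    dm = as.integer(table$dm),
    etiology = factor(table$etiology, levels = c("non-CAD", "CAD")),
    lge = as.integer(table$lge),
    lvmi_tertile = tertile_encode(table$lvmi),
    lvedvi_tertile = tertile_encode(table$lvedvi),
    lvef_band = cut(table$lvef, c(-Inf, lvef_bands, Inf),
                    labels = c("<35", "35-50", ">=50"), right = FALSE) |>
      factor(levels = c(">=50", "35-50", "<35")),
    ecv_tertile = tertile_encode(table$ecv_pct)
  )
}

#' Fit the tertile-coded outcome regression with the dual significance rule
#'
#' Ordinary least squares of a trabeculation outcome on the standard
#' covariate set: age bands, gender, hypertension, diabetes, heart-failure
#' etiology (CAD vs non-CAD), LGE, and tertiles of LVMi, LVEDVi and ECV plus
#' LVEF bands. Each predictor is fit univariately and all together
#' multivariately; an association is flagged as final only when both models
#' are significant. P-values of multi-level factors are Bonferroni-adjusted
#' across their level contrasts before flagging. Rows with missing values in
#' modeled columns are dropped (complete-case) with a recorded count.
#'
#' @param table Cohort data frame (see [generate_cohort_table()] for the
#'   column schema).
#' @param outcome One of `"tpmi"`, `"tpm_lvm_ratio"`, `"fd"`.
#' @param age_bands,lvef_bands Band edges for the age and LVEF factors.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `tpm_regression` object: tibble `table` with one row per
#'   predictor level (term, level, estimate, conf.low, conf.high, p.multi,
#'   p.uni, n_level_contrasts, uni_sig, multi_sig, final_sig) plus fit
#'   metadata.
#' @export
fit_outcome_model <- function(table, outcome = c("tpmi", "tpm_lvm_ratio", "fd"),
                              age_bands = c(60, 75), lvef_bands = c(35, 50),
                              alpha = 0.05) {
  outcome <- match.arg(outcome)
  if (!outcome %in% names(table)) {
    stop(sprintf("outcome column `%s` not found", outcome), call. = FALSE)
  }
  coded <- code_covariates(table, age_bands, lvef_bands)
  dat <- dplyr::bind_cols(tibble::tibble(.y = table[[outcome]]), coded)
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]

  preds <- names(coded)
  mv <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(mv))) {
    aliased <- names(stats::coef(mv))[is.na(stats::coef(mv))]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  ci <- suppressWarnings(stats::confint(mv))
  smv <- suppressWarnings(summary(mv)$coefficients)  # exact fits warn harmlessly

  rows <- purrr::map_dfr(preds, function(p) {
    uni <- stats::lm(stats::reformulate(p, ".y"), data = dat)
    suni <- suppressWarnings(summary(uni)$coefficients)
    x <- dat[[p]]
    lev_terms <- if (is.factor(x)) paste0(p, levels(x)[-1]) else p
    lev_names <- if (is.factor(x)) levels(x)[-1] else p
    k <- length(lev_terms)  # contrasts within this predictor
    purrr::map_dfr(seq_along(lev_terms), function(i) {
      tn <- lev_terms[i]
      tibble::tibble(
        term = p, level = lev_names[i],
        estimate = unname(smv[tn, "Estimate"]),
        conf.low = ci[tn, 1], conf.high = ci[tn, 2],
        p.multi = unname(smv[tn, "Pr(>|t|)"]),
        p.uni = unname(suni[tn, "Pr(>|t|)"]),
        n_level_contrasts = k
      )
    })
  })

  # Bonferroni across level contrasts of multi-level (>= 3 level) factors
  adj <- function(p, k) pmin(1, p * ifelse(k >= 2, k, 1))
  rows <- rows |>
    dplyr::mutate(
      p.multi.adj = adj(.data$p.multi, .data$n_level_contrasts),
      p.uni.adj = adj(.data$p.uni, .data$n_level_contrasts),
      uni_sig = .data$p.uni.adj < alpha,
      multi_sig = .data$p.multi.adj < alpha,
      final_sig = .data$uni_sig & .data$multi_sig
    )
  stopifnot(all(!rows$final_sig | (rows$uni_sig & rows$multi_sig)))

  structure(list(table = rows, outcome = outcome, n = nrow(dat),
                 n_dropped = n_dropped, alpha = alpha,
                 r.squared = suppressWarnings(summary(mv)$r.squared),
                 adj.r.squared = suppressWarnings(summary(mv)$adj.r.squared),
                 tertile_cuts = list(
                   lvmi = attr(coded$lvmi_tertile, "cuts"),
                   lvedvi = attr(coded$lvedvi_tertile, "cuts"),
                   ecv = attr(coded$ecv_tertile, "cuts"))),
            class = "tpm_regression")
}

#' @export
print.tpm_regression <- function(x, ...) {
  cat(sprintf("outcome %s: n = %d (%d dropped), R^2 = %.3f\n",
              x$outcome, x$n, x$n_dropped, x$r.squared))
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_outcome_model
#' @param x A `tpm_regression` object.
#' @param ... Unused.
#' @export
tidy.tpm_regression <- function(x, ...) x$table

#' @rdname fit_outcome_model
#' @export
glance.tpm_regression <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n, n_dropped = x$n_dropped,
                 r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
                 alpha = x$alpha)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) x$summary else
    dplyr::mutate(x$pairwise, variable = x$variable, .before = 1)
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, variable = x$variable, .before = 1)
}
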