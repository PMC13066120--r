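#' Greenhouse-Geisser epsilon (Box's estimate)
#'
#' Computes Box's sphericity-correction factor from the covariance matrix
#' of the `k` repeated measures: with `S_dc` the double-centered
#' covariance, `epsilon = tr(S_dc)^2 / ((k - 1) * sum(S_dc^2))`, bounded in
#' `[1/(k - 1), 1]`. Equals 1 exactly under compound symmetry and always
#' when `k = 2` (sphericity is vacuous with two levels).
#'
#' @param within_covariance Symmetric positive semi-definite `k x k`
#'   covariance matrix of the within-subject cells, `k >= 2`.
#' @return Epsilon in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(within_covariance) {
  s <- as.matrix(within_covariance)
  if (nrow(s) != ncol(s) ||
      !isSymmetric(unname(s), tol = 1e-8, check.attributes = FALSE)) {
    rlang::abort("within_covariance must be a symmetric square matrix",
      class = "metasense_domain_error")
  }
  k <- nrow(s)
  if (k < 2) {
    rlang::abort("need at least 2 within-subject levels",
      class = "metasense_domain_error")
  }
  if (k == 2) {
    return(1)
  }
  rm <- rowMeans(s)
  gm <- mean(s)
  sdc <- s - outer(rm, rep(1, k)) - outer(rep(1, k), rm) + gm
  denom <- (k - 1) * sum(sdc^2)
  if (denom < .Machine$double.eps) {
    return(1) # degenerate (zero double-centered variance): sphericity holds
  }
  eps <- sum(diag(sdc))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Fits the split-plot design used throughout the analysis: one
#' between-subjects factor (e.g. agent group) and one or two
#' within-subjects factors (e.g. condition, or correctness x condition),
#' with Type III sums of squares (sum-to-zero contrasts). Sphericity of
#' each within-subject term is assessed by Mauchly's test and the
#' Greenhouse-Geisser epsilon; under `gg = "auto"` (default) the corrected
#' degrees of freedom and p-value are used whenever the term has at least
#' three levels and Mauchly's test rejects at `alpha`; `"always"` and
#' `"never"` force the behaviour for exact-reproduction runs. Effect sizes
#' are generalized eta squared, `SS_effect / (SS_effect + sum of all error
#' SS in the design)`, which keeps subject variance in the denominator and
#' is comparable across between- and within-subject effects.
#'
#' The ANOVA numerics (sums of squares, sphericity tests, epsilon
#' estimates) are delegated to \pkg{car}'s multivariate repeated-measures
#' machinery; the correction policy, generalized eta squared and the
#' reporting contract are implemented here.
#'
#' @param data Long-format data frame: one row per subject and
#'   within-subject cell.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param between Name of the between-subjects factor column.
#' @param within Character vector (length 1 or 2) of within-subjects factor
#'   columns, or `NULL` for a pure between-subjects one-way ANOVA.
#' @param gg Greenhouse-Geisser policy: `"auto"`, `"always"` or `"never"`.
#' @param alpha Significance level of Mauchly's test under `"auto"`.
#' @return Tibble with one row per effect: `effect`, `df_num`, `df_den`
#'   (non-integer when corrected), `F`, `epsilon`, `p`, `ges`,
#'   `mauchly_p`, `gg_applied`.
#' @export
mixed_anova <- function(data, dv, subject, between, within = NULL,
                        gg = c("auto", "always", "never"), alpha = 0.05) {
  gg <- match.arg(gg)
  df <- tibble::as_tibble(data)
  for (col in c(dv, subject, between, within)) {
    if (!col %in% names(df)) {
      rlang::abort(paste0("column not found: ", col),
        class = "metasense_design_error")
    }
  }
  if (nrow(df) == 0) {
    rlang::abort("no observations", class = "metasense_design_error")
  }
  df[[subject]] <- as.character(df[[subject]])
  df[[between]] <- factor(df[[between]])
  if (anyNA(df[[dv]])) {
    rlang::abort("missing response values are not allowed (no imputation)",
      class = "metasense_design_error")
  }
  if (any(table(unique(df[, c(subject, between)])[[subject]]) > 1)) {
    rlang::abort("each subject must belong to exactly one between level",
      class = "metasense_design_error")
  }
  if (any(table(unique(df[, c(subject, between)])[[between]]) < 2)) {
    rlang::abort("need at least 2 subjects per between level",
      class = "metasense_design_error")
  }

  if (is.null(within) || length(within) == 0) {
    return(between_anova(df, dv, subject, between))
  }
  if (length(within) > 2) {
    rlang::abort("at most two within-subject factors are supported",
      class = "metasense_design_error")
  }
  for (w in within) df[[w]] <- factor(df[[w]])

  # balanced complete design: every subject observed once in every cell
  cell <- interaction(df[within], drop = FALSE, lex.order = TRUE)
  counts <- table(df[[subject]], cell)
  if (any(counts != 1)) {
    rlang::abort(
      "design error: every subject must be observed exactly once in every within-subject cell",
      class = "metasense_design_error")
  }

  idata <- rev(expand.grid(rev(lapply(df[within], levels)),
    stringsAsFactors = TRUE))
  names(idata) <- within
  cell_names <- apply(idata, 1, paste, collapse = ".")
  df$.cell <- factor(apply(df[within], 1, paste, collapse = "."),
    levels = cell_names)
  wide <- tidyr::pivot_wider(df[, c(subject, between, ".cell", dv)],
    names_from = ".cell", values_from = dplyr::all_of(dv))
  if (!all(cell_names %in% names(wide))) {
    rlang::abort("design error: empty within-subject cell(s)",
      class = "metasense_design_error")
  }
  y <- as.matrix(wide[, cell_names])
  grp <- wide[[between]]

  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  mlm <- stats::lm(y ~ grp)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # car warns when the Huynh-Feldt estimate exceeds 1; HF is not reported
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  uni <- s$univariate.tests
  effects <- setdiff(rownames(uni), "(Intercept)")
  # error strata: one per distinct within-term component ("" = subjects)
  stratum_of <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    paste(intersect(within, parts), collapse = ":")
  }
  strata <- vapply(rownames(uni), stratum_of, character(1))
  err_ss_by_stratum <- tapply(uni[, "Error SS"], strata, function(x) x[1])
  total_error_ss <- sum(err_ss_by_stratum)

  sph <- s$sphericity.tests
  adj <- s$pval.adjustments

  rows <- lapply(effects, function(eff) {
    f_val <- uni[eff, "F value"]
    df1 <- uni[eff, "num Df"]
    df2 <- uni[eff, "den Df"]
    ss <- uni[eff, "Sum Sq"]
    eps <- 1
    mau_p <- NA_real_
    has_adj <- !is.null(adj) && eff %in% rownames(adj)
    if (has_adj) {
      eps <- unname(adj[eff, "GG eps"])
      if (!is.finite(eps)) { # two-level within term: sphericity vacuous
        eps <- 1
        has_adj <- FALSE
      }
    }
    if (!is.null(sph) && eff %in% rownames(sph)) {
      mau_p <- unname(sph[eff, "p-value"])
    }
    applied <- switch(gg,
      never = FALSE,
      always = has_adj,
      auto = has_adj && !is.na(mau_p) && mau_p < alpha)
    if (applied) {
      df1a <- eps * df1
      df2a <- eps * df2
      p <- stats::pf(f_val, df1a, df2a, lower.tail = FALSE)
    } else {
      df1a <- df1
      df2a <- df2
      p <- uni[eff, "Pr(>F)"]
    }
    label <- gsub("grp", between, eff, fixed = TRUE)
    tibble::tibble(
      effect = label, df_num = df1a, df_den = df2a, F = unname(f_val),
      epsilon = if (has_adj) eps else 1,
      p = unname(p),
      ges = unname(ss / (ss + total_error_ss)),
      mauchly_p = mau_p, gg_applied = applied
    )
  })
  dplyr::bind_rows(rows)
}

between_anova <- function(df, dv, subject, between) {
  # single within level: reduces to a one-way between-subjects ANOVA
  fit <- stats::lm(stats::reformulate(between, response = dv), data = df)
  tab <- stats::anova(fit)
  ss_eff <- tab[between, "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  tibble::tibble(
    effect = between,
    df_num = tab[between, "Df"],
    df_den = tab["Residuals", "Df"],
    F = tab[between, "F value"],
    epsilon = NA_real_,
    p = tab[between, "Pr(>F)"],
    ges = ss_eff / (ss_eff + ss_err),
    mauchly_p = NA_real_,
    gg_applied = FALSE
  )
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Runs every comparison of an explicitly enumerated family of level pairs
#' and multiplies each raw p-value by the family size `m` (capped at 1).
#' When a `subject` column is supplied the comparisons are paired t-tests
#' matched by subject; otherwise independent two-sample t-tests with a
#' pooled variance estimate. Simple-effects families are formed by
#' filtering `data` before the call (e.g. the three condition comparisons
#' within one agent group form one family with `m = 3`).
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param factor_col Name of the column whose levels are compared.
#' @param subject Optional subject column for paired comparisons.
#' @param family List of length-2 character vectors naming the level pairs
#'   to test; `NULL` (default) enumerates all pairs.
#' @return Tibble with columns `level1`, `level2`, `mean_diff`
#'   (`level1 - level2`), `t`, `df`, `p_raw`, `p_adj`, `m`, `paired`.
#' @export
bonferroni_pairwise <- function(data, dv, factor_col, subject = NULL,
                                family = NULL) {
  df <- tibble::as_tibble(data)
  for (col in c(dv, factor_col, subject)) {
    if (!col %in% names(df)) {
      rlang::abort(paste0("column not found: ", col),
        class = "metasense_design_error")
    }
  }
  lv <- if (is.factor(df[[factor_col]])) {
    levels(droplevels(df[[factor_col]]))
  } else {
    unique(as.character(df[[factor_col]]))
  }
  if (is.null(family)) {
    if (length(lv) < 2) {
      rlang::abort("need at least two levels to compare",
        class = "metasense_domain_error")
    }
    family <- utils::combn(lv, 2, simplify = FALSE)
  }
  if (length(family) == 0) {
    rlang::abort("comparison family must not be empty",
      class = "metasense_domain_error")
  }
  m <- length(family)
  paired <- !is.null(subject)
  rows <- lapply(family, function(pair) {
    l1 <- pair[1]
    l2 <- pair[2]
    x1 <- df[df[[factor_col]] == l1, , drop = FALSE]
    x2 <- df[df[[factor_col]] == l2, , drop = FALSE]
    if (nrow(x1) == 0 || nrow(x2) == 0) {
      rlang::abort(paste0("no data for comparison ", l1, " vs ", l2),
        class = "metasense_domain_error")
    }
    if (paired) {
      merged <- merge(x1[, c(subject, dv)], x2[, c(subject, dv)],
        by = subject, suffixes = c(".1", ".2"))
      tt <- stats::t.test(merged[[paste0(dv, ".1")]],
        merged[[paste0(dv, ".2")]], paired = TRUE)
      diff_val <- mean(merged[[paste0(dv, ".1")]] -
        merged[[paste0(dv, ".2")]])
    } else {
      tt <- stats::t.test(x1[[dv]], x2[[dv]], var.equal = TRUE)
      diff_val <- mean(x1[[dv]]) - mean(x2[[dv]])
    }
    tibble::tibble(
      level1 = l1, level2 = l2, mean_diff = diff_val,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_adj = min(1, m * tt$p.value),
      m = m, paired = paired
    )
  })
  dplyr::bind_rows(rows)
}
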