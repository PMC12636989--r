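# Group comparison of scalar outcomes (layer thickness, vessel density)
# across model x genotype groups: random-intercept mixed model (eyes
# nested in mouse) fitted by REML, Satterthwaite degrees of freedom for
# each contrast, and Bonferroni correction over all pairwise comparisons.
# The model fit and the Satterthwaite moment matching are delegated to
# lme4/lmerTest, the standard implementations of both.

#' @noRd
prepare_table <- function(tab, outcome = NULL) {
  if (!is.null(outcome) && "outcome_name" %in% names(tab)) {
    tab <- tab[tab$outcome_name == outcome, , drop = FALSE]
  }
  need <- c("mouse_id", "group", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    rt_stop("ValidationError", "measurement table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (!all(is.finite(tab$value))) {
    rt_stop("ValidationError", "measurement values must be finite")
  }
  tab$group <- factor(tab$group)
  tab$mouse_id <- factor(tab$mouse_id)
  counts <- base::table(unique(tab[c("mouse_id", "group")])$group)
  if (nlevels(tab$group) < 2L) {
    rt_stop("ValidationError", "need >= 2 groups, got %d",
            nlevels(tab$group))
  }
  if (any(counts == 0L)) {
    rt_stop("ValidationError", "group '%s' has zero mice",
            names(counts)[counts == 0L][1])
  }
  if (nlevels(tab$mouse_id) < 2L) {
    rt_stop("ValidationError", "need >= 2 mice in total")
  }
  tab
}

#' Fit the random-intercept model for one outcome
#'
#' `value ~ 0 + group + (1 | mouse_id)`, fitted by REML: cell-mean fixed
#' effects per group and a per-mouse random intercept that accounts for
#' the left and right eye of the same mouse being repeated measurements.
#'
#' @param table data.frame with `mouse_id`, `group`, `value` (and
#'   optionally `outcome_name` to filter on)
#' @param outcome optional outcome name to select
#' @return an `ri_fit`: `model` (lmerModLmerTest), `group_means`,
#'   `var_mouse`, `var_resid`, `loglik` (REML), `groups`
#' @export
fit_random_intercept <- function(table, outcome = NULL) {
  tb <- prepare_table(table, outcome)
  fit <- suppressMessages(lmerTest::lmer(
    value ~ 0 + group + (1 | mouse_id), data = tb, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  gm <- lme4::fixef(fit)
  names(gm) <- levels(tb$group)
  structure(list(model = fit, group_means = gm,
                 var_mouse = vc$vcov[vc$grp == "mouse_id"][1],
                 var_resid = vc$vcov[vc$grp == "Residual"][1],
                 loglik = as.numeric(stats::logLik(fit)),
                 groups = levels(tb$group), data = tb),
            class = "ri_fit")
}

#' Satterthwaite degrees of freedom for a contrast
#'
#' Moment-matching df for the t statistic of a fixed-effect contrast,
#' from the gradient of the contrast variance in the variance components
#' and the observed REML information.
#'
#' @param fit an `ri_fit`
#' @param contrast numeric contrast vector over the group means (in
#'   `fit$groups` order)
#' @return degrees of freedom (positive real)
#' @export
satterthwaite_df <- function(fit, contrast) {
  ct <- contrast_test(fit, contrast)
  ct$df
}

#' t test of a fixed-effect contrast with Satterthwaite df
#'
#' @param fit an `ri_fit`
#' @param contrast numeric contrast vector over the group means
#' @return list `estimate`, `se`, `df`, `t`, `p`
#' @export
contrast_test <- function(fit, contrast) {
  if (length(contrast) != length(fit$groups)) {
    rt_stop("ValidationError",
            "contrast length %d does not match %d groups",
            length(contrast), length(fit$groups))
  }
  ct <- lmerTest::contest1D(fit$model, contrast, ddf = "Satterthwaite")
  list(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
       t = ct$`t value`, p = ct$`Pr(>|t|)`)
}

#' Bonferroni correction
#'
#' @param p_raw raw p value(s) in \[0, 1\]
#' @param m number of comparisons (>= 1)
#' @return `min(1, m * p_raw)`
#' @export
bonferroni <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1)) {
    rt_stop("ValidationError", "p values must lie in [0, 1]")
  }
  if (m < 1) rt_stop("ValidationError", "m must be >= 1")
  pmin(1, m * p_raw)
}

#' All pairwise group comparisons for one outcome
#'
#' One mixed-model fit per comparison family; all C(g, 2) pairwise
#' contrasts with Satterthwaite df; Bonferroni correction with
#' m = C(g, 2) and a significance flag at 0.05.
#'
#' @param table measurement table (see [fit_random_intercept()])
#' @param outcome optional outcome name
#' @param alpha family significance level
#' @return a `comparison_result`: `group_means`, `group_sds` (per-eye SD),
#'   `group_n_mice`, `pairwise` data.frame (`group1`, `group2`,
#'   `estimate`, `se`, `df`, `t`, `p_raw`, `p_bonferroni`, `significant`),
#'   `n_comparisons`, `fit`
#' @export
pairwise_compare <- function(table, outcome = NULL, alpha = 0.05) {
  fit <- fit_random_intercept(table, outcome)
  g <- fit$groups
  ng <- length(g)
  prs <- utils::combn(ng, 2L)
  m <- ncol(prs)
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    i <- prs[1L, k]; j <- prs[2L, k]
    L <- numeric(ng); L[i] <- 1; L[j] <- -1
    ct <- contrast_test(fit, L)
    rows[[k]] <- data.frame(group1 = g[i], group2 = g[j],
                            estimate = ct$estimate, se = ct$se, df = ct$df,
                            t = ct$t, p_raw = ct$p,
                            stringsAsFactors = FALSE)
  }
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- bonferroni(pw$p_raw, m)
  pw$significant <- pw$p_bonferroni < alpha
  tb <- fit$data
  sds <- tapply(tb$value, tb$group, stats::sd)
  nm <- tapply(tb$mouse_id, tb$group, function(x) length(unique(x)))
  structure(list(group_means = fit$group_means,
                 group_sds = as.numeric(sds)[match(g, names(sds))] |>
                   stats::setNames(g),
                 group_n_mice = as.integer(nm)[match(g, names(nm))] |>
                   stats::setNames(g),
                 pairwise = pw, n_comparisons = m, alpha = alpha,
                 fit = fit),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d groups, %d pairwise comparisons\n",
              length(x$group_means), x$n_comparisons))
  cat("group means +/- SD:\n")
  for (g in names(x$group_means)) {
    cat(sprintf("  %-14s %7.2f +/- %5.2f (n_mice=%d)\n", g,
                x$group_means[[g]], x$group_sds[[g]], x$group_n_mice[[g]]))
  }
  print(x$pairwise, digits = 4)
  invisible(x)
}
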