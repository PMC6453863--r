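#' Univariate group comparisons
#'
#' Thin, contract-stable front end to the standard two-sided tests used for
#' baseline comparisons: Mann-Whitney U (normal approximation, no continuity
#' correction), Kruskal-Wallis, Pearson chi-square without continuity
#' correction, and a Kolmogorov-Smirnov normality check against a normal
#' with the sample's moments.
#'
#' @param x First sample; for `chi_square` a contingency matrix/table; for
#'   `kruskal_wallis` optionally a list of samples.
#' @param y Second sample (ignored for `chi_square`).
#' @param kind One of `"mann_whitney"`, `"kruskal_wallis"`, `"chi_square"`,
#'   `"ks_normality"`.
#' @return List with `statistic`, `p_value`, `method` and, for chi-square,
#'   `low_expected` flagging expected cells < 1.
#' @export
compare_univariate <- function(x, y = NULL,
                               kind = c("mann_whitney", "kruskal_wallis",
                                        "chi_square", "ks_normality")) {
  kind <- match.arg(kind)
  if (kind == "chi_square") {
    x <- as.matrix(x)
    expected <- outer(rowSums(x), colSums(x)) / sum(x)
    low <- any(expected < 1)
    if (low) warning("chi-square: expected cell count below 1", call. = FALSE)
    ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "Pearson chi-square (no continuity correction)",
                low_expected = low))
  }
  if (kind == "ks_normality") {
    if (!length(x)) stop("empty sample", call. = FALSE)
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "Kolmogorov-Smirnov normality"))
  }
  if (kind == "kruskal_wallis") {
    groups <- if (is.list(x)) x else list(x, y)
    if (any(!lengths(groups))) stop("empty group", call. = FALSE)
    ht <- stats::kruskal.test(groups)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "Kruskal-Wallis"))
  }
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Mann-Whitney U (normal approximation)")
}

check_nesting <- function(records) {
  bad <- function(child, parent) {
    any(tapply(records[[parent]], records[[child]],
               function(v) length(unique(v))) > 1)
  }
  if (bad("scaffold_id", "animal_id") ||
      bad("cross_section_id", "scaffold_id")) {
    stop("ids do not form a strict nesting: each cross-section must belong ",
         "to one scaffold and each scaffold to one animal", call. = FALSE)
  }
  invisible(TRUE)
}

#' Three-level mixed-effects model for sector ESS
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `ess ~ scaffold_type * cross_sectional_area` with nested random
#' intercepts for animal, scaffold-within-animal and
#' cross-section-within-scaffold; sector observations are the residual
#' level. Fixed-effect p-values are Wald tests with Satterthwaite degrees
#' of freedom where available, otherwise a normal approximation (the method
#' used is recorded in the result).
#'
#' @param records `ess_records` data.frame (see
#'   [simulate_hierarchical_ess()]): `animal_id`, `scaffold_id`,
#'   `cross_section_id`, `scaffold_type`, `cross_sectional_area`, `ess`.
#' @param fixed RHS fixed-effects formula (response must be `ess`).
#' @param use_satterthwaite Use lmerTest's Satterthwaite df.
#' @return Object of class `mixed_model_result`: `fixed_effects`
#'   (data.frame: term, estimate, se, df, p_value), `variance_components`
#'   (data.frame: level, sd), `log_likelihood`, `n_obs`, `n_parameters`,
#'   `converged`, `singular`, `p_method`, `data_checksum`, and the
#'   underlying `fit`.
#' @export
fit_multilevel <- function(records,
                           fixed = ess ~ scaffold_type * cross_sectional_area,
                           use_satterthwaite = TRUE) {
  if (length(unique(records$scaffold_type)) < 2) {
    stop("need at least 2 scaffold types", call. = FALSE)
  }
  check_nesting(records)
  f <- stats::update(fixed,
    . ~ . + (1 | animal_id) + (1 | animal_id:scaffold_id) +
      (1 | animal_id:scaffold_id:cross_section_id))
  fit <- if (use_satterthwaite) {
    lmerTest::lmer(f, data = records, REML = FALSE)
  } else {
    lme4::lmer(f, data = records, REML = FALSE)
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  singular <- lme4::isSingular(fit)

  co <- summary(fit)$coefficients
  if (ncol(co) >= 5) {
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], df = co[, "df"],
                     p_value = co[, "Pr(>|t|)"], row.names = NULL)
    p_method <- "Wald t, Satterthwaite df"
  } else {
    z <- co[, "Estimate"] / co[, "Std. Error"]
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"], df = Inf,
                     p_value = 2 * stats::pnorm(-abs(z)), row.names = NULL)
    p_method <- "Wald z, normal approximation"
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- data.frame(level = vc$grp, sd = vc$sdcor)

  structure(list(fixed_effects = fe, variance_components = vcomp,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_obs = stats::nobs(fit),
                 n_parameters = attr(stats::logLik(fit), "df"),
                 converged = converged, singular = singular,
                 p_method = p_method,
                 data_checksum = sum(records$ess) + nrow(records),
                 fit = fit),
            class = "mixed_model_result")
}

#' @exportS3Method base::print
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> ML fit, logLik %.2f, %d obs, %s%s\n",
              x$log_likelihood, x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              if (x$singular) " (singular)" else ""))
  cat("fixed effects (", x$p_method, "):\n", sep = "")
  print(x$fixed_effects, digits = 4)
  cat("random-effect standard deviations:\n")
  print(x$variance_components, digits = 4)
  invisible(x)
}

#' Model selection by maximum likelihood
#'
#' Ranks candidate mixed models fitted by ML on identical records by
#' log-likelihood; nested pairs additionally get a likelihood-ratio test,
#' non-nested pairs are compared by AIC only. Ties in log-likelihood go to
#' the model with fewer parameters.
#'
#' @param ... `mixed_model_result` objects (or one list of them).
#' @return List: `best` (the selected model), `table` (log-likelihood / AIC
#'   ranking), `lrt` (data.frame of likelihood-ratio tests for nested
#'   consecutive pairs, if any).
#' @export
select_model <- function(...) {
  models <- list(...)
  if (length(models) == 1 && !inherits(models[[1]], "mixed_model_result")) {
    models <- models[[1]]
  }
  stopifnot(all(vapply(models, inherits, logical(1), "mixed_model_result")))
  if (length(unique(vapply(models, function(m) m$n_obs, numeric(1)))) > 1 ||
      length(unique(vapply(models, function(m) m$data_checksum, numeric(1)))) > 1) {
    stop("candidates were not fitted on identical records", call. = FALSE)
  }
  ll <- vapply(models, function(m) m$log_likelihood, numeric(1))
  np <- vapply(models, function(m) m$n_parameters, numeric(1))
  aic <- -2 * ll + 2 * np
  ord <- order(-round(ll, 8), np)
  tab <- data.frame(model = seq_along(models), log_likelihood = ll,
                    n_parameters = np, aic = aic)[ord, ]
  tab$rank <- seq_along(models)

  terms_of <- function(m) rownames(summary(m$fit)$coefficients)
  lrt <- NULL
  for (k in seq_len(length(ord) - 1)) {
    a <- models[[ord[k + 1]]]; b <- models[[ord[k]]]   # a smaller or equal
    nested <- all(terms_of(a) %in% terms_of(b)) && a$n_parameters < b$n_parameters
    if (nested) {
      stat <- 2 * (b$log_likelihood - a$log_likelihood)
      dfd <- b$n_parameters - a$n_parameters
      lrt <- rbind(lrt, data.frame(
        reduced = ord[k + 1], full = ord[k], chisq = stat, df = dfd,
        p_value = stats::pchisq(max(stat, 0), dfd, lower.tail = FALSE)))
    }
  }
  list(best = models[[ord[1]]], table = tab, lrt = lrt)
}
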