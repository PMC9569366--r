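## Inference layer: covariate-adjusted standardized OLS for the four
## mediation-diagram paths, Sobel mediation, ordinal moderation with simple
## slopes, effect sizes (Cohen's d, f^2), dual FDR control, propensity-style
## site adjustment, and split-sample validation by CV(RMSE).

## z-score continuous numeric columns (more than two distinct values);
## binaries, dummies and factors pass through untouched
.standardizeColumns <- function(df, cols) {
  for (cl in cols) {
    x <- df[[cl]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      s <- sd(x)
      if (s > 0) df[[cl]] <- (x - mean(x)) / s
    }
  }
  df
}

.backtick <- function(x) paste0("`", x, "`")

#' Covariate-adjusted standardized linear regression
#'
#' Continuous outcome and predictors are z-scored before fitting (binary and
#' dummy terms are left unscaled), so coefficients are standardized betas.
#' Rows with missing values in any used column are dropped listwise. An
#' ordinal primary predictor enters either as a linear-in-levels term
#' (\code{"linear"}) or as dummies against reference level 1
#' (\code{"dummy_ref1"}).
#'
#' @param table data.frame of subjects.
#' @param outcome,primary_predictor,covariates column names; the primary
#'   predictor must not appear among the covariates.
#' @param ordinal_coding coding of an ordinal primary predictor.
#' @param fdr_mode FDR variant for the per-term adjusted p-values.
#' @return object of class \code{"FitResult"}: list with \code{terms}
#'   (data.frame: term, beta, se, p, p_fdr), \code{adj_r2}, \code{aic},
#'   \code{n_used}, \code{condition_number}.
#' @export
fitOLSStandardized <- function(table, outcome, primary_predictor,
                               covariates = character(),
                               ordinal_coding = c("linear", "dummy_ref1"),
                               fdr_mode = "independent_BH") {
  ordinal_coding <- match.arg(ordinal_coding)
  used <- c(outcome, primary_predictor, covariates)
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols) > 0L)
    stop("column not found in table: ", missing_cols[1L])
  if (primary_predictor %in% covariates)
    stop("primary predictor must not appear among the covariates")
  df <- table[, used, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  for (cl in used)
    if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  if (ordinal_coding == "dummy_ref1")
    df[[primary_predictor]] <- factor(df[[primary_predictor]])
  df <- .standardizeColumns(df, used)
  rhs <- paste(.backtick(c(primary_predictor, covariates)), collapse = " + ")
  fml <- as.formula(paste(.backtick(outcome), "~", rhs))
  mm <- model.matrix(fml, df)
  if (nrow(df) <= ncol(mm) + 1L)
    stop("too few complete rows (", nrow(df), ") for ", ncol(mm), " terms")
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient model; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  kap <- kappa(mm, exact = FALSE)
  if (kap > 1e6)
    warning("design matrix is ill-conditioned (condition number ",
            format(kap, digits = 3), ")")
  sm <- summary(fit)$coefficients
  terms_df <- data.frame(term = rownames(sm), beta = sm[, 1L], se = sm[, 2L],
                         p = sm[, 4L], stringsAsFactors = FALSE,
                         row.names = NULL)
  nonint <- terms_df$term != "(Intercept)"
  terms_df$p_fdr <- terms_df$p
  terms_df$p_fdr[nonint] <- fdrAdjust(terms_df$p[nonint], fdr_mode)
  structure(list(terms = terms_df, adj_r2 = summary(fit)$adj.r.squared,
                 r2 = summary(fit)$r.squared, aic = AIC(fit),
                 n_used = nrow(df), condition_number = kap,
                 outcome = outcome, primary_predictor = primary_predictor),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: %s ~ %s (+%d covariate terms), n = %d\n",
              x$outcome, x$primary_predictor, nrow(x$terms) - 2L, x$n_used))
  print(x$terms, digits = 4)
  cat(sprintf("adj R^2 = %.4f, AIC = %.1f\n", x$adj_r2, x$aic))
  invisible(x)
}

## beta/se of a given term in a FitResult
.termStat <- function(fit, term) {
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("term not found in fit: ", term)
  fit$terms[i, c("beta", "se", "p", "p_fdr")]
}

#' Sobel test of an indirect effect
#'
#' z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2), with a two-sided normal p-value.
#'
#' @param a,se_a estimate and SE of the predictor-to-mediator path.
#' @param b,se_b estimate and SE of the mediator-to-outcome path (adjusted
#'   for the predictor).
#' @return list with \code{z} and \code{p}.
#' @export
sobelTest <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  denom <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- if (denom == 0) 0 else (a * b) / denom
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Mediation analysis over the four path models
#'
#' Fits, with one common covariate set so the models are comparable:
#' Path A (belief -> score), Path B (belief -> property), Path C
#' (property -> score) and Path D, the full model
#' (score ~ belief + property + covariates). The indirect effect is
#' a x b (a: Path B belief coefficient; b: Path D property coefficient)
#' with Sobel inference; the mediation class is decided at
#' FDR-adjusted alpha (BH over the pair {indirect, direct}): "partial"
#' requires significant indirect and direct (c') effects, "full" a
#' significant indirect effect with nonsignificant c'.
#'
#' @param table cohort table joined with the network property.
#' @param belief,property,score column names.
#' @param covariates common covariate column set.
#' @param ordinal_coding belief coding in the path models (linear default).
#' @param alpha significance level for classification.
#' @return object of class \code{"MediationResult"}.
#' @export
runMediation <- function(table, belief, property, score,
                         covariates = character(),
                         ordinal_coding = "linear", alpha = 0.05) {
  path_a <- fitOLSStandardized(table, score, belief, covariates, ordinal_coding)
  path_b <- fitOLSStandardized(table, property, belief, covariates, ordinal_coding)
  path_c <- fitOLSStandardized(table, score, property, covariates)
  path_d <- fitOLSStandardized(table, score, belief,
                               c(property, covariates), ordinal_coding)
  a_st <- .termStat(path_b, belief)
  b_st <- .termStat(path_d, property)
  c_st <- .termStat(path_d, belief)
  sob <- sobelTest(a_st$beta, a_st$se, b_st$beta, b_st$se)
  p_pair <- fdrAdjust(c(indirect = sob$p, direct = c_st$p), "independent_BH")
  cls <- if (p_pair[["indirect"]] >= alpha) "none"
         else if (p_pair[["direct"]] < alpha) "partial" else "full"
  structure(list(path_a = path_a, path_b = path_b, path_c = path_c,
                 path_d = path_d,
                 a = a_st$beta, se_a = a_st$se,
                 b = b_st$beta, se_b = b_st$se,
                 c_prime = c_st$beta, se_c_prime = c_st$se,
                 indirect_ab = a_st$beta * b_st$beta,
                 sobel_z = sob$z, sobel_p = sob$p,
                 p_indirect_fdr = p_pair[["indirect"]],
                 p_direct_fdr = p_pair[["direct"]],
                 mediation_class = cls, alpha = alpha),
            class = "MediationResult")
}

#' @export
print.MediationResult <- function(x, ...) {
  cat(sprintf("MediationResult: indirect ab = %.4f (Sobel z = %.2f, p = %.3g)\n",
              x$indirect_ab, x$sobel_z, x$sobel_p))
  cat(sprintf("  a = %.4f (SE %.4f), b = %.4f (SE %.4f), c' = %.4f\n",
              x$a, x$se_a, x$b, x$se_b, x$c_prime))
  cat(sprintf("  classification at FDR-adjusted alpha = %.2f: %s\n",
              x$alpha, x$mediation_class))
  invisible(x)
}

#' Moderation with ordinal belief levels and simple slopes
#'
#' The full model regresses the score on the network property, belief-level
#' dummies (reference: level 1, "not at all"), property-by-level
#' interactions, and covariates. The simple slope of property on score at
#' level l is beta_property + beta_interaction(l), with its SE from the
#' coefficient covariance (delta method). The moderation effect size is
#' f^2 = (R2_full - R2_reduced) / (1 - R2_full) against the no-interaction
#' model; the overall interaction p-value is the F test between the two.
#'
#' @param table cohort table joined with the network property.
#' @param property,score,belief column names; belief is ordinal 1-5.
#' @param covariates covariate column names.
#' @param min_level_n levels with fewer observations than this are flagged.
#' @return object of class \code{"ModerationResult"}: interaction table,
#'   simple slopes per observed level, \code{f_squared},
#'   \code{interaction_p}.
#' @export
runModeration <- function(table, property, score, belief,
                          covariates = character(), min_level_n = 10L) {
  used <- c(score, property, belief, covariates)
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols) > 0L)
    stop("column not found in table: ", missing_cols[1L])
  df <- table[, used, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df[[belief]])) < 2L)
    stop("belief moderator needs >= 2 observed levels")
  for (cl in used)
    if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  df <- .standardizeColumns(df, setdiff(used, belief))
  df[[belief]] <- factor(df[[belief]])
  cov_rhs <- if (length(covariates) > 0L)
    paste("+", paste(.backtick(covariates), collapse = " + ")) else ""
  f_full <- as.formula(paste(.backtick(score), "~", .backtick(property), "*",
                             .backtick(belief), cov_rhs))
  f_red <- as.formula(paste(.backtick(score), "~", .backtick(property), "+",
                            .backtick(belief), cov_rhs))
  fit_full <- lm(f_full, data = df)
  fit_red <- lm(f_red, data = df)
  if (anyNA(coef(fit_full)))
    stop("rank-deficient moderation model; aliased: ",
         paste(names(coef(fit_full))[is.na(coef(fit_full))], collapse = ", "))
  r2f <- summary(fit_full)$r.squared
  r2r <- summary(fit_red)$r.squared
  f2 <- max(0, (r2f - r2r) / (1 - r2f))
  an <- anova(fit_red, fit_full)
  interaction_p <- an$`Pr(>F)`[2L]
  V <- vcov(fit_full)
  cf <- coef(fit_full)
  prop_term <- .backtick(property)
  prop_name <- if (prop_term %in% names(cf)) prop_term else property
  levs <- sort(unique(as.integer(as.character(df[[belief]]))))
  rdf <- fit_full$df.residual
  slopes <- do.call(rbind, lapply(levs, function(l) {
    int_name <- grep(paste0(":", .backtick(belief), l, "$|:", belief, l, "$"),
                     names(cf), value = TRUE)
    if (l == min(levs) || length(int_name) == 0L) {
      b <- cf[[prop_name]]
      se <- sqrt(V[prop_name, prop_name])
      bi <- NA_real_
      pi_ <- NA_real_
    } else {
      b <- cf[[prop_name]] + cf[[int_name]]
      se <- sqrt(V[prop_name, prop_name] + V[int_name, int_name] +
                 2 * V[prop_name, int_name])
      bi <- cf[[int_name]]
      pi_ <- 2 * pt(-abs(cf[[int_name]] / sqrt(V[int_name, int_name])), rdf)
    }
    nl <- sum(as.integer(as.character(df[[belief]])) == l)
    data.frame(level = l, slope = b, se = se,
               p = 2 * pt(-abs(b / se), rdf),
               interaction_beta = bi, interaction_term_p = pi_,
               n = nl, low_n_flag = nl < min_level_n,
               stringsAsFactors = FALSE)
  }))
  rownames(slopes) <- NULL
  structure(list(simple_slopes = slopes, f_squared = f2,
                 interaction_p = interaction_p, r2_full = r2f,
                 r2_reduced = r2r, n_used = nrow(df)),
            class = "ModerationResult")
}

#' @export
print.ModerationResult <- function(x, ...) {
  cat(sprintf("ModerationResult: f^2 = %.4f, interaction p = %.3g, n = %d\n",
              x$f_squared, x$interaction_p, x$n_used))
  print(x$simple_slopes, digits = 4)
  invisible(x)
}

#' Cohen's d with unequal-sample-size adjustment
#'
#' d = (mean_cmp - mean_ref) / s_pooled with the pooled SD weighted by
#' degrees of freedom, and a 95\% CI from the standard large-sample
#' approximation of the SE of d.
#'
#' @param group_ref,group_cmp numeric vectors (reference first), each of
#'   length >= 2.
#' @return list with \code{d} and \code{ci} (length-2 vector).
#' @export
cohensD <- function(group_ref, group_cmp) {
  n1 <- length(group_ref); n2 <- length(group_cmp)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * var(group_ref) + (n2 - 1) * var(group_cmp)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  d <- (mean(group_cmp) - mean(group_ref)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(d = d, ci = c(d - 1.96 * se, d + 1.96 * se))
}

#' False discovery rate adjustment
#'
#' Step-up Benjamini-Hochberg for independent (or positively dependent)
#' p-values, or Benjamini-Yekutieli (harmonic-sum factor) under arbitrary
#' dependence. Order-preserving and monotone.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param mode \code{"independent_BH"} or \code{"dependent_BY"}.
#' @return adjusted p-values, same order and names as the input.
#' @export
fdrAdjust <- function(pvalues, mode = c("independent_BH", "dependent_BY")) {
  mode <- match.arg(mode)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("all p-values must lie in [0, 1]")
  p.adjust(pvalues, method = if (mode == "independent_BH") "BH" else "BY")
}

#' Propensity-style site adjustment
#'
#' Predicts multinomial site-membership probabilities from demographics and
#' appends each subject's predicted probability for their own site as a
#' covariate column (\code{site_propensity}); with
#' \code{variant = "ipw"} an inverse-probability weight column
#' (\code{site_ipw}) is appended instead.
#'
#' @param table cohort table.
#' @param site_col name of the categorical site column (>= 2 sites).
#' @param covariates demographic predictor column names.
#' @param variant \code{"covariate"} (default) or \code{"ipw"}.
#' @param min_site_n sites smaller than this trigger a warning.
#' @return \code{table} with the adjustment column appended.
#' @export
siteAdjustment <- function(table, site_col = "site", covariates,
                           variant = c("covariate", "ipw"),
                           min_site_n = 20L) {
  variant <- match.arg(variant)
  site <- factor(table[[site_col]])
  if (nlevels(site) < 2L) stop("site adjustment needs >= 2 sites")
  tab <- base::table(site)
  if (any(tab < min_site_n))
    warning("site(s) with fewer than ", min_site_n, " subjects: ",
            paste(names(tab)[tab < min_site_n], collapse = ", "))
  df <- .standardizeColumns(table[, covariates, drop = FALSE], covariates)
  df$.site <- site
  fit <- nnet::multinom(
    as.formula(paste(".site ~", paste(.backtick(covariates), collapse = " + "))),
    data = df, trace = FALSE)
  pr <- predict(fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-site binomial case
  colnames(pr) <- levels(site)
  own <- pr[cbind(seq_len(nrow(table)), as.integer(site))]
  own <- pmin(pmax(own, 1e-8), 1 - 1e-8)
  if (variant == "covariate") table$site_propensity <- own
  else table$site_ipw <- 1 / own
  table
}

#' Split-sample model validation by CV(RMSE)
#'
#' Repeatedly splits the cohort into a training fraction (default 75\%) and
#' a held-out validation set, fits the linear model on the training subjects,
#' predicts the held-out outcome, and reports per-repeat AIC and CV(RMSE) =
#' RMSE(validation) / |mean(observed validation outcome)| (range-normalized
#' variant available). Deterministic given the seed.
#'
#' @param table data.frame.
#' @param outcome,predictors column names of the model.
#' @param train_frac training fraction in (0, 1).
#' @param n_repeats number of random splits.
#' @param seed RNG seed.
#' @param normalizer \code{"mean"} (default) or \code{"range"} of the
#'   observed validation outcome.
#' @return object of class \code{"ValidationResult"}: per-repeat table,
#'   medians, split sizes, and the count of repeats where the normalizer
#'   was degenerate (those CV(RMSE) are NA).
#' @export
splitSampleValidate <- function(table, outcome, predictors,
                                train_frac = 0.75, n_repeats = 100L,
                                seed = 1L, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  used <- c(outcome, predictors)
  df <- table[complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  n <- nrow(df)
  n_train <- floor(train_frac * n)
  n_test <- n - n_train
  if (n_test < length(predictors) * 2L + 2L)
    stop("validation set too small for the number of model terms")
  fml <- as.formula(paste(.backtick(outcome), "~",
                          paste(.backtick(predictors), collapse = " + ")))
  res <- withLocalSeed(seed, {
    do.call(rbind, lapply(seq_len(n_repeats), function(r) {
      idx <- sample.int(n, n_train)
      fit <- lm(fml, data = df[idx, , drop = FALSE])
      test <- df[-idx, , drop = FALSE]
      pred <- predict(fit, newdata = test)
      obs <- test[[outcome]]
      rmse <- sqrt(mean((obs - pred)^2))
      den <- if (normalizer == "mean") abs(mean(obs)) else diff(range(obs))
      data.frame(repeat_id = r, aic = AIC(fit),
                 cv_rmse = if (den < 1e-10) NA_real_ else rmse / den)
    }))
  })
  structure(list(per_repeat = res,
                 median_aic = median(res$aic),
                 median_cv_rmse = median(res$cv_rmse, na.rm = TRUE),
                 n_train = n_train, n_test = n_test, n_repeats = n_repeats,
                 n_undefined = sum(is.na(res$cv_rmse))),
            class = "ValidationResult")
}

#' @export
print.ValidationResult <- function(x, ...) {
  cat(sprintf(
    "ValidationResult: %d repeats of %d/%d split; median CV(RMSE) = %.4f, median AIC = %.1f\n",
    x$n_repeats, x$n_train, x$n_test, x$median_cv_rmse, x$median_aic))
  if (x$n_undefined > 0)
    cat(sprintf("  %d repeat(s) had a degenerate normalizer (CV(RMSE) = NA)\n",
                x$n_undefined))
  invisible(x)
}
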