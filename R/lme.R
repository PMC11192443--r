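# Wrap a fitted lmerMod (or lm fallback) into the package's fit record.
# p values are two-tailed Wald tests on the normal approximation; logLik
# and AIC are as fitted (refit under ML for likelihood comparisons).
as_lme_fit <- function(model, formula_id, reference_level = NA_character_,
                       dropped = character(0)) {
  if (inherits(model, "merMod")) {
    beta <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    converged <- length(model@optinfo$conv$lme4) == 0
    singular <- lme4::isSingular(model)
    method <- if (lme4::isREML(model)) "REML" else "ML"
  } else {
    sm <- summary(model)$coefficients
    beta <- sm[, 1]
    se <- sm[, 2]
    converged <- TRUE
    singular <- FALSE
    method <- "ML"
  }
  wald <- beta / se
  terms <- data.frame(name = names(beta), beta = unname(beta),
                      se = unname(se),
                      p = 2 * stats::pnorm(-abs(unname(wald))),
                      stringsAsFactors = FALSE)
  ll <- as.numeric(stats::logLik(model))
  k <- attr(stats::logLik(model), "df")
  structure(list(formula_id = formula_id, terms = terms,
                 reference_level = reference_level,
                 loglik = ll, aic = 2 * k - 2 * ll, n_params = k,
                 n_obs = stats::nobs(model),
                 fit_method = method, converged = converged,
                 singular = singular, dropped_random = dropped,
                 model = model),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("LME fit '%s' (%s%s%s), logLik %.2f, AIC %.2f\n",
              x$formula_id, x$fit_method,
              if (x$singular) ", singular" else "",
              if (!x$converged) ", NOT CONVERGED" else "",
              x$loglik, x$aic))
  if (!is.na(x$reference_level)) cat("reference level:", x$reference_level, "\n")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

# Drop random-intercept terms whose grouping factor has < 2 levels in the
# data (they are inestimable); warn so the reduction is never silent.
build_formula <- function(fixed, random_factors, data) {
  usable <- random_factors[vapply(random_factors, function(f) {
    length(unique(data[[f]])) >= 2
  }, logical(1))]
  dropped <- setdiff(random_factors, usable)
  if (length(dropped)) {
    warning("random intercept(s) dropped (single level): ",
            paste(dropped, collapse = ", "))
  }
  rhs <- paste(c(fixed, sprintf("(1 | %s)", usable)), collapse = " + ")
  list(formula = stats::as.formula(paste("z ~", rhs)),
       usable = usable, dropped = dropped)
}

fit_lme <- function(data, fixed, random_factors, formula_id,
                    reference_level = NA_character_, reml = TRUE) {
  fb <- build_formula(fixed, random_factors, data)
  if (length(fb$usable) == 0) {
    model <- stats::lm(stats::as.formula(paste("z ~", fixed)), data = data)
  } else {
    model <- lme4::lmer(fb$formula, data = data, REML = reml,
                        control = lme4::lmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
  }
  as_lme_fit(model, formula_id, reference_level, fb$dropped)
}

ct_factor <- function(x, reference) {
  levels <- unique(x)
  if (!reference %in% levels) {
    stop("reference level '", reference, "' not present in the data")
  }
  stats::relevel(factor(x, levels = sort(levels)), ref = reference)
}

#' Condition-type mixed model for ISCs
#'
#' Fisher z modelled with condition type as a dummy-coded fixed effect
#' (reference `"+M/-L"` by default) and crossed random intercepts for fROI,
#' participant and condition (stimulus). The intercept estimates the
#' reference type's mean ISC against zero; the other coefficients are
#' contrasts against the reference.
#'
#' @param isc an `isc_table`.
#' @param reference reference condition type.
#' @param reml fit by REML (default) or ML (required for likelihood-ratio
#'   comparisons).
#' @return an `lme_fit`.
#' @export
fit_condition_model <- function(isc, reference = "+M/-L", reml = TRUE) {
  stopifnot(is.data.frame(isc))
  if (length(unique(isc$condition_type)) < 2) {
    stop("need >= 2 condition types; with one type fit an intercept-only model")
  }
  d <- as.data.frame(isc)
  d$condition_type <- ct_factor(d$condition_type, reference)
  fit_lme(d, "condition_type", c("froi", "participant", "condition"),
          "condition", reference_level = reference, reml = reml)
}

# Recode each meaningful-nonverbal stimulus as its own condition type,
# keeping the other two types pooled: 4 + 2 = 6 levels for the standard
# ten-condition design.
recode_six_types <- function(isc, expand_type = "+M/-L") {
  d <- as.data.frame(isc)
  d$condition_type6 <- ifelse(d$condition_type == expand_type,
                              d$condition, d$condition_type)
  d
}

#' Per-stimulus mixed models for the meaningful nonverbal conditions
#'
#' Each meaningful-nonverbal (`"+M/-L"`) stimulus becomes its own condition
#' type (six types in total for the full design); Fisher z is modelled with
#' this six-level factor as fixed effect and fROI and participant as random
#' intercepts. With `reference = "zero"` the model has no global intercept
#' and each level's coefficient tests its mean ISC against the zero
#' baseline; otherwise the named type serves as the dummy-coding reference.
#'
#' @param isc an `isc_table`.
#' @param reference `"zero"`, `"+M/+L"` or `"-M/-L"`.
#' @param reml REML (default) or ML.
#' @return an `lme_fit`.
#' @export
fit_per_condition_model <- function(isc, reference = c("zero", "+M/+L", "-M/-L"),
                                    reml = TRUE) {
  reference <- match.arg(reference)
  d <- recode_six_types(isc)
  if (reference == "zero") {
    d$condition_type6 <- factor(d$condition_type6)
    fb_fixed <- "0 + condition_type6"
  } else {
    d$condition_type6 <- ct_factor(d$condition_type6, reference)
    fb_fixed <- "condition_type6"
  }
  fit_lme(d, fb_fixed, c("froi", "participant"),
          paste0("per_condition_", reference),
          reference_level = reference, reml = reml)
}

#' Per-stimulus tests against all three baselines, FDR-corrected
#'
#' Runs [fit_per_condition_model()] once per reference (zero, `"+M/+L"`,
#' `"-M/-L"`) and assembles, for every meaningful-nonverbal stimulus, its
#' coefficient in each model with p values FDR-adjusted across the three
#' reference comparisons (within stimulus).
#'
#' @param isc an `isc_table`.
#' @return data.frame with columns `condition`, `reference`, `beta`, `se`,
#'   `p`, `p_fdr`.
#' @export
per_condition_tests <- function(isc) {
  stimuli <- unique(isc$condition[isc$condition_type == "+M/-L"])
  refs <- c("zero", "+M/+L", "-M/-L")
  rows <- list()
  for (ref in refs) {
    fit <- fit_per_condition_model(isc, ref)
    for (stim in stimuli) {
      term <- paste0("condition_type6", stim)
      tr <- fit$terms[fit$terms$name == term, ]
      if (nrow(tr) != 1) stop("coefficient for ", stim, " not found (", ref, ")")
      rows[[length(rows) + 1L]] <- data.frame(
        condition = stim, reference = ref, beta = tr$beta, se = tr$se,
        p = tr$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (stim in stimuli) {
    sel <- out$condition == stim
    out$p_fdr[sel] <- fdr_bh(out$p[sel])
  }
  rownames(out) <- NULL
  out
}

#' Per-fROI condition-type models, FDR-corrected across fROIs
#'
#' Fits the condition-type model separately within each fROI (random
#' intercepts for participant and condition) and FDR-adjusts each fixed
#' term's p values across the fROI family.
#'
#' @param isc an `isc_table`.
#' @param reference reference condition type.
#' @return named list of `lme_fit`s with attribute `"fdr_table"`: a
#'   data.frame (froi, name, beta, se, p, p_fdr).
#' @export
fit_per_froi_model <- function(isc, reference = "+M/-L") {
  frois <- unique(isc$froi)
  fits <- lapply(frois, function(fr) {
    sub <- isc[isc$froi == fr, , drop = FALSE]
    if (length(unique(sub$condition_type)) < 2) {
      stop("fROI '", fr, "' has fewer than 2 condition types")
    }
    d <- as.data.frame(sub)
    d$condition_type <- ct_factor(d$condition_type, reference)
    fit_lme(d, "condition_type", c("participant", "condition"),
            paste0("per_froi_", fr), reference_level = reference)
  })
  names(fits) <- frois
  tab <- do.call(rbind, lapply(frois, function(fr) {
    cbind(froi = fr, fits[[fr]]$terms, stringsAsFactors = FALSE)
  }))
  tab$p_fdr <- NA_real_
  for (nm in unique(tab$name)) {
    sel <- tab$name == nm
    tab$p_fdr[sel] <- fdr_bh(tab$p[sel])
  }
  rownames(tab) <- NULL
  attr(fits, "fdr_table") <- tab
  fits
}

#' fROI-by-condition-type interaction model
#'
#' `z ~ 0 + froi + froi:condition_type + (1 | condition) + (1 | participant)`:
#' no global intercept, so each fROI gets its own intercept (its reference-
#' type mean) plus per-fROI condition-type contrasts.
#'
#' @param isc an `isc_table`.
#' @param reference reference condition type for the contrasts.
#' @return an `lme_fit`.
#' @export
fit_interaction_model <- function(isc, reference = "+M/-L") {
  d <- as.data.frame(isc)
  d$condition_type <- ct_factor(d$condition_type, reference)
  d$froi <- factor(d$froi)
  fit_lme(d, "0 + froi + froi:condition_type",
          c("condition", "participant"),
          "interaction", reference_level = reference)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1, over a family of
#' `n` comparisons (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric p values in `[0, 1]`.
#' @param n family size (default `length(pvals)`).
#' @return adjusted p values in input order.
#' @export
fdr_bh <- function(pvals, n = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH", n = n)
}

#' Compare two mixed-model fits
#'
#' Nested fits (both ML): likelihood-ratio test with
#' `chi2 = 2 (logLik_B - logLik_A)` on `df = k_B - k_A`. Non-nested fits:
#' `delta_aic = AIC_B - AIC_A` (negative favours B).
#'
#' @param fitA,fitB `lme_fit`s on identical rows; for `nested = TRUE`, A
#'   must be the reduced model.
#' @param nested logical; use the LRT (TRUE) or AIC (FALSE).
#' @return list with `chi2`, `df`, `p` (nested) or `delta_aic`.
#' @export
compare_models <- function(fitA, fitB, nested) {
  stopifnot(inherits(fitA, "lme_fit"), inherits(fitB, "lme_fit"))
  if (fitA$n_obs != fitB$n_obs) {
    stop("fits are not on the same rows (n_obs differ)")
  }
  if (nested) {
    if (fitA$fit_method != "ML" || fitB$fit_method != "ML") {
      stop("likelihood-ratio test requires ML fits (refit with reml = FALSE)")
    }
    chi2 <- 2 * (fitB$loglik - fitA$loglik)
    df <- fitB$n_params - fitA$n_params
    if (df < 0) stop("fitB has fewer parameters than fitA; swap the arguments")
    p <- if (df == 0) as.numeric(chi2 <= 0) else
      stats::pchisq(chi2, df, lower.tail = FALSE)
    list(chi2 = chi2, df = df, p = p)
  } else {
    list(delta_aic = fitB$aic - fitA$aic)
  }
}

#' Write an lme_fit's term table and metadata
#' @param fit an `lme_fit`.
#' @param path_tsv path for the term table TSV.
#' @param path_json optional path for the logLik/AIC/convergence bundle.
#' @return `path_tsv`, invisibly.
#' @export
write_lme_fit <- function(fit, path_tsv, path_json = NULL) {
  stopifnot(inherits(fit, "lme_fit"))
  utils::write.table(fit$terms, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      fit[c("formula_id", "reference_level", "loglik", "aic", "n_params",
            "n_obs", "fit_method", "converged", "singular")],
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}
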