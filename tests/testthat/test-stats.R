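# a small but estimable ISC-like table with known structure
sim_isc_table <- function(seed, delta = c("+M/+L" = 0.12, "-M/-L" = -0.12),
                          n_cond_per_type = 2, n_part = 12, n_froi = 3,
                          noise_sd = 0.1, base = 0.15) {
  set.seed(seed)
  types <- c("+M/-L", names(delta))
  rows <- list()
  for (ty in types) {
    for (ci in seq_len(n_cond_per_type)) {
      cond <- paste0(gsub("[^A-Za-z]", "", ty), ci)
      for (p in seq_len(n_part)) {
        for (fr in seq_len(n_froi)) {
          off <- if (ty == "+M/-L") 0 else delta[[ty]]
          rows[[length(rows) + 1L]] <- data.frame(
            participant = paste0("p", p), condition = cond,
            condition_type = ty, froi = paste0("F", fr),
            z = base + off + rnorm(1, 0, noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$r <- tanh(out$z)
  out
}

test_that("condition-type model uses the stated reference and recovers signs", {
  it <- sim_isc_table(1)
  fit <- fit_condition_model(it)
  expect_equal(fit$reference_level, "+M/-L")
  expect_s3_class(fit, "lme_fit")
  b <- fit$terms
  expect_gt(b$beta[b$name == "condition_type+M/+L"], 0)
  expect_lt(b$beta[b$name == "condition_type-M/-L"], 0)
  expect_true(all(b$se > 0))
  expect_true(all(b$p > 0 & b$p <= 1))
  # AIC identity under ML
  ml <- fit_condition_model(it, reml = FALSE)
  expect_equal(ml$aic, 2 * ml$n_params - 2 * ml$loglik)
  one_type <- it[it$condition_type == "+M/-L", ]
  expect_error(fit_condition_model(one_type), "2 condition types")
})

test_that("null simulations keep condition-type coefficients near zero", {
  hits <- sapply(1:20, function(s) {
    it <- sim_isc_table(s, delta = c("+M/+L" = 0, "-M/-L" = 0))
    b <- fit_condition_model(it)$terms
    contr <- b[b$name != "(Intercept)", ]
    all(abs(contr$beta) < 2.5 * contr$se)
  })
  expect_gte(mean(hits), 0.85)
})

test_that("changing the reference level shifts coefficients by contrast algebra", {
  it <- sim_isc_table(7)
  f1 <- fit_condition_model(it, reference = "+M/-L")
  f2 <- fit_condition_model(it, reference = "+M/+L")
  b1 <- setNames(f1$terms$beta, f1$terms$name)
  b2 <- setNames(f2$terms$beta, f2$terms$name)
  # mean of +M/+L under ref A = intercept_A + beta_A(+M/+L) = intercept_B
  expect_equal(unname(b1["(Intercept)"] + b1["condition_type+M/+L"]),
               unname(b2["(Intercept)"]), tolerance = 1e-6)
  # contrast -M/-L vs +M/-L equals difference of the two references' terms
  expect_equal(unname(b1["condition_type-M/-L"]),
               unname(b2["condition_type-M/-L"] - b2["condition_type+M/-L"]),
               tolerance = 1e-6)
})

test_that("per-stimulus recoding yields six types and three FDR-grouped baselines", {
  d <- make_design("paper", seed = 6)
  it <- compute_isc_table(preprocess_timecourses(simulate_timecourses(d)))
  d6 <- natisc:::recode_six_types(it)
  expect_length(unique(d6$condition_type6), 6)

  tests <- per_condition_tests(it)
  stimuli <- unique(it$condition[it$condition_type == "+M/-L"])
  expect_equal(nrow(tests), 3 * length(stimuli))
  expect_true(all(tests$p_fdr >= tests$p - 1e-15))
  # every +M/-L stimulus is above zero baseline in this simulation
  vs0 <- tests[tests$reference == "zero", ]
  expect_true(all(vs0$beta > 0))
})

test_that("per-fROI models fit each region and correct across the fROI family", {
  it <- sim_isc_table(3, n_froi = 4)
  fits <- fit_per_froi_model(it)
  expect_length(fits, 4)
  tab <- attr(fits, "fdr_table")
  expect_true(all(tab$p_fdr >= tab$p - 1e-15))
  for (nm in unique(tab$name)) {
    sel <- tab$name == nm
    expect_equal(tab$p_fdr[sel], fdr_bh(tab$p[sel]))
  }
})

test_that("interaction model drops the global intercept and sizes its design", {
  it <- sim_isc_table(4, n_froi = 5)
  fit <- fit_interaction_model(it)
  expect_false("(Intercept)" %in% fit$terms$name)
  n_froi <- 5; n_types <- 3
  expect_equal(nrow(fit$terms), n_froi + n_froi * (n_types - 1))
})

test_that("fdr_bh validates input and matches the brute-force oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  sorted <- fdr_bh(c(0.001, 0.01, 0.2, 0.6))
  expect_true(all(diff(sorted) >= 0))
  for (seed in 1:60) {
    set.seed(seed)
    p <- runif(sample(1:6, 1))
    expect_equal(fdr_bh(p), unname(oracle_bh(p)), tolerance = 1e-15)
  }
})

test_that("model comparison distinguishes nested LRT from AIC and guards misuse", {
  it <- sim_isc_table(5)
  a <- fit_condition_model(it, reml = FALSE)
  same <- compare_models(a, a, nested = TRUE)
  expect_equal(same$chi2, 0)
  expect_equal(same$df, 0)
  expect_equal(compare_models(a, a, nested = FALSE)$delta_aic, 0)

  # add a pure-noise regressor: chi2 small, p from the chi-square quantile
  d <- as.data.frame(it)
  set.seed(99)
  d$junk <- rnorm(nrow(d))
  d$condition_type <- natisc:::ct_factor(d$condition_type, "+M/-L")
  b <- natisc:::fit_lme(d, "condition_type + junk",
                        c("froi", "participant", "condition"), "junk",
                        reml = FALSE)
  cmp <- compare_models(a, b, nested = TRUE)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p, pchisq(cmp$chi2, 1, lower.tail = FALSE))
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)

  reml_fit <- fit_condition_model(it, reml = TRUE)
  expect_error(compare_models(reml_fit, reml_fit, nested = TRUE), "ML")
  small <- fit_condition_model(it[-(1:3), ], reml = FALSE)
  expect_error(compare_models(a, small, nested = FALSE), "same rows")
})

test_that("single-level random factors are dropped loudly, not silently", {
  it <- sim_isc_table(8)
  it$froi <- "onlyF"
  expect_warning(fit <- fit_condition_model(it), "froi")
  expect_true("froi" %in% fit$dropped_random)
})
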