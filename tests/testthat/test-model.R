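make_frame <- function(n_per_region = 40L, seed = 2L, ...) {
  gen <- generate_dataset(small_genconfig(n_per_region, seed = seed, ...), mask = FALSE)
  lags <- compute_lags(gen$records)
  list(frame = build_model_frame(gen$records, lags), truth = gen$truth)
}

test_that("collinearity screen flags pairs above the absolute threshold", {
  set.seed(1)
  x <- rnorm(200)
  df <- data.frame(a = x, b = 2 * x, c = -x, d = rnorm(200))
  hits <- collinearity_screen(df, threshold = 0.70)
  pairs <- paste(hits$var1, hits$var2)
  expect_true(all(c("a b", "a c", "b c") %in% pairs))
  expect_false(any(grepl("d", pairs)))
  # independent columns pass at realistic n
  set.seed(2)
  clean <- as.data.frame(matrix(rnorm(5000 * 4), ncol = 4))
  expect_equal(nrow(collinearity_screen(clean)), 0L)
  expect_error(collinearity_screen(data.frame(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("fitted coefficients recover the generator truth on one large dataset", {
  mf <- make_frame(n_per_region = 224L, seed = 8L)
  fit <- fit_lmm(mf$frame)
  expect_true(fit$converged)
  beta <- attr(mf$truth, "beta")
  co <- fit$coefficients
  for (term in c("genetics", "n_authors", "n_trips")) {
    est <- co$estimate[co$term == term]
    se <- co$se[co$term == term]
    expect_lt(abs(est - beta[[term]]), 3 * se)
  }
  # AIC identity
  expect_equal(fit$AIC, 2 * fit$df - 2 * fit$logLik, tolerance = 1e-10)
  expect_true(all(fit$varcomp >= 0))
})

test_that("the lme4 fit agrees with the glmmTMB route on the same data", {
  mf <- make_frame(n_per_region = 30L, seed = 15L)
  fit <- fit_lmm(mf$frame)
  tmb <- glmmTMB::glmmTMB(
    log_description_y ~ genetics + n_authors + n_types + n_species_in_paper +
      n_trips + genus_richness + (1 | genus) + (1 | region),
    data = mf$frame, family = stats::gaussian(), REML = FALSE
  )
  expect_equal(fit$coefficients$estimate, unname(glmmTMB::fixef(tmb)$cond),
               tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(tmb)), tolerance = 1e-4)
})

test_that("with a single-level random effect the fit collapses to OLS", {
  mf <- make_frame(n_per_region = 25L, seed = 6L)
  one_region <- mf$frame[mf$frame$region == "India", ]
  one_region$genus <- factor("onlygenus")
  fit <- suppressMessages(fit_lmm(one_region, scope = "India"))
  ols <- stats::lm(log_description_y ~ genetics + n_authors + n_types +
                     n_species_in_paper + n_trips + genus_richness,
                   data = one_region)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("a constant response with intercept-only fixed part is fit exactly", {
  mf <- make_frame(n_per_region = 10L, seed = 3L)
  fr <- mf$frame
  fr$log_description_y <- 1.234
  fit <- fit_lmm(fr, fixed = character())
  expect_equal(fit$coefficients$estimate[1], 1.234, tolerance = 1e-6)
  expect_lt(fit$varcomp[["residual"]], 1e-8)
})

test_that("regional scope drops region and any covariate constant within it", {
  mf <- make_frame(n_per_region = 30L, seed = 10L)
  fr <- mf$frame
  fr$genetics[fr$region == "India"] <- 1
  expect_message(fit <- fit_lmm(fr, scope = "India"), "constant within scope")
  expect_false("genetics" %in% fit$spec$fixed)
  expect_equal(fit$spec$random, "genus")
})

test_that("single-coefficient Wald terms satisfy the (coef/se)^2 identity", {
  mf <- make_frame(n_per_region = 30L, seed = 5L)
  fit <- fit_lmm(mf$frame)
  an <- wald_anova(fit)
  co <- fit$coefficients
  for (term in an$term) {
    expect_equal(an$chisq[an$term == term],
                 (co$estimate[co$term == term] / co$se[co$term == term])^2,
                 tolerance = 1e-6)
    expect_equal(an$df[an$term == term], 1)
  }
  expect_equal(an$p, stats::pchisq(an$chisq, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("null comparison reports LR, df and AIC preference correctly", {
  mf <- make_frame(n_per_region = 40L, seed = 9L)
  full <- fit_lmm(mf$frame)
  null <- fit_lmm(mf$frame, fixed = character())
  cmp <- compare_null(full, null)
  expect_equal(cmp$df, 6)
  expect_equal(cmp$lr, 2 * (full$logLik - null$logLik), tolerance = 1e-10)
  # full-model ML likelihood can never fall below the nested null's
  expect_gte(full$logLik, null$logLik)
  self <- compare_null(full, full)
  expect_equal(self$lr, 0)
  expect_equal(self$aic_delta, 0)
  expect_error(compare_null(null, full), "nested")
})

test_that("scaled residuals are bounded, seed-reproducible and well calibrated in-sample", {
  mf <- make_frame(n_per_region = 40L, seed = 12L)
  fit <- fit_lmm(mf$frame)
  r1 <- simulate_residuals(fit, n_sim = 100, seed = 99)
  r2 <- simulate_residuals(fit, n_sim = 100, seed = 99)
  expect_identical(r1, r2)
  expect_true(all(r1$residuals >= 0 & r1$residuals <= 1))
  # data generated by the model itself should not be flagged
  expect_gt(r1$uniformity$p, 0.01)
  expect_gt(r1$dispersion$p, 0.01)
  r3 <- simulate_residuals(fit, n_sim = 100, seed = 100)
  expect_false(identical(r1$residuals, r3$residuals))
})

test_that("a response with doubled residual spread triggers the dispersion alarm", {
  mf <- make_frame(n_per_region = 40L, seed = 13L)
  fit <- fit_lmm(mf$frame)
  y <- taxalag:::observed_response(fit$model)
  mu <- taxalag:::unconditional_fitted(fit$model)
  res <- simulate_residuals(fit, n_sim = 200, seed = 1, response = mu + 2 * (y - mu))
  expect_lt(res$dispersion$p, 0.05)
  expect_gt(res$dispersion$statistic, 2)
})

test_that("model JSON serialization writes every block", {
  mf <- make_frame(n_per_region = 15L, seed = 2L)
  fit <- fit_lmm(mf$frame)
  null <- fit_lmm(mf$frame, fixed = character())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, tmp, anova = wald_anova(fit),
                   null_comparison = compare_null(fit, null),
                   diagnostics = simulate_residuals(fit, n_sim = 60, seed = 2))
  got <- jsonlite::read_json(tmp)
  expect_named(got, c("spec", "n", "converged", "coefficients", "varcomp",
                      "logLik", "AIC", "anova", "null_comparison", "diagnostics"))
  expect_equal(got$n, fit$n)
})
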