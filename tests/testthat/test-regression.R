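# 2x2 table as an aggregated single-covariate design
table_design <- function(tb) {
  list(x = matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "drug")),
       y = c(1, 0, 1, 0),
       w = as.numeric(tb[c(1, 3, 2, 4)]))  # a, c, b, d
}

test_that("a single-covariate fit reproduces the crude odds ratio", {
  tb <- c(128, 33, 22387, 224449)
  d <- table_design(tb)
  fit <- fit_logistic(d$x, d$y, weights = d$w)
  crude <- (tb[1] * tb[4]) / (tb[2] * tb[3])
  expect_equal(exp(fit$coefficients[["drug"]]), crude, tolerance = 1e-7)
  expect_equal(fit$aror[["drug"]], exp(fit$coefficients[["drug"]]))
})

test_that("intercept-only and null fits have their closed forms", {
  set.seed(41)
  y <- rbinom(500, 1, 0.3)
  fit <- fit_logistic(NULL, y)
  expect_equal(plogis(fit$coefficients[["(Intercept)"]]), mean(y),
               tolerance = 1e-10)
})

test_that("coefficients match the reference GLM fitter", {
  set.seed(42)
  n <- 2000
  x <- cbind(x1 = rbinom(n, 1, 0.3), x2 = rbinom(n, 1, 0.5),
             x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x[, 1] - 0.5 * x[, 2] + 0.3 * x[, 3]))
  fit <- fit_logistic(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # likelihood at the fit is no worse than at the null model
  expect_gte(fit$loglik, fit_logistic(NULL, y)$loglik)
})

test_that("perfect separation raises an error naming the covariate", {
  x <- matrix(rep(0:1, each = 20), ncol = 1,
              dimnames = list(NULL, "sepdrug"))
  y <- rep(0:1, each = 20)
  expect_error(fit_logistic(x, y), "sepdrug")
  expect_error(fit_logistic(matrix(1, 10, 1, dimnames = list(NULL, "k")),
                            rbinom(10, 1, 0.5)), "constant")
})

test_that("null-model p-values are uniform across replicates", {
  set.seed(43)
  pvals <- c()
  for (r in 1:200) {
    n <- 1000
    x <- cbind(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.5),
               c = rbinom(n, 1, 0.1))
    y <- rbinom(n, 1, 0.2)
    fit <- fit_logistic(x, y)
    pvals <- c(pvals, fit$p_values[-1])
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stepwise selection honors its degenerate contracts", {
  run <- shared_run()
  at <- run$analysis
  des <- build_design(at, c("lansoprazole", "aspirin"))
  # empty candidate list: identical to the forced-terms fit
  s0 <- stepwise_select(des$x, des$y, des$forced_terms, character(0))
  f0 <- fit_logistic(des$x[, des$forced_terms], des$y)
  expect_equal(s0$coefficients, f0$coefficients)
  expect_length(s0$selected_drugs, 0L)
})

test_that("stepwise recovers injected effects and skips null drugs", {
  run <- shared_run()
  sel <- run$model$selected_drugs
  expect_true(all(c("lansoprazole", "aspirin") %in% sel))
  # the fitted aROR CI covers each injected odds ratio
  ci <- run$model$aror_ci
  expect_true(ci["lansoprazole", "low"] <= 35 &&
                35 <= ci["lansoprazole", "high"])
  expect_true(ci["aspirin", "low"] <= 2 && 2 <= ci["aspirin", "high"])
  # VIFs in the final model stay below 2
  expect_true(all(run$model$vif < 2))
})

test_that("by-sex subsets partition the table and mirror symmetric data", {
  run <- shared_run()
  at <- run$analysis
  fits <- subset_by_sex(at, c("lansoprazole", "aspirin"))
  expect_equal(fits$female$n + fits$male$n, nrow(at$cases))
  expect_false("sex_female" %in% fits$female$terms)

  # duplicated pooled data with sex relabelled: coefficients coincide
  at2 <- at
  dup <- at$cases
  dup$case_id <- paste0(dup$case_id, "_m")
  dup$sex <- "male"
  fem <- at$cases
  fem$sex <- "female"
  at2$cases <- rbind(fem, dup)
  expo2 <- rbind(at$exposures,
                 transform(at$exposures,
                           case_id = paste0(case_id, "_m")))
  at2$exposures <- expo2
  fits2 <- subset_by_sex(at2, "lansoprazole")
  expect_equal(fits2$female$coefficients, fits2$male$coefficients,
               tolerance = 1e-6)
})

test_that("VIFs match their closed forms", {
  x <- cbind(u = rep(c(0, 1), each = 50), v = rep(c(0, 1), times = 50))
  v <- compute_vif(x)
  expect_equal(unname(v), c(1, 1))  # orthogonal design

  set.seed(44)
  a <- rnorm(400)
  b <- 0.6 * a + rnorm(400)
  r <- cor(a, b)
  v2 <- compute_vif(cbind(a = a, b = b))
  expect_equal(unname(v2), rep(1 / (1 - r^2), 2), tolerance = 1e-9)

  v3 <- compute_vif(cbind(a = a, b = b, a2 = a))  # exact collinearity
  expect_true(is.infinite(v3[["a"]]) && is.infinite(v3[["a2"]]))

  skip_if_not_installed("car")
  y <- rnorm(400)
  ref <- car::vif(lm(y ~ a + b))
  expect_equal(unname(v2), unname(ref), tolerance = 1e-8)
})
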