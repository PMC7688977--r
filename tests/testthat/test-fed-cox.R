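# The 3-patient toy admits full hand enumeration at beta = 0:
#   grid (1.0, 2.0); risk sets {1,2,3} and {2,3}; d = (1,1); s = (1,0);
#   S0 = (3,2); S1 = (2,1); S2 = (2,1);
#   ll(0) = -(log 3 + log 2); U = -1/6; I = 17/36; step = -6/17.

test_that("local aggregates at beta = 0 match hand-enumerated risk sets", {
  toy <- toy_site()
  grid <- c(10L, 20L)
  agg <- cox_local_aggregates(toy$time, toy$event, toy$X, grid, beta = 0)
  expect_equal(agg$d, c(1L, 1L))
  expect_equal(unname(agg$s), matrix(c(1, 0), 2, 1))
  expect_equal(agg$S0, c(3, 2))
  expect_equal(unname(agg$S1), matrix(c(2, 1), 2, 1))
  expect_equal(as.numeric(agg$S2), c(2, 1))
})

test_that("a site past its last follow-up contributes zeros to the grid", {
  agg <- cox_local_aggregates(time = c(0.5, 0.9), event = c(1L, 0L),
                              X = matrix(1:2, 2, 1), grid = c(5L, 12L),
                              beta = 0)
  expect_equal(agg$S0, c(2, 0))
  expect_equal(unname(agg$S1[2, ]), 0)
})

test_that("partial log-likelihood at zero has the closed risk-set form", {
  toy <- toy_site()
  agg <- cox_local_aggregates(toy$time, toy$event, toy$X, c(10L, 20L), 0)
  expect_equal(partial_loglik(agg, 0), -(log(3) + log(2)))
})

test_that("one Newton step reproduces the scalar hand computation", {
  toy <- toy_site()
  agg <- cox_local_aggregates(toy$time, toy$event, toy$X, c(10L, 20L), 0)
  st <- newton_step(agg, beta = 0)
  expect_equal(unname(st$gradient), -1 / 6)
  expect_equal(as.numeric(st$information), 17 / 36)
  expect_equal(unname(st$beta), -6 / 17)
})

test_that("aggregates are additive: two copies equal one doubled site", {
  toy <- toy_site()
  beta <- 0.3
  one <- cox_local_aggregates(toy$time, toy$event, toy$X, c(10L, 20L), beta)
  both <- sum_aggregates(list(one, one))
  doubled <- cox_local_aggregates(rep(toy$time, 2), rep(toy$event, 2),
                                  rbind(toy$X, toy$X), c(10L, 20L), beta)
  expect_equal(both$S0, doubled$S0)
  expect_equal(both$s, doubled$s)
  expect_equal(newton_step(both, beta)$beta, newton_step(doubled, beta)$beta)
})

test_that("the event grid is the sorted union of site event times", {
  a <- data.frame(time = c(0.5, 1.2, 4.0), event = c(1L, 1L, 0L))
  b <- data.frame(time = c(1.2, 3.0), event = c(1L, 1L))
  fed <- federation(list(A = a, B = b))
  grid <- build_event_grid(fed)
  expect_equal(grid$times, c(0.5, 1.2, 3.0))
  expect_equal(grid$K, 3)
  one <- federation(list(A = a))
  expect_equal(build_event_grid(one)$times, c(0.5, 1.2))
  cens <- federation(list(A = data.frame(time = c(1, 2), event = c(0L, 0L))))
  expect_error(build_event_grid(cens), "no events")
})

test_that("a single-site federation equals the centralized Breslow fit", {
  skip_if_not_installed("survival")
  cfg <- sim_config(n = c(TW = 400), probs = lt50_probs(), seed = 21)
  co <- generate_cohorts(cfg)$TW
  spec <- model_spec(cohort_domains()[c("age_cat", "sex", "stage_group")])
  fit <- fit_federated_cox(federation(list(TW = co)), spec)
  X <- build_design_matrix(co, spec)
  or <- suppressWarnings(
    survival::coxph(survival::Surv(co$time, co$event) ~ X, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-12)))
  expect_lt(max(abs(coef(fit) - unname(coef(or)))), 1e-8)
  expect_lt(max(abs(vcov(fit) - unname(vcov(or)))), 1e-8)
  expect_equal(fit$loglik, or$loglik[2], tolerance = 1e-10)
  expect_equal(fit$loglik_null, or$loglik[1], tolerance = 1e-10)
})

test_that("estimates are invariant to partitioning and to centering", {
  cfg <- sim_config(n = c(TW = 360), probs = lt50_probs(), seed = 22)
  co <- generate_cohorts(cfg)$TW[cohort_columns()]
  spec <- model_spec(cohort_domains()[c("sex", "treatment")])
  fit1 <- fit_federated_cox(federation(list(A = co)), spec)
  set.seed(1)
  parts <- split(co, sample(rep(1:3, length.out = nrow(co))))
  fit3 <- fit_federated_cox(federation(parts), spec)
  expect_lt(max(abs(coef(fit1) - coef(fit3))), 1e-9)
  expect_lt(max(abs(fit1$loglik - fit3$loglik)), 1e-9)
  expect_lt(max(abs(vcov(fit1) - vcov(fit3))), 1e-9)
  raw <- fit_federated_cox(federation(list(A = co)), spec,
                           fed_cox_control(center = FALSE))
  expect_lt(max(abs(coef(fit1) - coef(raw))), 1e-9)
  expect_lt(max(abs(fit1$loglik - raw$loglik)), 1e-9)
})

test_that("fitted models are stationary and improve on the null", {
  cfg <- study_scaled_config(seed = 23)
  fed <- federation(generate_cohorts(cfg))
  fit <- fit_federated_cox(fed, multivariable_spec())
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_true(all(eigen(fit$var, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(fit$var, t(fit$var))
})

test_that("a covariate independent of survival is estimated near zero", {
  cfg <- sim_config(n = c(TW = 4000), probs = lt50_probs(),
                    spec = model_spec(list(sex = c("female", "male"))),
                    beta = c("sex=male" = 0), seed = 24)
  co <- generate_cohorts(cfg)$TW
  # break any residual link by permuting the covariate
  set.seed(25)
  co$sex <- co$sex[sample(nrow(co))]
  fit <- fit_federated_cox(federation(list(TW = co)),
                           model_spec(list(sex = c("female", "male"))))
  expect_lt(abs(coef(fit)[[1]]), 3 * sqrt(vcov(fit)[1, 1]))
})

test_that("the max-delta stopping rule reaches the same optimum", {
  cfg <- sim_config(n = c(TW = 300), probs = lt50_probs(), seed = 26)
  co <- generate_cohorts(cfg)$TW
  spec <- model_spec(cohort_domains()[c("sex", "age_cat")])
  f1 <- fit_federated_cox(federation(list(TW = co)), spec)
  f2 <- fit_federated_cox(federation(list(TW = co)), spec,
                          fed_cox_control(criterion = "max_delta", tol = 1e-9))
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-7)
})

test_that("non-convergence and collinearity raise informative errors", {
  cfg <- sim_config(n = c(TW = 200), probs = lt50_probs(), seed = 27)
  co <- generate_cohorts(cfg)$TW
  spec <- model_spec(list(sex = c("female", "male")))
  expect_error(fit_federated_cox(federation(list(TW = co)), spec,
                                 fed_cox_control(max_iter = 1)),
               "did not converge")
  co$dup <- co$sex
  spec2 <- model_spec(list(sex = c("female", "male"),
                           dup = c("female", "male")))
  expect_error(fit_federated_cox(federation(list(TW = co)), spec2),
               "collinear")
})

test_that("hazard-ratio tables follow the closed Wald form", {
  spec <- model_spec(list(sex = c("female", "male")))
  fit <- structure(list(coefficients = c("sex=male" = log(2)),
                        var = matrix(0.01, 1, 1,
                                     dimnames = list("sex=male", "sex=male")),
                        spec = spec, labels = "sex=male", converged = TRUE),
                   class = "fed_cox_fit")
  tab <- hazard_ratios(fit)
  expect_equal(tab$hr, c(1, 2))
  expect_true(tab$reference[1])
  expect_equal(tab$lo[2], exp(log(2) - qnorm(0.975) * 0.1))
  expect_equal(tab$hi[2], exp(log(2) + qnorm(0.975) * 0.1))
  fmt <- format_hr_table(tab)
  expect_equal(fmt$HR, c("1.00", "2.00"))
  expect_equal(fmt$CI[1], "–")
  fit$converged <- FALSE
  expect_error(hazard_ratios(fit), "non-converged")
  # a zero coefficient gives HR 1 with a log-symmetric interval
  fit$converged <- TRUE
  fit$coefficients[1] <- 0
  tab0 <- hazard_ratios(fit)
  expect_equal(tab0$hr[2], 1)
  expect_equal(tab0$lo[2] * tab0$hi[2], 1, tolerance = 1e-12)
})
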