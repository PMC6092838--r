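test_that("single-record shrinkage follows the scalar closed form", {
  ped <- pedigree(data.frame(animal = 1, sire = 0, dam = 0))
  rec <- tibble::tibble(animal = 1, litter = 1, pen = 1, y = 7)
  # two animals so the mean is not fully confounded with the record
  ped2 <- pedigree(data.frame(animal = 1:2, sire = 0, dam = 0))
  rec2 <- tibble::tibble(animal = 1:2, litter = 1:2, pen = 1:2, y = c(7, 3))
  fit <- fit_blup(rec2, ped2, varcomp = list(sigma_a2 = 120, sigma_e2 = 280),
                  model = "A", level = "individual")
  mu <- fit$fixed
  h2like <- 120 / (120 + 280)
  # with two unrelated animals, EBV_i = k (y_i - mu) with k from the MME
  eb <- ebv(fit)$ebv
  expect_equal(eb, h2like * (rec2$y - mu), tolerance = 1e-8)
})

test_that("MME/BLUP solutions and likelihoods match dense GLS oracles", {
  set.seed(88)
  for (rep in 1:8) {
    toy <- oracle_toy(n_founders = sample(5:9, 1), n_extra = sample(10:20, 1),
                      n_rec = sample(12:24, 1))
    model <- sample(c("A", "AL", "AP", "ALP"), 1)
    level <- sample(c("individual", "group"), 1)
    terms <- groupbv:::parse_model(model)
    theta <- stats::setNames(runif(length(terms) + 1, 0.5, 5),
                             c(terms, "residual"))
    vc <- as.list(theta)
    names(vc) <- c(c(litter = "sigma_l2", pen = "sigma_c2",
                     additive = "sigma_a2")[terms], "sigma_e2")
    des <- groupbv:::as_design(toy$rec, toy$ped, level)
    fit <- fit_blup(des, varcomp = vc, model = model,
                    control = reml_control(force = TRUE))
    X <- as.matrix(des$X); y <- des$y
    Vl <- oracle_vlist(des, toy$A, terms)
    gls <- oracle_gls(y, X, Vl, theta, as.matrix(des$Za), toy$A,
                      theta[["additive"]])
    expect_equal(fit$fixed, gls$b, tolerance = 1e-8)
    expect_equal(ebv(fit)$ebv, gls$u, tolerance = 1e-8)
    expect_equal(-2 * fit$loglik, oracle_m2ll(y, X, Vl, theta),
                 tolerance = 1e-6)
  }
})

test_that("degenerate limits behave", {
  set.seed(90)
  toy <- oracle_toy()
  vc <- list(sigma_l2 = 2, sigma_c2 = 2, sigma_a2 = 1e-10, sigma_e2 = 3)
  fit <- fit_blup(toy$rec, toy$ped, varcomp = vc, model = "ALP",
                  level = "individual")
  expect_lt(max(abs(ebv(fit)$ebv)), 1e-6)

  rec0 <- toy$rec; rec0$y <- 0
  fit0 <- fit_blup(rec0, toy$ped,
                   varcomp = list(sigma_a2 = 2, sigma_e2 = 3), model = "A",
                   level = "group")
  expect_equal(ebv(fit0)$ebv, rep(0, nrow(toy$ped)))
  expect_equal(fit0$fixed, 0)
})

test_that("full sibs in one group with no other information share an EBV", {
  ped <- pedigree(data.frame(animal = 1:8, sire = c(0, 0, rep(1, 6)),
                             dam = c(0, 0, rep(2, 6))))
  rec <- tibble::tibble(animal = 3:8, litter = 1, pen = rep(1:2, each = 3),
                        y = rnorm(6, 5))
  fit <- fit_blup(rec, ped,
                  varcomp = list(sigma_a2 = 120, sigma_l2 = 40,
                                 sigma_c2 = 40, sigma_e2 = 200),
                  model = "ALP", level = "group",
                  control = reml_control(force = TRUE))
  eb <- ebv(fit)
  expect_lt(diff(range(eb$ebv[eb$animal %in% 3:5])), 1e-10)
  expect_lt(diff(range(eb$ebv[eb$animal %in% 6:8])), 1e-10)
})

test_that("REML matches a dense-likelihood optimiser on a toy dataset", {
  set.seed(91)
  toy <- oracle_toy(n_founders = 8, n_extra = 20, n_rec = 30, n_lit = 6,
                    n_pen = 5)
  des <- groupbv:::as_design(toy$rec, toy$ped, "individual")
  fit <- fit_reml(des, model = "AL")
  terms <- c("litter", "additive")
  Vl <- oracle_vlist(des, toy$A, terms)
  X <- as.matrix(des$X)
  # oracle: direct optimisation of the dense REML likelihood on log scale
  ob <- function(lt) oracle_m2ll(des$y, X, Vl, exp(lt))
  best <- Inf
  for (s in 1:3) {
    o <- optim(log(c(2, 2, 2) * s), ob, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    if (o$value < best) { best <- o$value; opar <- exp(o$par) }
  }
  expect_equal(-2 * fit$loglik, best, tolerance = 1e-5)
  est <- stats::setNames(fit$varcomp$estimate, fit$varcomp$term)
  expect_equal(unname(est[c("sigma_l2", "sigma_a2", "sigma_e2")]), opar,
               tolerance = 1e-2)
})

test_that("REML score matches numerical derivatives of the dense likelihood", {
  set.seed(92)
  toy <- oracle_toy()
  for (level in c("individual", "group")) {
    des <- groupbv:::as_design(toy$rec, toy$ped, level)
    mc <- groupbv:::mme_machine(des, "ALP")
    theta <- c(litter = 2, pen = 1.5, additive = 3, residual = 2.5)
    ev <- groupbv:::mme_eval(mc, theta, derivs = TRUE)
    Vl <- oracle_vlist(des, toy$A, c("litter", "pen", "additive"))
    X <- as.matrix(des$X)
    for (k in seq_along(theta)) {
      h <- 1e-5 * theta[k]
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      gnum <- -(oracle_m2ll(des$y, X, Vl, tp) -
                  oracle_m2ll(des$y, X, Vl, tm)) / (2 * unname(h)) / 2
      expect_equal(unname(ev$g[k]), gnum, tolerance = 1e-6)
    }
  }
})

test_that("reduced-weight model reproduces the full pen model", {
  set.seed(93)
  pop <- simulate_population(tiny_config(), seed = 93)
  vc <- list(sigma_a2 = 120, sigma_l2 = 40, sigma_c2 = 40, sigma_e2 = 200)
  full <- fit_blup(pop, varcomp = vc, model = "ALP", level = "group")
  red <- fit_blup(pop, varcomp = vc[c("sigma_a2", "sigma_l2", "sigma_e2")],
                  model = "AL", level = "group",
                  reduced_pen = TRUE, b_ratio = 40 / 200)
  expect_equal(red$loglik, full$loglik, tolerance = 1e-8)
  expect_equal(ebv(red)$ebv, ebv(full)$ebv, tolerance = 1e-8)

  # equivalence holds for arbitrary b and varying group sizes
  b <- 0.37
  full2 <- fit_blup(pop, varcomp = list(sigma_a2 = 100, sigma_l2 = 30,
                                        sigma_c2 = b * 150, sigma_e2 = 150),
                    model = "ALP", level = "group")
  red2 <- fit_blup(pop, varcomp = list(sigma_a2 = 100, sigma_l2 = 30,
                                       sigma_e2 = 150),
                   model = "AL", level = "group", reduced_pen = TRUE,
                   b_ratio = b)
  expect_equal(red2$loglik, full2$loglik, tolerance = 1e-8)
  expect_equal(ebv(red2)$ebv, ebv(full2)$ebv, tolerance = 1e-8)
})

test_that("record order does not change estimates", {
  set.seed(94)
  toy <- oracle_toy(n_rec = 24)
  f1 <- fit_reml(toy$rec, toy$ped, model = "AL", level = "individual")
  perm <- sample(nrow(toy$rec))
  f2 <- fit_reml(toy$rec[perm, ], toy$ped, model = "AL", level = "individual")
  expect_equal(f1$varcomp$estimate, f2$varcomp$estimate, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("confounded layouts are refused without force", {
  pop <- simulate_population(tiny_config(attrition = 0), seed = 95)
  expect_error(fit_reml(pop, level = "group", model = "ALP"),
               class = "groupbv_singular")
  expect_error(
    fit_blup(simulate_population(tiny_config(allocation = "L_1x6",
                                             pen_capacity = 6, attrition = 0),
                                 seed = 96),
             varcomp = list(sigma_a2 = 120, sigma_l2 = 40, sigma_c2 = 40,
                            sigma_e2 = 200),
             model = "ALP", level = "group"),
    class = "groupbv_singular")
})

test_that("mixed_model_equations returns a solvable symmetric system", {
  set.seed(97)
  toy <- oracle_toy()
  des <- groupbv:::as_design(toy$rec, toy$ped, "group")
  vc <- list(sigma_a2 = 3, sigma_l2 = 2, sigma_c2 = 1.5, sigma_e2 = 2.5)
  mm <- mixed_model_equations(des, vc, model = "ALP")
  expect_true(Matrix::isSymmetric(mm$C))
  sol <- as.numeric(Matrix::solve(mm$C, mm$rhs))
  fit <- fit_blup(des, varcomp = vc, model = "ALP",
                  control = reml_control(force = TRUE))
  expect_equal(sol[mm$index$additive], ebv(fit)$ebv, tolerance = 1e-8)
})
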