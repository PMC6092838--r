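test_that("population counts follow the mating design", {
  cfg <- tiny_config()
  pop <- simulate_population(cfg, seed = 1)
  an <- pop$animals
  per_gen <- cfg$n_sires * cfg$n_dams_per_sire * cfg$litter_size
  expect_equal(sum(an$generation == 1), per_gen)
  expect_equal(length(unique(an$litter[an$generation == 2])),
               cfg$n_sires * cfg$n_dams_per_sire)
  # littermates share dam and sire
  lits <- an[an$generation == 3, ]
  bylit <- split(lits, lits$litter)
  expect_true(all(vapply(bylit, function(d)
    length(unique(d$dam)) == 1 && length(unique(d$sire)) == 1, logical(1))))
  # phenotypes only in the last n_pheno_generations
  expect_setequal(unique(an$generation[!is.na(an$y)]), 3:4)
})

test_that("config validation rejects infeasible structures", {
  expect_error(sim_config(pen_capacity = 10, allocation = "L_1x6"),
               class = "groupbv_allocation_error")
  expect_error(sim_config(pen_capacity = 10, allocation = "L_2x3"),
               class = "groupbv_allocation_error")
  expect_error(sim_config(attrition = 1), class = "groupbv_config_error")
  expect_error(sim_config(sigma_a2 = -1), class = "groupbv_config_error")
  expect_error(sim_config(n_sires = 2, n_dams_per_sire = 2, litter_size = 1,
                          allocation = "random", pen_capacity = 2),
               class = "groupbv_config_error")
})

test_that("phenotypic variance matches the component sum", {
  # additive + residual phenotype: Var(y) ~ 120 + 280
  cfg <- sim_config(n_sires = 10, n_dams_per_sire = 20, n_generations = 2,
                    n_pheno_generations = 1, with_litter_pen = FALSE,
                    attrition = 0)
  pop <- simulate_population(cfg, seed = 11)
  v <- var(records(pop)$y)
  expect_gt(v, 360); expect_lt(v, 440)

  # full phenotype: 120 + 40 + 40 + 200 = 400 (between-components independent)
  cfg2 <- sim_config(n_sires = 10, n_dams_per_sire = 20, n_generations = 2,
                     n_pheno_generations = 1, attrition = 0)
  pop2 <- simulate_population(cfg2, seed = 12)
  v2 <- var(records(pop2)$y)
  expect_gt(v2, 350); expect_lt(v2, 450)
})

test_that("breeding values transmit without bias and with Mendelian noise", {
  cfg <- sim_config(n_sires = 8, n_dams_per_sire = 15, n_generations = 3,
                    n_pheno_generations = 1)
  pop <- simulate_population(cfg, seed = 21)
  an <- pop$animals
  off <- an[an$generation > 0, ]
  mid <- 0.5 * (an$a[off$sire] + an$a[off$dam])
  fit <- lm(off$a ~ mid)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.07)
  ms <- off$a - mid
  expect_equal(var(ms), 60, tolerance = 0.1 * 60) # sigma_a2 / 2 = 60
})

test_that("pen allocation structures hold", {
  cfg <- tiny_config(attrition = 0)
  # whole litters: every pen has exactly two litters, each litter one pen
  p1 <- simulate_population(tiny_config(allocation = "L_1x6", attrition = 0),
                            seed = 31)
  r1 <- records(p1)
  litters_per_pen <- tapply(r1$litter, r1$pen, function(x) length(unique(x)))
  expect_true(all(litters_per_pen == 2))
  counts <- table(r1$pen, r1$litter)
  expect_setequal(unique(as.vector(counts[counts > 0])), 6)

  # sub-litters of three: litters contribute in multiples of 3; pens draw
  # from (almost always) four litters -- the two sub-litters of one litter
  # can land in the same pen under random placement
  p2 <- simulate_population(tiny_config(allocation = "L_2x3", attrition = 0),
                            seed = 32)
  r2 <- records(p2)
  counts2 <- table(r2$pen, r2$litter)
  expect_true(all(as.vector(counts2) %% 3 == 0))
  litters_pp <- rowSums(counts2 > 0)
  expect_true(all(litters_pp >= 3 & litters_pp <= 4))
  expect_gt(mean(litters_pp), 3.5)

  # capacity 3 sub-litters: each pen is one intact sub-litter
  p3 <- simulate_population(tiny_config(allocation = "sublitter3",
                                        pen_capacity = 3, attrition = 0),
                            seed = 33)
  r3 <- records(p3)
  expect_true(all(table(r3$pen) == 3))
  expect_true(all(tapply(r3$litter, r3$pen, function(x) length(unique(x))) == 1))

  # no attrition: all groups at designed capacity
  expect_true(all(table(records(simulate_population(cfg, seed = 34))$pen) == 12))
})

test_that("attrition yields binomial group sizes and spares breeders", {
  cfg <- sim_config(n_sires = 5, n_dams_per_sire = 10, n_generations = 5,
                    n_pheno_generations = 3)
  sizes <- integer(); nlit <- numeric()
  for (s in 1:6) {
    pop <- simulate_population(cfg, seed = 40 + s)
    an <- pop$animals
    # every parent of generation g+1 is retained in its own generation
    parents <- unique(c(an$sire[an$generation > 0], an$dam[an$generation > 0]))
    parents <- parents[parents > 0]
    tested_parents <- an$animal %in% parents & an$phenotyped
    expect_true(all(an$retained[tested_parents]))
    rec <- records(pop)
    # pens containing no breeders: sizes are Binomial(12, 0.8) draws
    breeder_pens <- unique(an$pen[an$breeder & !is.na(an$pen)])
    free <- rec[!(rec$pen %in% breeder_pens), ]
    sizes <- c(sizes, as.integer(table(free$pen)))
    nlit <- c(nlit, as.vector(table(rec$pen, rec$litter)))
  }
  expect_equal(mean(sizes), 12 * 0.8, tolerance = 0.03)
  nlit <- nlit[nlit > 0]
  # chi-square fit to Binomial(12, 0.8), pooling the lower tail
  tab <- table(factor(pmax(sizes, 6), levels = 6:12))
  pr <- dbinom(6:12, 12, 0.8); pr[1] <- pbinom(6, 12, 0.8)
  pval <- suppressWarnings(chisq.test(as.vector(tab), p = pr / sum(pr)))$p.value
  expect_gt(pval, 0.01)
})

test_that("mean littermates per pen under sub-litter allocation is 2.4", {
  cfg <- sim_config(n_sires = 5, n_dams_per_sire = 10, n_generations = 4,
                    n_pheno_generations = 2, allocation = "sublitter3")
  nl <- numeric()
  for (s in 1:5) {
    rec <- records(simulate_population(cfg, seed = 50 + s))
    cnt <- table(rec$pen, rec$litter)
    nl <- c(nl, as.vector(cnt[cnt > 0]))
  }
  expect_equal(mean(nl), 3 * 0.8, tolerance = 0.05)
})

test_that("named scenarios set the documented variance structures", {
  expect_equal(scenario_config("base")$sigma_e2, 200)
  nl <- scenario_config("no_litter_pen")
  expect_equal(c(nl$sigma_l2, nl$sigma_c2, nl$sigma_e2), c(0, 0, 280))
  lh <- scenario_config("low_h2")
  expect_equal(lh$sigma_e2, 1000)
  # h2 = 120 / (120 + 40 + 40 + 1000) = 0.10
  expect_equal(lh$sigma_a2 / (lh$sigma_a2 + lh$sigma_l2 + lh$sigma_c2 +
                                lh$sigma_e2), 0.1)
  lh2 <- scenario_config("low_h2_no_litter_pen")
  expect_equal(lh2$sigma_a2 / (lh2$sigma_a2 + lh2$sigma_e2), 0.1)
  expect_equal(scenario_config("L_1x6")$allocation, "L_1x6")
  expect_equal(scenario_config("base", n_sires = 4)$n_sires, 4)
})

test_that("simulation is reproducible from the seed", {
  cfg <- tiny_config()
  r1 <- records(simulate_population(cfg, seed = 99))
  r2 <- records(simulate_population(cfg, seed = 99))
  expect_identical(r1, r2)
})
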