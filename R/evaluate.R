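#' Accuracy and bias of predicted breeding values
#'
#' Accuracy is the Pearson correlation between predicted and true breeding
#' values over phenotyped animals; bias is the ordinary least-squares slope
#' of true on predicted breeding value (1 = unbiased, < 1 = inflated
#' predictions).
#'
#' @param tbv true breeding values.
#' @param ebv predicted breeding values, aligned with `tbv`.
#' @param phenotyped logical mask selecting the animals with phenotype data.
#' @return a single number.
#' @examples
#' accuracy(1:10, (1:10) * 2, rep(TRUE, 10))   # 1
#' bias_slope(1:10, (1:10) * 2, rep(TRUE, 10)) # 0.5
#' @export
accuracy <- function(tbv, ebv, phenotyped = rep(TRUE, length(tbv))) {
  check_metric_input(tbv, ebv, phenotyped)
  cor(tbv[phenotyped], ebv[phenotyped])
}

#' @rdname accuracy
#' @export
bias_slope <- function(tbv, ebv, phenotyped = rep(TRUE, length(tbv))) {
  check_metric_input(tbv, ebv, phenotyped)
  t1 <- tbv[phenotyped]; e1 <- ebv[phenotyped]
  sum((t1 - mean(t1)) * (e1 - mean(e1))) / sum((e1 - mean(e1))^2)
}

check_metric_input <- function(tbv, ebv, phenotyped) {
  stopifnot(length(tbv) == length(ebv), length(phenotyped) == length(tbv))
  if (sum(phenotyped) < 2)
    abort("need at least two phenotyped animals", class = "groupbv_degenerate")
  if (var(tbv[phenotyped]) == 0 || var(ebv[phenotyped]) == 0)
    abort("zero variance in breeding values", class = "groupbv_degenerate")
  invisible(TRUE)
}

#' Accuracy/bias of a fit against a simulated population
#'
#' @param pop the simulated `groupbv_pop` the fit was computed from.
#' @param fit a `groupbv_fit`.
#' @return one-row tibble `accuracy, bias`.
#' @export
prediction_metrics <- function(pop, fit) {
  tb <- true_bv(pop) %>% left_join(ebv(fit), by = "animal")
  tibble(accuracy = accuracy(tb$tbv, tb$ebv, tb$phenotyped),
         bias = bias_slope(tb$tbv, tb$ebv, tb$phenotyped))
}

#' Replicate simulation experiment
#'
#' Runs the full pipeline per replicate - simulate, allocate, attrite,
#' aggregate, fit each requested model by REML (or BLUP at the true
#' simulated variances), compute accuracy and bias - and summarises across
#' replicates. Replicate r uses seed `seed + r`, making runs reproducible
#' from the configuration alone. Replicates where a fit fails or does not
#' converge are excluded from the summaries and counted.
#'
#' @param config a [sim_config()].
#' @param models character vector of model codes (`"ALP"`, `"AL"`, `"AP"`,
#'   `"A"`).
#' @param levels character vector, subset of `c("group", "individual")`.
#' @param variance_mode `"estimated"` (AI-REML per replicate) or `"true"`
#'   (BLUP at the simulated variances).
#' @param n_rep number of replicates.
#' @param seed base seed.
#' @param control a [reml_control()].
#' @return object of class `groupbv_replicates`: list with `summary`
#'   (per scenario/model/level means and SDs over replicates), `replicates`
#'   (per-replicate metrics and estimates) and `n_failed`.
#' @export
run_replicates <- function(config, models = "ALP",
                           levels = c("group", "individual"),
                           variance_mode = c("estimated", "true"),
                           n_rep = 10, seed = 1,
                           control = reml_control()) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(n_rep >= 1)
  truevc <- config_vc(config)
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    pop <- simulate_population(config, seed = seed + r)
    designs <- list()
    if ("individual" %in% levels)
      designs$individual <- individual_design(records(pop), pop$pedigree)
    if ("group" %in% levels) {
      rec <- records(pop)
      groups <- split(seq_len(nrow(rec)), rec$pen)
      designs$group <- aggregate_design(
        designs$individual %||% individual_design(rec, pop$pedigree),
        grouping_matrix(groups, nrow(rec)))
    }
    for (lv in levels) for (md in models) {
      res <- tryCatch({
        fit <- if (variance_mode == "true")
          fit_blup(designs[[lv]], varcomp = truevc, model = md,
                   control = control)
        else
          fit_reml(designs[[lv]], model = md, control = control)
        if (!fit$converged) abort("not converged", class = "groupbv_convergence")
        met <- prediction_metrics(pop, fit)
        est <- stats::setNames(fit$varcomp$estimate, fit$varcomp$term)
        pick <- function(nm) if (nm %in% names(est)) est[[nm]] else NA_real_
        tibble(replicate = r, model = md, level = lv,
               accuracy = met$accuracy, bias = met$bias,
               sigma_a2 = pick("sigma_a2"), sigma_l2 = pick("sigma_l2"),
               sigma_c2 = pick("sigma_c2"), sigma_e2 = pick("sigma_e2"),
               loglik = fit$loglik, n_iter = fit$n_iter)
      }, error = function(e) NULL, groupbv_convergence = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L else rows <- c(rows, list(res))
    }
  }
  reps <- bind_rows(rows)
  summary <- reps %>%
    group_by(.data$model, .data$level) %>%
    summarise(across(c("accuracy", "bias", "sigma_a2", "sigma_l2",
                       "sigma_c2", "sigma_e2"),
                     list(mean = ~ mean(.x), sd = ~ sd(.x))),
              n_rep = n(), .groups = "drop")
  structure(list(summary = summary, replicates = reps, n_failed = n_failed,
                 config = config, variance_mode = variance_mode, seed = seed),
            class = "groupbv_replicates")
}

config_vc <- function(config) {
  list(sigma_a2 = config$sigma_a2, sigma_l2 = config$sigma_l2,
       sigma_c2 = config$sigma_c2, sigma_e2 = config$sigma_e2)
}

#' Accuracy as a function of group size
#'
#' Sweeps the designed group size, simulating, predicting breeding values by
#' BLUP at the true simulated variances with the model matching the
#' generating process (litter + pen model for the phenotype with those
#' effects, additive-only otherwise), and recording the mean accuracy from
#' group records; an individual-record reference is computed alongside.
#'
#' @param sizes integer group capacities (e.g. `seq(3, 30, 3)`).
#' @param allocation `"sublitter3"` (three littermates per sub-litter) or
#'   `"random"`.
#' @param with_litter_pen simulate litter and pen effects on the phenotype?
#' @param config template [sim_config()]; size/allocation fields are
#'   overridden per sweep point.
#' @param n_rep replicates per size.
#' @param seed base seed.
#' @return tibble of class `groupbv_sweep`: per size, mean/SD accuracy from
#'   group records and from the individual-record reference.
#' @export
group_size_sweep <- function(sizes, allocation = c("sublitter3", "random"),
                             with_litter_pen = TRUE, config = sim_config(),
                             n_rep = 10, seed = 1) {
  allocation <- match.arg(allocation)
  model <- if (with_litter_pen) "ALP" else "A"
  out <- purrr::map(sizes, function(sz) {
    cfg <- sim_config(
      n_sires = config$n_sires, n_dams_per_sire = config$n_dams_per_sire,
      litter_size = config$litter_size, n_generations = config$n_generations,
      n_pheno_generations = config$n_pheno_generations,
      sigma_a2 = config$sigma_a2, sigma_l2 = config$sigma_l2,
      sigma_c2 = config$sigma_c2,
      sigma_e2 = if (with_litter_pen) config$sigma_e2 else NULL,
      with_litter_pen = with_litter_pen, pen_capacity = sz,
      allocation = allocation, attrition = config$attrition)
    rr <- run_replicates(cfg, models = model, levels = c("group", "individual"),
                         variance_mode = "true", n_rep = n_rep, seed = seed)
    s <- rr$summary
    tibble(size = sz,
           accuracy_group = s$accuracy_mean[s$level == "group"],
           accuracy_group_sd = s$accuracy_sd[s$level == "group"],
           accuracy_individual = s$accuracy_mean[s$level == "individual"],
           accuracy_individual_sd = s$accuracy_sd[s$level == "individual"])
  }) %>% list_rbind()
  class(out) <- c("groupbv_sweep", class(out))
  out
}
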