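#' Simulation configuration
#'
#' Describes a simulated pig breeding population with litter and pen
#' structure. Defaults reproduce the reference design: 30 sires each mated
#' to 20 dams, litters of six test candidates, eight discrete generations
#' with phenotypes in the last five, trait variances
#' (sigma_a2, sigma_l2, sigma_c2, sigma_e2) = (120, 40, 40, 200) for the
#' phenotype with litter and pen effects, pens of 12 formed from random
#' sub-litters of three, and 20% random attrition among non-breeders.
#'
#' @param n_sires sires per generation.
#' @param n_dams_per_sire dams mated to each sire (one parity each).
#' @param litter_size test candidates per litter.
#' @param n_generations number of offspring generations simulated.
#' @param n_pheno_generations trailing generations that receive phenotypes.
#' @param sigma_a2,sigma_l2,sigma_c2,sigma_e2 additive, litter, pen and
#'   residual variances (squared trait units).
#' @param with_litter_pen if `FALSE`, the phenotype is additive + residual
#'   only; unless given explicitly, `sigma_l2` and `sigma_c2` are set to 0
#'   and `sigma_e2` to 280 so that total variance stays 400.
#' @param pen_capacity designed group (pen) size before attrition.
#' @param allocation how litters are placed into pens: `"L_1x6"` (whole
#'   litters), `"L_2x3"` (random sub-litters of three; the base design),
#'   `"L_ran"` (individuals at random), `"sublitter3"` (sub-litters of three
#'   into pens of arbitrary capacity divisible by 3), `"random"`.
#' @param attrition fraction of non-breeding test animals deleted at random.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 30, n_dams_per_sire = 20, litter_size = 6,
                       n_generations = 8, n_pheno_generations = 5,
                       sigma_a2 = 120, sigma_l2 = 40, sigma_c2 = 40,
                       sigma_e2 = NULL, with_litter_pen = TRUE,
                       pen_capacity = 12, allocation = "L_2x3",
                       attrition = 0.2) {
  allocation <- match.arg(allocation,
                          c("L_2x3", "L_1x6", "L_ran", "sublitter3", "random"))
  if (!with_litter_pen) {
    sigma_l2 <- 0
    sigma_c2 <- 0
    if (is.null(sigma_e2)) sigma_e2 <- 280
  }
  if (is.null(sigma_e2)) sigma_e2 <- 200
  cfg <- list(n_sires = n_sires, n_dams_per_sire = n_dams_per_sire,
              litter_size = litter_size, n_generations = n_generations,
              n_pheno_generations = n_pheno_generations,
              sigma_a2 = sigma_a2, sigma_l2 = sigma_l2, sigma_c2 = sigma_c2,
              sigma_e2 = sigma_e2, with_litter_pen = with_litter_pen,
              pen_capacity = pen_capacity, allocation = allocation,
              attrition = attrition)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Named study scenarios
#'
#' Presets for the scenarios examined in the validation study: the base
#' design (`"base"`, litter + pen effects, pens of 12 from sub-litters of
#' three), the phenotype without litter and pen effects
#' (`"no_litter_pen"`, sigma_e2 = 280), whole-litter and random pen
#' structures (`"L_1x6"`, `"L_ran"`), and the low-heritability variants
#' (`"low_h2"`: sigma_e2 = 1000 with litter/pen effects;
#' `"low_h2_no_litter_pen"`: sigma_e2 = 1080 without), both h2 = 0.10.
#'
#' @param name scenario name.
#' @param ... overrides passed on to [sim_config()].
#' @return a [sim_config()].
#' @export
scenario_config <- function(name = c("base", "no_litter_pen", "L_1x6",
                                     "L_ran", "low_h2",
                                     "low_h2_no_litter_pen"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    base = list(),
    no_litter_pen = list(with_litter_pen = FALSE),
    L_1x6 = list(allocation = "L_1x6"),
    L_ran = list(allocation = "L_ran"),
    low_h2 = list(sigma_e2 = 1000),
    low_h2_no_litter_pen = list(with_litter_pen = FALSE, sigma_e2 = 1080))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (any(c(sigma_a2, sigma_l2, sigma_c2, sigma_e2) < 0))
      abort("variances must be non-negative", class = "groupbv_config_error")
    if (attrition < 0 || attrition >= 1)
      abort("attrition must be in [0, 1)", class = "groupbv_config_error")
    if (pen_capacity < 1)
      abort("pen_capacity must be >= 1", class = "groupbv_config_error")
    if (n_pheno_generations > n_generations)
      abort("more phenotyped than simulated generations",
            class = "groupbv_config_error")
    if (allocation == "L_1x6" && pen_capacity %% litter_size != 0)
      abort("L_1x6 needs pen_capacity divisible by litter size",
            class = "groupbv_allocation_error")
    if (allocation %in% c("L_2x3", "sublitter3")) {
      if (litter_size %% 3 != 0 || pen_capacity %% 3 != 0)
        abort("sub-litter allocation needs litter size and capacity divisible by 3",
              class = "groupbv_allocation_error")
    }
    # next generation's parents must be available among current offspring
    per_gen <- n_sires * n_dams_per_sire * litter_size
    if (n_generations > 1 && per_gen < n_sires + n_sires * n_dams_per_sire)
      abort("not enough offspring to supply the next generation's breeders",
            class = "groupbv_config_error")
  })
  invisible(cfg)
}

#' Simulate a pig population with group structure
#'
#' Builds the mating structure (random selection, random mating,
#' non-overlapping generations, one parity), computes inbreeding, draws true
#' breeding values down the pedigree with Mendelian sampling variance
#' 0.5 (1 - (F_s + F_d)/2) sigma_a2, draws litter, pen and residual effects,
#' assigns pens within each phenotyped generation, applies attrition
#' (breeders of the next generation are always kept) and assembles
#' phenotypes for retained animals in the phenotyped generations.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return object of class `groupbv_pop`: list with `pedigree` (a
#'   [pedigree()] tibble) and `animals` (tibble with per-animal generation,
#'   sex, litter, pen, true breeding value `a`, effect realisations,
#'   phenotype `y`, `phenotyped` and `retained` flags), plus the config.
#' @examples
#' pop <- simulate_population(sim_config(n_sires = 2, n_dams_per_sire = 3,
#'                                       n_generations = 3,
#'                                       n_pheno_generations = 2), seed = 1)
#' nrow(records(pop))
#' @export
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  ns <- cfg$n_sires; nd <- cfg$n_dams_per_sire; ls <- cfg$litter_size
  G <- cfg$n_generations

  # --- pedigree / mating structure (independent of phenotypes: random mating)
  n_found <- ns + ns * nd
  per_gen <- ns * nd * ls
  n_tot <- n_found + G * per_gen
  animal <- seq_len(n_tot)
  sire <- integer(n_tot); dam <- integer(n_tot)
  gen <- integer(n_tot); sex <- integer(n_tot)   # 1 = male, 2 = female
  litter <- integer(n_tot)
  sex[seq_len(ns)] <- 1L
  sex[ns + seq_len(ns * nd)] <- 2L
  cur_sires <- seq_len(ns)
  cur_dams <- ns + seq_len(ns * nd)
  breeder <- rep(FALSE, n_tot)
  kept <- rep(TRUE, n_tot)
  pheno_gens <- seq(G - cfg$n_pheno_generations + 1, G)
  off0 <- n_found
  lit0 <- 0L
  for (g in seq_len(G)) {
    dam_of_litter <- sample(cur_dams)            # random mating: shuffle dams
    sire_of_litter <- rep(cur_sires, each = nd)
    idx <- off0 + seq_len(per_gen)
    sire[idx] <- rep(sire_of_litter, each = ls)
    dam[idx] <- rep(dam_of_litter, each = ls)
    litter[idx] <- lit0 + rep(seq_len(ns * nd), each = ls)
    gen[idx] <- g
    sex[idx] <- sample(rep(1:2, length.out = per_gen))
    # attrition strikes tested generations; breeders are drawn from the
    # survivors, so "all breeding animals were kept" holds and realized
    # group sizes stay binomial with mean capacity * (1 - attrition)
    if (g %in% pheno_gens)
      kept[idx] <- stats::runif(per_gen) >= cfg$attrition
    if (g < G) {
      avail <- idx[kept[idx]]
      males <- avail[sex[avail] == 1L]; females <- avail[sex[avail] == 2L]
      if (length(males) < ns || length(females) < ns * nd)
        abort("too few offspring of one sex to form next generation's breeders",
              class = "groupbv_config_error")
      cur_sires <- sort(sample(males, ns))
      cur_dams <- sort(sample(females, ns * nd))
      breeder[cur_sires] <- TRUE
      breeder[cur_dams] <- TRUE
    }
    off0 <- off0 + per_gen
    lit0 <- lit0 + ns * nd
  }

  ped <- pedigree(tibble(animal = animal, sire = sire, dam = dam,
                         generation = gen))
  # pedigree() preserves input order here (already sorted), but map anyway
  ord <- match(animal, ped$animal)

  # --- true breeding values with Mendelian sampling
  Fv <- ped$F[ord]
  a <- numeric(n_tot)
  founders <- sire == 0 & dam == 0
  a[founders] <- rnorm(sum(founders), 0, sqrt(cfg$sigma_a2))
  for (g in seq_len(G)) {
    idx <- which(gen == g)
    msv <- (0.5 - 0.25 * (Fv[sire[idx]] + Fv[dam[idx]])) * cfg$sigma_a2
    a[idx] <- 0.5 * (a[sire[idx]] + a[dam[idx]]) + rnorm(length(idx), 0, sqrt(msv))
  }

  pheno_gens <- seq(G - cfg$n_pheno_generations + 1, G)
  animals <- tibble(animal = animal, generation = gen, sex = sex,
                    sire = sire, dam = dam, litter = litter,
                    breeder = breeder, a = a,
                    phenotyped = gen %in% pheno_gens)

  # litter effects (phenotyped litters suffice, but draw for all litters)
  n_lit <- max(litter)
  l_eff <- rnorm(n_lit, 0, sqrt(cfg$sigma_l2))
  animals$l_effect <- ifelse(animals$litter > 0, l_eff[pmax(animals$litter, 1)], 0)
  animals$e <- rnorm(n_tot, 0, sqrt(cfg$sigma_e2))
  animals$pen <- NA_integer_
  animals$c_effect <- 0
  animals$retained <- animals$phenotyped & kept

  pop <- structure(list(pedigree = ped, animals = animals, config = cfg),
                   class = "groupbv_pop")
  assign_pens(pop, cfg$allocation, cfg$pen_capacity)
}

#' Assign animals to pens within generations
#'
#' Pens are formed independently within each phenotyped generation. Under
#' `"L_1x6"` whole litters fill a pen (capacity / litter-size litters per
#' pen); under `"L_2x3"`/`"sublitter3"` litters are split at random into
#' sub-litters of three which are shuffled into pens; under
#' `"L_ran"`/`"random"` individuals are shuffled into pens independently of
#' litter. Pen environmental effects are drawn N(0, sigma_c2) per pen and
#' phenotypes recomposed.
#'
#' @param pop a `groupbv_pop`.
#' @param allocation,pen_capacity see [sim_config()].
#' @return the population with `pen`, `c_effect` and `y` updated.
#' @export
assign_pens <- function(pop, allocation = pop$config$allocation,
                        pen_capacity = pop$config$pen_capacity) {
  an <- pop$animals
  cfg <- pop$config
  cfg$allocation <- match.arg(allocation,
                              c("L_2x3", "L_1x6", "L_ran", "sublitter3", "random"))
  cfg$pen_capacity <- pen_capacity
  validate_config(cfg)
  an$pen <- NA_integer_
  pen0 <- 0L
  for (g in sort(unique(an$generation[an$phenotyped]))) {
    idx <- which(an$generation == g & an$phenotyped)
    pens <- switch(cfg$allocation,
      L_1x6 = pens_by_block(idx, an$litter[idx], block = cfg$litter_size,
                            capacity = pen_capacity),
      L_2x3 = ,
      sublitter3 = pens_by_block(idx, an$litter[idx], block = 3,
                                 capacity = pen_capacity),
      L_ran = ,
      random = {
        sh <- sample(idx)
        ceiling(match(idx, sh) / pen_capacity)
      })
    an$pen[idx] <- pen0 + pens
    pen0 <- pen0 + max(pens)
  }
  n_pen <- max(an$pen, na.rm = TRUE)
  c_eff <- rnorm(n_pen, 0, sqrt(cfg$sigma_c2))
  an$c_effect <- ifelse(is.na(an$pen), 0, c_eff[pmax(an$pen, 1L, na.rm = TRUE)])
  pop$animals <- an
  pop$config <- cfg
  compose_phenotypes(pop)
}

# split litters into blocks (whole litters or sub-litters), shuffle blocks,
# fill pens of `capacity` sequentially; returns pen index per element of idx
pens_by_block <- function(idx, lit, block, capacity) {
  ord <- order(lit, stats::runif(length(idx)))   # random within-litter split
  blocks <- ceiling(seq_along(ord) / block)      # block ids along litter order
  bshuf <- sample(max(blocks))
  pen_of_block <- ceiling(order(bshuf)[blocks] / (capacity / block))
  pen <- integer(length(idx))
  pen[ord] <- pen_of_block
  pen
}

#' Random attrition of tested animals
#'
#' Deletes each non-breeding tested animal independently with probability
#' `fraction` (breeders of the next generation are always kept), so realized
#' group sizes follow a binomial distribution with mean capacity x
#' (1 - fraction). Deleted animals stay in the pedigree but lose their
#' phenotype and pen membership.
#'
#' @param pop a `groupbv_pop`.
#' @param fraction deletion probability.
#' @return the population with `retained` and `y` updated.
#' @export
apply_attrition <- function(pop, fraction = pop$config$attrition) {
  if (fraction < 0 || fraction >= 1)
    abort("attrition must be in [0, 1)", class = "groupbv_config_error")
  an <- pop$animals
  an$retained <- an$phenotyped &
    (an$breeder | stats::runif(nrow(an)) >= fraction)
  pop$animals <- an
  pop$config$attrition <- fraction
  compose_phenotypes(pop)
}

compose_phenotypes <- function(pop) {
  an <- pop$animals
  cfg <- pop$config
  on_test <- an$retained & !is.na(an$pen)
  y <- an$a + an$e
  if (cfg$with_litter_pen) y <- y + an$l_effect + an$c_effect
  an$y <- ifelse(on_test, y, NA_real_)
  pop$animals <- an
  pop
}

#' Individual records of a simulated population
#'
#' @param pop a `groupbv_pop`.
#' @return tibble `animal, generation, litter, pen, y` for retained,
#'   phenotyped animals.
#' @export
records <- function(pop) {
  pop$animals %>%
    filter(.data$retained, !is.na(.data$y)) %>%
    select("animal", "generation", "litter", "pen", "y")
}

#' Group (pen-total) records of a simulated population
#'
#' @param pop a `groupbv_pop`.
#' @return tibble `group, total, size, members` (list-column of animal ids).
#' @export
group_records <- function(pop) {
  records(pop) %>%
    group_by(group = .data$pen) %>%
    summarise(total = sum(.data$y), size = n(),
              members = list(.data$animal), .groups = "drop")
}

#' True breeding values
#' @param pop a `groupbv_pop`.
#' @return tibble `animal, tbv, phenotyped` (phenotyped = retained with record).
#' @export
true_bv <- function(pop) {
  pop$animals %>%
    mutate(phenotyped = .data$retained & !is.na(.data$y)) %>%
    select("animal", tbv = "a", "phenotyped")
}

#' @method print groupbv_pop
#' @export
print.groupbv_pop <- function(x, ...) {
  r <- records(x)
  cat(sprintf(paste0("<simulated population: %d animals, %d generations, ",
                     "%d records in %d pens>\n"),
              nrow(x$animals), max(x$animals$generation),
              nrow(r), length(unique(r$pen))))
  invisible(x)
}

#' Write simulated data as CSV files
#'
#' Writes `pedigree.csv` (animal,sire,dam,generation), `records.csv`
#' (animal,generation,litter,pen,y) and `groups.csv`
#' (group,total,size,member_ids semicolon-separated) into `dir`.
#'
#' @param pop a `groupbv_pop`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "pedigree.csv")
  p2 <- file.path(dir, "records.csv")
  p3 <- file.path(dir, "groups.csv")
  write_pedigree(pop$pedigree, p1)
  readr::write_csv(records(pop), p2)
  gr <- group_records(pop) %>%
    mutate(member_ids = purrr::map_chr(.data$members,
                                       ~ paste(.x, collapse = ";"))) %>%
    select("group", "total", "size", "member_ids")
  readr::write_csv(gr, p3)
  invisible(c(p1, p2, p3))
}

#' Read group records written by [write_population()]
#' @param path path to a groups CSV.
#' @return tibble `group, total, size, members` (list-column).
#' @export
read_group_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#") %>%
    mutate(members = purrr::map(strsplit(.data$member_ids, ";"), as.integer)) %>%
    select("group", "total", "size", "members")
}
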