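#' Closed-form variances of a group total
#'
#' For a group (pen) of n_g animals the variance of the pen-total phenotype
#' decomposes into cumulative components: the shared pen effect contributes
#' quadratically, n_g^2 sigma_c2; litters contribute the sum of squared
#' within-group litter counts times sigma_l2; the additive part is sigma_a2
#' times the sum of all elements of the relationship submatrix of the
#' members; independent residuals contribute linearly, n_g sigma_e2. The
#' quadratic-versus-linear contrast between pen and residual contributions is
#' what makes pen effects estimable from totals once group sizes vary.
#'
#' @param n_g group size.
#' @param sigma_c2 pen variance.
#' @return variance of the cumulative effect for the group.
#' @examples
#' pen_var_group(12, 40)              # 5760
#' litter_var_group(rep(3, 4), 40)    # 1440
#' residual_var_group(12, 200)        # 2400
#' @export
pen_var_group <- function(n_g, sigma_c2) {
  stopifnot(n_g >= 1, sigma_c2 >= 0)
  n_g^2 * sigma_c2
}

#' @rdname pen_var_group
#' @param litter_counts numbers of littermates per litter present in the
#'   group (must sum to the group size).
#' @param sigma_l2 litter variance.
#' @export
litter_var_group <- function(litter_counts, sigma_l2) {
  stopifnot(all(litter_counts > 0), sigma_l2 >= 0)
  sum(litter_counts^2) * sigma_l2
}

#' @rdname pen_var_group
#' @param A_star relationship submatrix of the group members (see
#'   [relationship_submatrix()] or [fullsib_block_relationship()]).
#' @param sigma_a2 additive genetic variance.
#' @export
additive_var_group <- function(A_star, sigma_a2) {
  stopifnot(isSymmetric(unname(as.matrix(A_star))), sigma_a2 >= 0)
  sum(A_star) * sigma_a2
}

#' @rdname pen_var_group
#' @param sigma_e2 residual variance.
#' @export
residual_var_group <- function(n_g, sigma_e2) {
  stopifnot(n_g >= 1, sigma_e2 >= 0)
  n_g * sigma_e2
}

#' Relationship matrix of unrelated full-sib litters
#'
#' Block-diagonal relationship submatrix for a group composed of full-sib
#' litters whose parents are unrelated and non-inbred: 1 on the diagonal,
#' 0.5 within litters, 0 across litters.
#'
#' @param litter_counts littermates per litter.
#' @return dense symmetric matrix of dimension `sum(litter_counts)`.
#' @export
fullsib_block_relationship <- function(litter_counts) {
  blocks <- lapply(litter_counts, function(k) {
    m <- matrix(0.5, k, k); base::diag(m) <- 1; m
  })
  as.matrix(bdiag(blocks))
}

#' Proportion of additive to total variance at the group level
#'
#' sigma_a*^2 / (sigma_a*^2 + sigma_l*^2 + sigma_c*^2 + sigma_e*^2) for a
#' group of full-sib litters. This is the group-level analogue of
#' heritability and grows with the relatedness of pen mates.
#'
#' @param litter_counts littermates per litter in the group.
#' @param sigma_a2,sigma_l2,sigma_c2,sigma_e2 variance components.
#' @param A_star optional relationship submatrix overriding the unrelated
#'   full-sib default.
#' @return the ratio.
#' @examples
#' group_additive_fraction(rep(3, 4), 120, 40, 40, 200)  # ~0.23
#' group_additive_fraction(rep(6, 2), 120, 40, 40, 200)  # ~0.31
#' group_additive_fraction(rep(3, 4), 120, 0, 0, 280)    # ~0.46
#' @export
group_additive_fraction <- function(litter_counts, sigma_a2, sigma_l2,
                                    sigma_c2, sigma_e2, A_star = NULL) {
  if (is.null(A_star)) A_star <- fullsib_block_relationship(litter_counts)
  n_g <- sum(litter_counts)
  va <- additive_var_group(A_star, sigma_a2)
  vl <- litter_var_group(litter_counts, sigma_l2)
  vc <- pen_var_group(n_g, sigma_c2)
  ve <- residual_var_group(n_g, sigma_e2)
  va / (va + vl + vc + ve)
}

#' Expected residual variance under a misspecified group model
#'
#' When litter and/or pen effects act on the phenotype but are dropped from
#' the group model, their cumulative variance is absorbed by the residual.
#' Because the residual weight for a group is its size n_g, the reported
#' per-unit-weight residual estimate is expected to be (for average group
#' composition):
#' * `"M_AL"` (pen ignored):    n_g sigma_c2 + sigma_e2
#' * `"M_AP"` (litter ignored): sum(n_lk^2) sigma_l2 / n_g + sigma_e2
#' * `"M_A"` (both ignored):    sum(n_lk^2) sigma_l2 / n_g + n_g sigma_c2 + sigma_e2
#'
#' Average (non-integer) compositions are accepted.
#'
#' @param model one of `"M_AL"`, `"M_AP"`, `"M_A"` (or without the `M_`
#'   prefix).
#' @param n_g_bar average group size.
#' @param n_litters average number of litters per group.
#' @param n_l_bar average littermates per group.
#' @param sigma_l2,sigma_c2,sigma_e2 simulated variance components.
#' @return expected residual-variance estimate on the per-weight scale.
#' @examples
#' expected_residual_misspecified("M_AL", 9.6, sigma_c2 = 40, sigma_e2 = 200) # 584
#' expected_residual_misspecified("M_AP", 9.6, 4, 2.4, sigma_l2 = 40,
#'                                sigma_e2 = 200)                             # 296
#' @export
expected_residual_misspecified <- function(model, n_g_bar, n_litters = NULL,
                                           n_l_bar = NULL, sigma_l2 = 0,
                                           sigma_c2 = 0, sigma_e2 = 0) {
  model <- toupper(sub("^M_?", "", model))
  if (any(c(n_g_bar, sigma_l2, sigma_c2, sigma_e2) < 0))
    abort("parameters must be non-negative", class = "groupbv_value_error")
  lit_part <- function() {
    if (is.null(n_litters) || is.null(n_l_bar))
      abort("litter composition needed when litter effects are ignored",
            class = "groupbv_value_error")
    n_litters * n_l_bar^2 * sigma_l2 / n_g_bar
  }
  switch(model,
         AL = n_g_bar * sigma_c2 + sigma_e2,
         AP = lit_part() + sigma_e2,
         A = lit_part() + n_g_bar * sigma_c2 + sigma_e2,
         abort("model must be one of M_AL, M_AP, M_A",
               class = "groupbv_value_error"))
}
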