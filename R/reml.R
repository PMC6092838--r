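#' @name fit_reml
#' @title Variance components by average-information REML
#'
#' @description Fits a pedigree animal model, optionally with litter and pen
#' random effects, to individual or group (pen-total) records. Group records
#' carry diagonal residual weights equal to group size. Estimation maximises
#' the restricted likelihood with average-information updates, step-halving
#' and an EM fallback; components are kept above a small positive floor and
#' boundary pinning is flagged rather than failing. First derivatives use
#' exact traces obtained from a Takahashi selected inverse of the sparse
#' Cholesky factor of the mixed-model equations.
#'
#' @param data individual records (`animal, litter, pen, y`) or a
#'   `groupbv_design`; for `level = "group"` the pen is the grouping factor.
#' @param pedigree a [pedigree()] object (ignored when `data` is a design).
#' @param model `"ALP"`, `"AL"`, `"AP"` or `"A"` (optionally prefixed
#'   `M_`): which random terms besides the additive effect are fitted.
#' @param level `"individual"` or `"group"`.
#' @param start optional named starting values
#'   (`sigma_l2`, `sigma_c2`, `sigma_a2`, `sigma_e2`); default is an equal
#'   partition of the empirical phenotypic variance (for group records, the
#'   variance of totals divided by the mean group size).
#' @param reduced_pen absorb the pen variance into the residual through
#'   weights n_g (b n_g + 1) instead of an explicit pen term (group level,
#'   models without `P`); see [reduced_weights()].
#' @param b_ratio pen-to-residual variance ratio b used when `reduced_pen`.
#' @param control a [reml_control()].
#' @return object of class `groupbv_fit`; see [tidy.groupbv_fit()] and
#'   [glance.groupbv_fit()].
#' @export
fit_reml <- function(data, pedigree = NULL, model = "ALP",
                     level = c("individual", "group"), start = NULL,
                     reduced_pen = FALSE, b_ratio = 0,
                     control = reml_control()) {
  design <- as_design(data, pedigree, level)
  fit_core(design, model, start = start, vc_fixed = NULL,
           reduced_pen = reduced_pen, b_ratio = b_ratio, control = control)
}

#' Best linear unbiased prediction at given variances
#'
#' Solves the mixed-model equations once at fixed variance components and
#' returns breeding values for every pedigree animal. At the group level,
#' full sibs within a group that carry no other information receive
#' identical predictions.
#'
#' @inheritParams fit_reml
#' @param varcomp named list/vector of variances (`sigma_a2`, `sigma_e2` and,
#'   as required by `model`, `sigma_l2`, `sigma_c2`).
#' @return a `groupbv_fit` (no standard errors; `n_iter = 0`).
#' @export
fit_blup <- function(data, pedigree = NULL, varcomp, model = "ALP",
                     level = c("individual", "group"),
                     reduced_pen = FALSE, b_ratio = 0,
                     control = reml_control()) {
  design <- as_design(data, pedigree, level)
  fit_core(design, model, vc_fixed = normalize_vc(varcomp),
           reduced_pen = reduced_pen, b_ratio = b_ratio, control = control)
}

#' REML control parameters
#'
#' @param tol_param relative parameter-change convergence tolerance.
#' @param tol_grad tolerance on the norm of the scaled score (gradient times
#'   parameter, per observation).
#' @param max_iter iteration cap.
#' @param floor_frac variance floor as a fraction of the phenotypic variance.
#' @param force fit even when [check_identifiability()] flags confounding.
#' @param verbose print the iteration trajectory.
#' @export
reml_control <- function(tol_param = 1e-6, tol_grad = 1e-4, max_iter = 200,
                         floor_frac = 1e-8, force = FALSE, verbose = FALSE) {
  list(tol_param = tol_param, tol_grad = tol_grad, max_iter = max_iter,
       floor_frac = floor_frac, force = force, verbose = verbose)
}

#' Residual weights of the reduced (pen-absorbed) group model
#'
#' Absorbing the pen effect into the residual of the group model gives
#' per-group residual variance n_g^2 sigma_c2 + n_g sigma_e2 =
#' n_g (b n_g + 1) sigma_e2 with b = sigma_c2 / sigma_e2, i.e. diagonal
#' weights R*_ii = n_gi (b n_gi + 1). With b = 0 this reduces to the plain
#' group-size weights.
#'
#' @param n_g vector of group sizes.
#' @param b pen-to-residual variance ratio (>= 0).
#' @return numeric vector of weights.
#' @examples
#' reduced_weights(c(9, 12), 0)   # 9 12
#' reduced_weights(10, 0.2)       # 30
#' @export
reduced_weights <- function(n_g, b) {
  if (b < 0) abort("b must be non-negative", class = "groupbv_value_error")
  stopifnot(all(n_g > 0))
  n_g * (b * n_g + 1)
}

#' Henderson mixed-model equations
#'
#' Coefficient matrix and right-hand side of the sparse symmetric system
#' whose solution gives GLS fixed-effect estimates and BLUPs:
#' `C = W' (R sigma_e2)^-1 W + blockdiag(0, I/sigma_l2, I/sigma_c2,
#' A^-1/sigma_a2)` (terms as present in `model`), `rhs = W' (R sigma_e2)^-1 y`.
#'
#' @param design a `groupbv_design`.
#' @param varcomp named variances, see [fit_blup()].
#' @param model model code.
#' @param Ainv optional precomputed [ainverse()] of the design's pedigree.
#' @return list with `C` (sparse symmetric), `rhs`, and the block `index`
#'   map.
#' @export
mixed_model_equations <- function(design, varcomp, model = "ALP",
                                  Ainv = NULL) {
  mc <- mme_machine(design, model, Ainv = Ainv)
  vc <- normalize_vc(varcomp)
  th <- theta_from_vc(vc, mc$terms)
  parts <- mme_assemble(mc, th)
  list(C = parts$C, rhs = parts$rhs, index = mc$index)
}

# ---------------------------------------------------------------------------
# internals

parse_model <- function(model) {
  code <- toupper(sub("^M_?", "", model))
  if (!code %in% c("A", "AL", "AP", "ALP"))
    abort("model must be one of A, AL, AP, ALP", class = "groupbv_value_error")
  c("litter"[grepl("L", code)], "pen"[grepl("P", code)], "additive")
}

normalize_vc <- function(vc) {
  vc <- unlist(vc)
  nm <- names(vc)
  nm <- sub("^sigma_([alce])2?$", "\\1", nm)
  map <- c(a = "additive", l = "litter", c = "pen", e = "residual",
           additive = "additive", litter = "litter", pen = "pen",
           residual = "residual")
  if (!all(nm %in% names(map)))
    abort("unrecognised variance component names", class = "groupbv_value_error")
  stats::setNames(as.numeric(vc), unname(map[nm]))
}

theta_from_vc <- function(vc, terms) {
  need <- c(terms, "residual")
  if (!all(need %in% names(vc)))
    abort(paste("missing variance components:",
                paste(setdiff(need, names(vc)), collapse = ", ")),
          class = "groupbv_value_error")
  vc[need]
}

as_design <- function(data, pedigree, level) {
  if (inherits(data, "groupbv_design")) return(data)
  level <- match.arg(level, c("individual", "group"))
  if (inherits(data, "groupbv_pop")) {
    pedigree <- data$pedigree
    data <- records(data)
  }
  ind <- individual_design(data, pedigree)
  if (level == "individual") return(ind)
  groups <- split(seq_len(nrow(data)), data$pen)
  aggregate_design(ind, grouping_matrix(groups, nrow(data)))
}

# static pieces of the MME for one design/model: built once per fit
mme_machine <- function(design, model, Ainv = NULL, weights = NULL) {
  terms <- parse_model(model)
  if (is.null(Ainv)) Ainv <- design$Ainv
  if (is.null(Ainv)) abort("Ainv must be supplied", class = "groupbv_value_error")
  Zs <- list(litter = design$Zl, pen = design$Zc, additive = design$Za)[terms]
  W <- do.call(cbind, c(list(design$X), unname(Zs)))
  R <- if (is.null(weights)) design$R else weights
  rinv <- 1 / R
  p <- ncol(design$X)
  q <- vapply(Zs, ncol, integer(1))
  off <- p + cumsum(c(0, utils::head(q, -1)))
  index <- purrr::map2(off, q, ~ .x + seq_len(.y))
  names(index) <- terms
  WtRiW <- forceSymmetric(crossprod(W, W * rinv))
  list(terms = terms, W = W, Zs = Zs, y = design$y, R = R, rinv = rinv,
       n = length(design$y), p = p, q = q, index = index,
       WtRiW = WtRiW, WtRiy = as.numeric(crossprod(W, design$y * rinv)),
       ytRiy = sum(design$y^2 * rinv), logdetR = sum(log(R)),
       Ainv = Ainv, logdetA = -ainv_logdet(Ainv),
       animals = design$animals, level = design$level)
}

ainv_logdet <- function(Ainv) {
  ch <- Cholesky(forceSymmetric(Ainv), LDL = FALSE, super = FALSE, perm = TRUE)
  L <- as(ch, "sparseMatrix")
  2 * sum(log(Matrix::diag(L)))
}

mme_assemble <- function(mc, theta) {
  se <- theta[["residual"]]
  blocks <- c(list(Diagonal(mc$p, 0)),
              purrr::map(mc$terms, function(tm) {
                if (tm == "additive") mc$Ainv / theta[[tm]]
                else Diagonal(mc$q[[tm]]) / theta[[tm]]
              }))
  C <- forceSymmetric(mc$WtRiW / se + bdiag(blocks))
  list(C = C, rhs = mc$WtRiy / se)
}

# Dense-V evaluator for group-level fits: with a few hundred group totals
# the phenotypic covariance fits in memory, and likelihood, score and
# average information are direct matrix expressions. Returns the same
# quantities as mme_eval (minus the MME solution vector).
dense_evaluator <- function(mc, design) {
  Vlist <- list()
  for (tm in mc$terms) {
    Vlist[[tm]] <- switch(tm,
      litter = as.matrix(Matrix::tcrossprod(design$Zl)),
      pen = as.matrix(Matrix::tcrossprod(design$Zc)),
      additive = {
        chA <- Cholesky(forceSymmetric(mc$Ainv), LDL = FALSE, perm = TRUE)
        as.matrix(design$Za %*% solve(chA, Matrix::t(design$Za)))
      })
  }
  Vlist$residual <- diag(mc$R, nrow = mc$n)
  X <- as.matrix(design$X)
  y <- mc$y
  n <- mc$n
  p <- mc$p
  function(theta, derivs = FALSE) {
    V <- Reduce(`+`, Map(`*`, Vlist[names(theta)], theta))
    cholV <- chol(V)
    Vi <- chol2inv(cholV)
    XVi <- base::crossprod(X, Vi)
    XVX <- XVi %*% X
    P <- Vi - base::t(XVi) %*% solve(XVX, XVi)
    Py <- as.numeric(P %*% y)
    m2ll <- (n - p) * log(2 * pi) + 2 * sum(log(base::diag(cholV))) +
      as.numeric(determinant(XVX)$modulus) + sum(y * Py)
    out <- list(theta = theta, m2ll = m2ll, loglik = -m2ll / 2)
    if (!derivs) return(out)
    k <- length(theta)
    g <- numeric(k); names(g) <- names(theta)
    Fm <- matrix(0, n, k)
    for (j in seq_len(k)) {
      Vj <- Vlist[[names(theta)[j]]]
      Fm[, j] <- Vj %*% Py
      g[j] <- -0.5 * (sum(P * Vj) - sum(Py * Fm[, j]))
    }
    AI <- 0.5 * base::crossprod(Fm, P %*% Fm)
    AI <- (AI + base::t(AI)) / 2
    dimnames(AI) <- list(names(theta), names(theta))
    c(out, list(g = g, AI = AI))
  }
}

# one likelihood (and optionally derivative) evaluation
mme_eval <- function(mc, theta, derivs = FALSE) {
  se <- theta[["residual"]]
  parts <- mme_assemble(mc, theta)
  ch <- Cholesky(parts$C, LDL = FALSE, super = FALSE, perm = TRUE)
  L <- as(ch, "sparseMatrix")
  sol <- as.numeric(solve(ch, parts$rhs))
  logdetC <- 2 * sum(log(Matrix::diag(L)))
  yPy <- (mc$ytRiy - sum(sol * mc$WtRiy)) / se
  m2ll <- (mc$n - mc$p) * log(2 * pi) +
    mc$logdetR + mc$n * log(se) +
    sum(vapply(mc$terms, function(tm) mc$q[[tm]] * log(theta[[tm]]),
               numeric(1))) +
    mc$logdetA + logdetC + yPy
  out <- list(theta = theta, m2ll = m2ll, loglik = -m2ll / 2, sol = sol)
  if (!derivs) return(out)

  # exact traces of G_u^{-1} C^{uu} from the selected inverse of C
  perm <- ch@perm + 1L
  pos <- integer(length(perm)); pos[perm] <- seq_along(perm)
  Sx <- .takahashi_selinv(L@p, L@i, L@x, nrow(L))
  lookup <- function(i, j) {           # symmetric entries of C^{-1}
    pi <- pos[i]; pj <- pos[j]
    qi <- pmax(pi, pj) - 1L; qj <- pmin(pi, pj) - 1L
    .selinv_lookup(L@p, L@i, Sx, qi, qj)
  }
  dg <- lookup(seq_len(nrow(L)), seq_len(nrow(L)))

  ehat <- mc$y - as.numeric(mc$W %*% sol)
  g <- numeric(length(theta)); names(g) <- names(theta)
  trP <- numeric(length(mc$terms)); names(trP) <- mc$terms
  tr_uu <- trP
  for (tm in mc$terms) {
    idx <- mc$index[[tm]]
    u <- sol[idx]
    if (tm == "additive") {
      Al <- as(Matrix::tril(mc$Ainv), "TsparseMatrix")
      mult <- ifelse(Al@i == Al@j, 1, 2)
      tr_uu[tm] <- sum(mult * Al@x * lookup(idx[Al@i + 1L], idx[Al@j + 1L]))
      quad <- sum(u * as.numeric(mc$Ainv %*% u))
    } else {
      tr_uu[tm] <- sum(dg[idx])
      quad <- sum(u^2)
    }
    s_u <- theta[[tm]]
    trP[tm] <- (mc$q[[tm]] - tr_uu[tm] / s_u) / s_u
    g[tm] <- -0.5 * (trP[tm] - quad / s_u^2)
  }
  quad_e <- sum(ehat^2 * mc$rinv) / se^2
  trPR <- (mc$n - mc$p -
           sum(vapply(mc$terms, function(tm) theta[[tm]] * trP[tm],
                      numeric(1)))) / se
  g["residual"] <- -0.5 * (trPR - quad_e)

  # average information from working variates f_u = Z_u u / s_u, f_e = e / s_e
  Fm <- vapply(mc$terms, function(tm) {
    as.numeric(mc$Zs[[tm]] %*% sol[mc$index[[tm]]]) / theta[[tm]]
  }, numeric(mc$n))
  Fm <- cbind(Fm, residual = ehat / se)
  Sf <- solve(ch, crossprod(mc$W, Fm * mc$rinv) / se)
  PF <- (Fm - as.matrix(mc$W %*% Sf)) * mc$rinv / se
  AI <- 0.5 * base::crossprod(Fm, PF)
  AI <- (AI + base::t(AI)) / 2
  dimnames(AI) <- list(names(theta), names(theta))

  c(out, list(g = g, AI = AI, tr_uu = tr_uu, ehat = ehat, quad_e = quad_e))
}

fit_core <- function(design, model, start = NULL, vc_fixed = NULL,
                     reduced_pen = FALSE, b_ratio = 0,
                     control = reml_control()) {
  terms <- parse_model(model)
  if (reduced_pen) {
    if ("pen" %in% terms)
      abort("reduced_pen replaces the explicit pen term; use model AL or A",
            class = "groupbv_value_error")
    if (design$level != "group")
      abort("reduced_pen applies to group records", class = "groupbv_value_error")
  }
  if (design$level == "group" && !control$force) {
    flags <- check_identifiability(design)
    if ("pen" %in% terms && "PEN_RESIDUAL_CONFOUNDED" %in% flags)
      abort("constant group sizes: pen and residual variance are confounded (set control force = TRUE to fit anyway)",
            class = "groupbv_singular")
    if (all(c("litter", "pen") %in% terms) && "LITTER_PEN_CONFOUNDED" %in% flags)
      abort("each pen holds one whole litter: litter and pen variance are confounded (set control force = TRUE to fit anyway)",
            class = "groupbv_singular")
  }
  Ainv <- design$Ainv
  if (is.null(Ainv)) abort("design lacks Ainv; attach with design$Ainv",
                           class = "groupbv_value_error")
  weights <- if (reduced_pen) reduced_weights(design$n_g, b_ratio) else NULL
  mc <- mme_machine(design, model, Ainv = Ainv, weights = weights)

  vp <- if (mc$level == "group") var(mc$y) / mean(design$n_g) else var(mc$y)
  floor_v <- control$floor_frac * vp

  # BLUP at fixed variances: a single solve
  if (!is.null(vc_fixed)) {
    th <- theta_from_vc(vc_fixed, mc$terms)
    ev <- mme_eval(mc, th, derivs = FALSE)
    return(make_fit(mc, ev, se = NULL, n_iter = 0L, converged = TRUE,
                    boundary = character(), model = model,
                    reduced_pen = reduced_pen, b_ratio = b_ratio))
  }

  k <- length(terms) + 1
  theta <- if (!is.null(start)) theta_from_vc(normalize_vc(start), mc$terms) else
    stats::setNames(rep(vp / k, k), c(terms, "residual"))
  theta <- pmax(theta, floor_v)

  # group totals are few: iterate on the dense phenotypic covariance and
  # solve the sparse MME once at convergence; individual records use the
  # sparse MME with Takahashi traces throughout
  dense <- mc$level == "group" && mc$n <= 2000
  evalf <- if (dense) dense_evaluator(mc, design) else
    function(th, derivs = FALSE) mme_eval(mc, th, derivs)
  q_em <- c(vapply(mc$terms, function(tm) mc$q[[tm]], numeric(1)),
            residual = mc$n)

  ev <- evalf(theta, derivs = TRUE)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # active set: a component pinned at the floor with a downhill score is
    # held there and excluded from the update and the convergence norms
    free <- !(ev$theta <= floor_v * (1 + 1e-6) & ev$g < 0)
    delta <- rep(0, length(ev$theta))
    if (any(free)) {
      d_free <- tryCatch(
        solve(ev$AI[free, free, drop = FALSE], ev$g[free]),
        error = function(e) NULL)
      if (is.null(d_free)) delta <- NULL else delta[free] <- d_free
    }
    accepted <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:12) {
        th_new <- ev$theta + step * delta
        if (all(th_new >= floor_v)) {
          trial <- evalf(th_new, derivs = FALSE)
          if (trial$m2ll <= ev$m2ll + 1e-8) { accepted <- TRUE; break }
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # EM step expressed through the score: s+ = s + (2 s^2 / q) g,
      # uphill by construction of EM
      th_new <- pmax(ev$theta + (2 * ev$theta^2 / q_em) * ev$g, floor_v)
    }
    # EM shrinks a vanishing component geometrically without ever reaching
    # zero; snap such components onto the floor and let the active set
    # decide whether they stay there
    th_new[th_new < 1e-4 * vp] <- floor_v
    rel <- max(abs(th_new - ev$theta)[free] /
                 pmax(abs(ev$theta), floor_v)[free], 0)
    ev <- evalf(th_new, derivs = TRUE)
    gnorm <- sqrt(sum((ev$g * ev$theta)[free]^2)) / mc$n
    if (control$verbose)
      message(sprintf("it %3d  -2logL %.6f  rel %.2e  g %.2e  [%s]", iter,
                      ev$m2ll, rel, gnorm,
                      paste(signif(ev$theta, 5), collapse = " ")))
    if (rel < control$tol_param && gnorm < control$tol_grad) {
      converged <- TRUE; break
    }
    if (iter >= control$max_iter) break
  }
  boundary <- names(ev$theta)[ev$theta <= floor_v * (1 + 1e-6)]
  if (!converged)
    warn(sprintf("REML did not converge in %d iterations", iter),
         class = "groupbv_convergence")
  se_vec <- tryCatch(sqrt(base::diag(solve(ev$AI))), error = function(e)
    rep(NA_real_, length(ev$theta)))
  if (is.null(ev$sol)) {
    fin <- mme_eval(mc, ev$theta, derivs = FALSE)
    ev$sol <- fin$sol
  }
  make_fit(mc, ev, se = se_vec, n_iter = iter, converged = converged,
           boundary = boundary, model = model,
           reduced_pen = reduced_pen, b_ratio = b_ratio)
}

make_fit <- function(mc, ev, se, n_iter, converged, boundary, model,
                     reduced_pen = FALSE, b_ratio = 0) {
  labels <- c(litter = "sigma_l2", pen = "sigma_c2", additive = "sigma_a2",
              residual = "sigma_e2")
  vc <- tibble(term = unname(labels[names(ev$theta)]),
               estimate = unname(ev$theta),
               std.error = if (is.null(se)) NA_real_ else unname(se))
  structure(list(
    varcomp = vc,
    ebv = tibble(animal = mc$animals, ebv = ev$sol[mc$index[["additive"]]]),
    fixed = ev$sol[seq_len(mc$p)],
    loglik = ev$loglik,
    n_iter = n_iter, converged = converged, boundary = boundary,
    model = toupper(sub("^M_?", "", model)), level = mc$level,
    reduced_pen = reduced_pen, b_ratio = b_ratio,
    n_obs = mc$n, ai = ev$AI %||% NULL), class = "groupbv_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Breeding values of a fit
#' @param fit a `groupbv_fit`.
#' @return tibble `animal, ebv` covering every pedigree animal.
#' @export
ebv <- function(fit) {
  stopifnot(inherits(fit, "groupbv_fit"))
  fit$ebv
}

#' @method print groupbv_fit
#' @export
print.groupbv_fit <- function(x, ...) {
  cat(sprintf("<%s-level %s fit: logLik %.3f, %d iterations%s%s>\n",
              x$level, paste0("M_", x$model), x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)",
              if (length(x$boundary)) paste0(", at boundary: ",
                                             paste(x$boundary, collapse = ","))
              else ""))
  print(x$varcomp)
  invisible(x)
}
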