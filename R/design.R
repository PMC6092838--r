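#' Individual-level model design
#'
#' Builds the incidence matrices of the individual-record animal model
#' y = X b + Z_l l + Z_c c + Z_a a + e from a records tibble. The fixed part
#' is an overall mean (column of ones); `Z_a` columns are indexed against the
#' full pedigree so that every pedigree animal receives a breeding value.
#'
#' @param data tibble with columns `animal`, `litter`, `pen`, `y`.
#' @param ped a [pedigree()] object.
#' @return object of class `groupbv_design`, level `"individual"`, holding
#'   `y`, `X`, `Zl`, `Zc`, `Za` (sparse), residual weights `R` (all ones) and
#'   level maps for litters, pens and animals.
#' @export
individual_design <- function(data, ped) {
  stopifnot(inherits(ped, "groupbv_ped"))
  data <- as_tibble(data)
  n <- nrow(data)
  ai <- match(data$animal, ped$animal)
  if (anyNA(ai)) abort("record animal missing from pedigree",
                       class = "groupbv_id_error")
  litters <- sort(unique(data$litter))
  pens <- sort(unique(data$pen))
  Zl <- sparseMatrix(i = seq_len(n), j = match(data$litter, litters), x = 1,
                     dims = c(n, length(litters)))
  Zc <- sparseMatrix(i = seq_len(n), j = match(data$pen, pens), x = 1,
                     dims = c(n, length(pens)))
  Za <- sparseMatrix(i = seq_len(n), j = ai, x = 1, dims = c(n, nrow(ped)))
  structure(list(level = "individual", y = data$y,
                 X = Matrix(1, n, 1, sparse = TRUE),
                 Zl = Zl, Zc = Zc, Za = Za, R = rep(1, n),
                 litters = litters, pens = pens, animals = ped$animal,
                 record_animal = data$animal, Ainv = ainverse(ped)),
            class = "groupbv_design")
}

#' Group indicator matrix
#'
#' The transformation matrix with one row per group and one column per
#' record; entry (i, j) is 1 when record j belongs to group i. Premultiplying
#' the individual-level model by this matrix yields the group-record model.
#'
#' @param groups list of integer vectors of record row indices, one per group.
#' @param n_records number of individual records (columns).
#' @return sparse indicator matrix.
#' @export
grouping_matrix <- function(groups, n_records) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    abort("a record belongs to more than one group", class = "groupbv_overlap")
  if (length(members) > 0 && (max(members) > n_records || min(members) < 1))
    abort("group member index out of range", class = "groupbv_id_error")
  sparseMatrix(i = rep(seq_along(groups), lengths(groups)), j = members,
               x = 1, dims = c(length(groups), n_records))
}

#' Aggregate an individual design to the group level
#'
#' Applies the indicator transformation: `y* = T y`, `X* = T X`,
#' `Zl* = T Zl`, `Zc* = T Zc`, `Za* = T Za`, and sets the diagonal residual
#' weights R_ii to the group sizes n_gi (row sums of T). When the pen is the
#' grouping factor, `Zc*` is diagonal with the group size on the diagonal.
#'
#' @param design an individual-level [individual_design()].
#' @param T group indicator matrix from [grouping_matrix()].
#' @return a `groupbv_design` with level `"group"`; keeps group membership
#'   (record animal ids per group) for relationship-submatrix extraction.
#' @export
aggregate_design <- function(design, T) {
  stopifnot(inherits(design, "groupbv_design"), design$level == "individual")
  if (ncol(T) != length(design$y))
    abort("indicator columns must match records", class = "groupbv_dim_error")
  n_g <- as.numeric(rowSums(T))
  Tt <- as(T, "TsparseMatrix")
  members <- split(design$record_animal[Tt@j + 1L],
                   factor(Tt@i + 1L, levels = seq_len(nrow(T))))
  structure(list(level = "group", y = as.numeric(T %*% design$y),
                 X = T %*% design$X, Zl = T %*% design$Zl,
                 Zc = T %*% design$Zc, Za = T %*% design$Za,
                 R = n_g, n_g = n_g,
                 litters = design$litters, pens = design$pens,
                 animals = design$animals, members = members,
                 Ainv = design$Ainv),
            class = "groupbv_design")
}

#' Group design straight from a simulated population
#'
#' Convenience wrapper: builds the individual design from [records()] and
#' aggregates by pen (pen = group).
#'
#' @param pop a `groupbv_pop` or a records tibble.
#' @param ped pedigree (taken from `pop` when omitted).
#' @return a group-level `groupbv_design`.
#' @export
group_design <- function(pop, ped = NULL) {
  if (inherits(pop, "groupbv_pop")) {
    ped <- pop$pedigree
    data <- records(pop)
  } else data <- as_tibble(pop)
  ind <- individual_design(data, ped)
  groups <- split(seq_len(nrow(data)), data$pen)
  aggregate_design(ind, grouping_matrix(groups, nrow(data)))
}

#' Identifiability diagnostics for a group design
#'
#' Two confounding patterns make variance components inseparable from group
#' totals: (1) constant group size, where the pen covariance `Zc* Zc*'`
#' equals n_g times the residual weight matrix, so pen and residual variance
#' cannot be separated; (2) each pen holding exactly one whole litter, where
#' `Zl* Zl*' = Zc* Zc*'`, so litter and pen variance cannot be separated.
#'
#' @param design a group-level `groupbv_design`.
#' @return character vector of flags, possibly empty: any of
#'   `"PEN_RESIDUAL_CONFOUNDED"`, `"LITTER_PEN_CONFOUNDED"`.
#' @export
check_identifiability <- function(design) {
  stopifnot(inherits(design, "groupbv_design"), design$level == "group")
  flags <- character()
  ZcZc <- Matrix::tcrossprod(design$Zc)
  Rm <- Diagonal(x = design$n_g)
  if (length(unique(design$n_g)) == 1 &&
      isTRUE(all(abs(ZcZc - design$n_g[1] * Rm) < 1e-10)))
    flags <- c(flags, "PEN_RESIDUAL_CONFOUNDED")
  ZlZl <- Matrix::tcrossprod(design$Zl)
  if (isTRUE(max(abs(ZlZl - ZcZc)) < 1e-10))
    flags <- c(flags, "LITTER_PEN_CONFOUNDED")
  flags
}
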