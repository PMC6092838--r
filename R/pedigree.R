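#' Validate and topologically sort a pedigree
#'
#' Takes a data frame of animal/sire/dam triplets and returns a validated
#' pedigree tibble sorted so that parents always precede their offspring.
#' Unknown parents are coded as 0 (or `NA`). Animal ids may be arbitrary
#' positive integers; internally they are densified to consecutive indices
#' (columns `si`, `di` hold the 1-based row positions of sire and dam,
#' 0 for unknown).
#'
#' @param x data frame with columns `animal`, `sire`, `dam` and optionally
#'   `generation`.
#' @return A tibble of class `groupbv_ped` with columns `animal`, `sire`,
#'   `dam`, `generation`, `si`, `di`, `F` (inbreeding coefficient).
#' @examples
#' ped <- pedigree(data.frame(animal = c(3, 1, 2), sire = c(1, 0, 0),
#'                            dam = c(2, 0, 0)))
#' ped$animal # founders first
#' @export
pedigree <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("animal", "sire", "dam") %in% names(x)))
  x$sire[is.na(x$sire)] <- 0
  x$dam[is.na(x$dam)] <- 0
  if (any(x$animal <= 0)) abort("animal ids must be positive", class = "groupbv_id_error")
  if (anyDuplicated(x$animal)) abort("duplicated animal ids", class = "groupbv_id_error")
  known <- c(0, x$animal)
  missing_par <- setdiff(c(x$sire, x$dam), known)
  if (length(missing_par) > 0) {
    abort(paste0("parent ids absent from pedigree: ",
                 paste(utils::head(missing_par, 5), collapse = ", ")),
          class = "groupbv_missing_parent")
  }
  if (any(x$sire == x$animal | x$dam == x$animal)) {
    abort("animal recorded as its own parent", class = "groupbv_cycle")
  }

  n <- nrow(x)
  pos <- match(x$animal, x$animal)
  si <- match(x$sire, x$animal, nomatch = 0L)
  di <- match(x$dam, x$animal, nomatch = 0L)

  # longest-path depth; a pass that resolves nothing flags a cycle
  depth <- rep(NA_integer_, n)
  depth[si == 0 & di == 0] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    ds <- ifelse(si[todo] == 0, -1L, depth[si[todo]])
    dd <- ifelse(di[todo] == 0, -1L, depth[di[todo]])
    ready <- !is.na(ds) & !is.na(dd)
    if (!any(ready)) abort("pedigree contains a cycle", class = "groupbv_cycle")
    depth[todo[ready]] <- pmax(ds[ready], dd[ready], na.rm = FALSE) + 1L
  }

  ord <- order(depth, seq_len(n))
  x <- x[ord, ]
  x$si <- match(x$sire, x$animal, nomatch = 0L)
  x$di <- match(x$dam, x$animal, nomatch = 0L)
  if (!"generation" %in% names(x)) x$generation <- depth[ord]
  x$F <- as.numeric(.ml_inbreeding(x$si, x$di))
  class(x) <- c("groupbv_ped", class(x))
  x
}

#' Inbreeding coefficients
#'
#' Meuwissen-Luo recursion on the Cholesky decomposition of the numerator
#' relationship matrix; exact for arbitrary (acyclic) pedigrees. Founders
#' have F = 0; the diagonal of A is 1 + F.
#'
#' @param ped a [pedigree()] object.
#' @return numeric vector of inbreeding coefficients, pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "groupbv_ped"))
  ped$F
}

# Mendelian sampling variance scale d_i given parent inbreeding
mendelian_scale <- function(si, di, F) {
  ifelse(si > 0 & di > 0, 0.5 - 0.25 * (F[pmax(si, 1)] + F[pmax(di, 1)]),
  ifelse(si > 0, 0.75 - 0.25 * F[pmax(si, 1)],
  ifelse(di > 0, 0.75 - 0.25 * F[pmax(di, 1)], 1)))
}

#' Inverse of the numerator relationship matrix
#'
#' Direct sparse assembly by Henderson's rules with inbreeding accounted for:
#' each animal contributes at most nine entries, scaled by the inverse of its
#' Mendelian sampling variance 0.5 - 0.25 (F_s + F_d).
#'
#' @param ped a [pedigree()] object.
#' @return sparse symmetric matrix (`dsCMatrix`), dimension = number of animals.
#' @export
ainverse <- function(ped) {
  stopifnot(inherits(ped, "groupbv_ped"))
  n <- nrow(ped)
  si <- ped$si; di <- ped$di
  alpha <- 1 / mendelian_scale(si, di, ped$F)
  i <- seq_len(n)

  ii <- c(i, si, di, i, i, si, di, si, di)
  jj <- c(i, i, i, si, di, si, di, di, si)
  xx <- c(alpha, -alpha / 2, -alpha / 2, -alpha / 2, -alpha / 2,
          alpha / 4, alpha / 4, alpha / 4, alpha / 4)
  keep <- ii > 0 & jj > 0
  M <- sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep], dims = c(n, n))
  forceSymmetric(drop0(M), uplo = "L")
}

# Lower-triangular (I - P) with -0.5 at parent links, from A = (I-P)^-1 D (I-P)^-T
ped_tmat <- function(ped) {
  n <- nrow(ped)
  i <- seq_len(n)
  ii <- c(i, i[ped$si > 0], i[ped$di > 0])
  jj <- c(i, ped$si[ped$si > 0], ped$di[ped$di > 0])
  xx <- c(rep(1, n), rep(-0.5, sum(ped$si > 0)), rep(-0.5, sum(ped$di > 0)))
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Relationship submatrix for a set of animals
#'
#' Returns the dense block of the numerator relationship matrix A for the
#' requested animals, computed by sparse triangular solves against the
#' pedigree decomposition A = (I-P)^-1 D (I-P)^-T, so the full dense A is
#' never formed. Diagonal equals 1 + F.
#'
#' @param ped a [pedigree()] object.
#' @param ids animal ids (original labels).
#' @return dense symmetric matrix with dimnames = ids.
#' @export
relationship_submatrix <- function(ped, ids) {
  stopifnot(inherits(ped, "groupbv_ped"))
  idx <- match(ids, ped$animal)
  if (anyNA(idx)) abort("unknown animal id", class = "groupbv_id_error")
  n <- nrow(ped)
  Tm <- ped_tmat(ped)
  E <- sparseMatrix(i = idx, j = seq_along(idx), x = 1, dims = c(n, length(idx)))
  X <- solve(Matrix::t(Tm), E)                    # (I-P)^-T E
  d <- mendelian_scale(ped$si, ped$di, ped$F)
  A <- as.matrix(Matrix::crossprod(X, d * X))
  A <- (A + base::t(A)) / 2
  dimnames(A) <- list(ids, ids)
  A
}

#' Read / write pedigree CSV
#'
#' CSV columns `animal,sire,dam,generation`, header required, 0 = unknown
#' parent.
#'
#' @param path file path.
#' @return [read_pedigree()] returns a [pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  pedigree(readr::read_csv(path, show_col_types = FALSE, comment = "#"))
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_csv(ped[, c("animal", "sire", "dam", "generation")], path)
  invisible(path)
}

#' @method print groupbv_ped
#' @export
print.groupbv_ped <- function(x, ...) {
  cat(sprintf("<pedigree: %d animals, %d founders, mean F = %.4f>\n",
              nrow(x), sum(x$si == 0 & x$di == 0), mean(x$F)))
  NextMethod()
}
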