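#' Tidy a REML/BLUP fit
#'
#' One row per variance component with estimate and (for REML fits)
#' asymptotic standard error from the inverse average-information matrix.
#'
#' @param x a `groupbv_fit`.
#' @param ... unused.
#' @return tibble `term, estimate, std.error`.
#' @export
tidy.groupbv_fit <- function(x, ...) x$varcomp

#' @rdname tidy.groupbv_fit
#' @export
glance.groupbv_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_obs = x$n_obs, model = x$model, level = x$level,
         boundary = paste(x$boundary, collapse = ","))
}

#' @rdname tidy.groupbv_fit
#' @export
augment.groupbv_fit <- function(x, ...) x$ebv

#' @export
tidy.groupbv_replicates <- function(x, ...) x$summary

#' @export
glance.groupbv_replicates <- function(x, ...) {
  tibble(n_rep = max(x$replicates$replicate), n_failed = x$n_failed,
         variance_mode = x$variance_mode, seed = x$seed)
}

#' @method print groupbv_replicates
#' @export
print.groupbv_replicates <- function(x, ...) {
  cat(sprintf("<replicate experiment: %s variances, %d fits, %d failed>\n",
              x$variance_mode, nrow(x$replicates), x$n_failed))
  print(x$summary)
  invisible(x)
}

#' Plot a group-size sweep
#'
#' Mean accuracy of predicted breeding values against designed group size,
#' group records versus the individual-record reference.
#'
#' @param object a `groupbv_sweep` from [group_size_sweep()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.groupbv_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("size", "accuracy_group", "accuracy_individual")],
    -"size", names_to = "records", names_prefix = "accuracy_",
    values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$accuracy,
                                     colour = .data$records)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "designed group size", y = "accuracy of EBV",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate variance-component estimates
#'
#' Boxplots of per-replicate REML estimates by model and level, with the
#' simulated values overlaid as dashed lines when available.
#'
#' @param object a `groupbv_replicates`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.groupbv_replicates <- function(object, ...) {
  long <- tidyr::pivot_longer(object$replicates,
                              c("sigma_a2", "sigma_l2", "sigma_c2", "sigma_e2"),
                              names_to = "component", values_to = "estimate")
  long <- long[!is.na(long$estimate), ]
  truth <- tibble(component = c("sigma_a2", "sigma_l2", "sigma_c2", "sigma_e2"),
                  value = unlist(config_vc(object$config)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$estimate,
                                     fill = .data$level)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = truth,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::theme_minimal()
}
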