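# Tidy/glance/autoplot methods for the model result objects. Every run
# function returns a `vesiflow_result` carrying a wide trace tibble; tidy()
# pivots it to long observable/value rows, glance() gives a one-row summary,
# autoplot() draws the observables the paper's figures focus on.

#' @export
print.vesiflow_result <- function(x, ...) {
  cat("<vesiflow_result:", x$kind, "> ",
      nrow(x$trace), " trace records, t in [",
      min(x$trace$time), ", ", max(x$trace$time), "] s\n", sep = "")
  invisible(x)
}

#' Tidy a model result into long observable records
#'
#' @param x A `vesiflow_result`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `observable`, `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.vesiflow_result <- function(x, ...) {
  tr <- x$trace
  obs <- setdiff(names(tr), "time")
  out <- lapply(obs, function(o) {
    tibble::tibble(time = tr$time, observable = o, value = tr[[o]])
  })
  do.call(rbind, out)
}

#' One-row summary of a model result
#'
#' @param x A `vesiflow_result`.
#' @param ... Unused.
#' @return One-row tibble with the final observables, step count and the
#'   worst accepted local error of the run.
#' @exportS3Method generics::glance
#' @export
glance.vesiflow_result <- function(x, ...) {
  dg <- diagnostics(x$sim)
  fin <- x$trace[nrow(x$trace), , drop = FALSE]
  names(fin) <- paste0("final_", names(fin))
  names(fin)[1] <- "duration"
  tibble::as_tibble(cbind(kind = x$kind, fin,
                          n_steps = x$sim$step,
                          max_local_rel_err = max(10^dg$eps_local)))
}

#' Plot a model result
#'
#' Draws the observable time courses as line plots, faceted per observable.
#' Model-specific methods highlight the headline observable (phospho-ratio,
#' regional cAMP, pit counts, permeability).
#'
#' @param object A `vesiflow_result`.
#' @param observables Character vector restricting the panels; `NULL` = all.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vesiflow_result <- function(object, observables = NULL, ...) {
  df <- tidy.vesiflow_result(object)
  if (!is.null(observables)) df <- df[df$observable %in% observables, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.phospho_result <- function(object, ...) {
  autoplot.vesiflow_result(object,
                           observables = c("aqp2_s256_ratio", "pka_activity",
                                           "cAMP", "pde4_ratio")) +
    ggplot2::geom_hline(yintercept = c(0.46, 0.75), linetype = "dashed",
                        colour = "grey50")
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.compartment_result <- function(object, ...) {
  autoplot.vesiflow_result(object,
                           observables = c("cAMP_cytosol", "cAMP_storage",
                                           "fold_ratio"))
}

#' Plot the pit-lifetime histogram of an endocytosis run
#'
#' The distribution is bimodal: the first peak holds abortive pits that
#' never passed the cargo checkpoint, the second pits that matured into
#' vesicles (checkpoint time + maturation).
#'
#' @param result An `endocytosis_result`.
#' @param binwidth Histogram bin width (s).
#' @return A ggplot object.
#' @export
plot_pit_lifetimes <- function(result, binwidth = 2) {
  df <- tibble::tibble(lifetime = result$lifetimes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lifetime)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = result$params$pit$t_cp,
                        linetype = "dashed") +
    ggplot2::labs(x = "pit lifetime (s)", y = "count")
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.full_result <- function(object, ...) {
  autoplot.vesiflow_result(object,
                           observables = c("permeability", "cAMP_cytosol",
                                           "cAMP_storage", "src_phospho_ratio"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
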