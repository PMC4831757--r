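# broom-style accessors and plots for result objects

#' @export
print.rp_divergence <- function(x, ...) {
  r <- x$results
  cat(
    "Divergence test (", x$assay, "): ", nrow(r), " pairs, ",
    sum(!is.na(r$p_max)), " tested, ", sum(r$significant), " significant at FDR ",
    x$fdr, " (", x$n_resamples, " resamples)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.rp_te <- function(x, ...) {
  r <- x$results
  cat(
    "Translation-efficiency test: ", nrow(r), " pairs, ",
    sum(!is.na(r$p_max)), " tested, ", sum(r$significant),
    " significant at FDR ", x$fdr, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.rp_rrt <- function(x, ...) {
  r <- x$results
  cat(
    "Ribosome residence time: ", length(unique(r$codon)), " codons x ",
    max(r$position), " positions (", x$n_perm, " permutations)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a divergence, TE or RRT result
#'
#' @param x An `rp_divergence`, `rp_te` or `rp_rrt` object.
#' @param ... Unused.
#' @return The per-gene (or per codon-position) results tibble.
#' @exportS3Method generics::tidy
tidy.rp_divergence <- function(x, ...) x$results

#' @rdname tidy.rp_divergence
#' @exportS3Method generics::tidy
tidy.rp_te <- function(x, ...) x$results

#' @rdname tidy.rp_divergence
#' @exportS3Method generics::tidy
tidy.rp_rrt <- function(x, ...) x$results

#' One-row summaries of result objects
#'
#' @param x An `rp_divergence`, `rp_te` or `rp_rrt` object.
#' @param ... Unused.
#' @return A one-row tibble of counts and settings.
#' @exportS3Method generics::glance
glance.rp_divergence <- function(x, ...) {
  r <- x$results
  tibble(
    assay = x$assay, n_pairs = nrow(r), n_tested = sum(!is.na(r$p_max)),
    n_significant = sum(r$significant), fdr = x$fdr,
    n_resamples = x$n_resamples
  )
}

#' @rdname glance.rp_divergence
#' @exportS3Method generics::glance
glance.rp_te <- function(x, ...) {
  r <- x$results
  tibble(
    n_pairs = nrow(r), n_tested = sum(!is.na(r$p_max)),
    n_significant = sum(r$significant), fdr = x$fdr,
    n_resamples = x$n_resamples
  )
}

#' @rdname glance.rp_divergence
#' @exportS3Method generics::glance
glance.rp_rrt <- function(x, ...) {
  r <- x$results
  tibble(
    n_codons = length(unique(r$codon)),
    n_defined = sum(!is.na(r$rrt)) %/% max(r$position),
    median_windows = stats::median(unique(r[, c("codon", "n_windows")])$n_windows),
    n_perm = x$n_perm
  )
}

#' Volcano plot of a divergence or TE test
#'
#' @param object An `rp_divergence` or `rp_te` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rp_divergence <- function(object, ...) {
  r <- object$results %>% filter(!is.na(.data$p_max))
  ggplot2::ggplot(r, ggplot2::aes(
    x = .data$log2_mean, y = -log10(.data$p_max),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "observed log2(Y/B)", y = "-log10 max P",
      title = paste0(object$assay, " divergence")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rp_divergence
#' @exportS3Method ggplot2::autoplot
autoplot.rp_te <- function(object, ...) {
  r <- object$results %>% filter(!is.na(.data$p_max))
  ggplot2::ggplot(r, ggplot2::aes(
    x = .data$te_log2, y = -log10(.data$p_max),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 TE(B/Y)", y = "-log10 max P",
      title = "translation-efficiency divergence"
    ) +
    ggplot2::theme_minimal()
}

#' Codon-by-position RRT heat map
#'
#' @param object An `rp_rrt` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rp_rrt <- function(object, ...) {
  r <- object$results %>% filter(!is.na(.data$rrt))
  ggplot2::ggplot(r, ggplot2::aes(
    x = factor(.data$position), y = .data$codon, fill = log2(.data$rrt)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick", mid = "white") +
    ggplot2::labs(
      x = "window position (A/P/E = 6/5/4)", y = NULL,
      fill = "log2 RRT"
    ) +
    ggplot2::theme_minimal()
}
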