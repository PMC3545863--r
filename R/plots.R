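# broom-style accessors and ggplot2 displays for the result objects.

#' @export
tidy.snp_comparison <- function(x, ...) {
  x$pairs
}

#' @export
glance.snp_comparison <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_a, n_b = x$n_b, n_common = x$n_common,
    n_unique_a = x$n_unique_a, n_unique_b = x$n_unique_b,
    min_matches = x$min_matches
  )
}

#' @export
glance.capsi_assembly_stats <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.capsi_run <- function(x, ...) {
  st <- x$manifest$stages
  purrr::map_dfr(names(st), function(nm) {
    vals <- purrr::keep(st[[nm]], ~ is.numeric(.x) && length(.x) == 1)
    tibble::tibble(stage = nm, metric = names(vals), value = unlist(vals))
  })
}

#' @export
glance.capsi_run <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    seed = m$seed,
    n_contigs = m$stages$simulate$n_contigs,
    n_reads = m$stages$simulate$n_reads,
    n_snps_kept = m$stages$snp$n_kept %||% NA_integer_,
    n_ssr_records = m$stages$ssr$n_records %||% NA_integer_
  )
}

#' Plot the contig size-bin distribution of an assembly
#'
#' @param object a `capsi_assembly_stats` from [assembly_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.capsi_assembly_stats <- function(object, ...) {
  bins <- c("<1", "1-2", "2-3", "3-4", "4-5", "5-10", "10-20", ">=20")
  df <- tibble::tibble(
    bin = factor(bins, levels = bins),
    n = c(
      object$n_lt_1kb, object$n_1_2kb, object$n_2_3kb, object$n_3_4kb,
      object$n_4_5kb, object$n_5_10kb, object$n_10_20kb, object$n_ge_20kb
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Contig size (KB)", y = "Contigs",
                  title = "Contig length distribution") +
    ggplot2::theme_minimal()
}

#' Plot common/unique SNP counts of a cross-assembly comparison
#'
#' @param object a `snp_comparison` from [compare_snp_sets()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.snp_comparison <- function(object, ...) {
  df <- tibble::tibble(
    set = factor(c("unique A", "common", "unique B"),
                 levels = c("unique A", "common", "unique B")),
    n = c(object$n_unique_a, object$n_common, object$n_unique_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "SNPs", title = "Cross-assembly SNP comparison") +
    ggplot2::theme_minimal()
}

#' Plot canonical SSR motif class frequencies
#'
#' @param ssrs perfect-SSR tibble from [find_ssrs()].
#' @param top show the `top` most frequent classes (default 12).
#' @return a ggplot.
#' @export
plot_ssr_classes <- function(ssrs, top = 12) {
  df <- ssrs |>
    dplyr::count(.data$canonical_class, sort = TRUE) |>
    dplyr::slice_head(n = top)
  df$canonical_class <- factor(df$canonical_class, levels = rev(df$canonical_class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$canonical_class)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "SSRs", y = "Motif class",
                  title = "Most frequent SSR motif classes") +
    ggplot2::theme_minimal()
}
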