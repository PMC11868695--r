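# Figures: the bubble-matrix view of MAG fractions (how universal a gene
# is within each phylum at each depth), and depth-profile views of gene
# and lipid abundances drawn the oceanographic way (depth on a reversed
# vertical axis).

#' Bubble-matrix plot of MAG fractions
#'
#' Circle size is the number of MAGs of a taxon binned at a sample; fill is
#' the fraction of those MAGs that carry the gene family.
#'
#' @param fractions A tibble from [mag_fraction_matrix()].
#' @return A ggplot object.
#' @export
plot_mag_fractions <- function(fractions) {
  check_columns(fractions, c("family", "taxon", "sample", "n_mags",
                             "fraction"), "fraction matrix")
  df <- fractions %>%
    mutate(sample = factor(.data$sample, levels = sample_order(.data$sample)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$taxon)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_mags,
                                     fill = .data$fraction),
                        shape = 21, colour = "grey30") +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "sample (depth, m)", y = NULL,
                  size = "MAGs", fill = "fraction with gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Depth profiles of taxon-by-gene normalized depth
#'
#' @param profiles A tibble from [profile_by_taxon_gene()].
#' @return A ggplot object with depth on a reversed vertical axis.
#' @export
plot_taxon_profiles <- function(profiles) {
  check_columns(profiles, c("taxon", "family", "sample", "value"),
                "profiles")
  df <- profiles %>%
    mutate(depth_m = suppressWarnings(as.numeric(.data$sample)))
  if (anyNA(df$depth_m)) {
    df$depth_m <- as.numeric(factor(df$sample,
                                    levels = sample_order(df$sample)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$depth_m,
                                   colour = .data$taxon)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = "summed normalized depth (reads/bp per 1e8 mapped reads)",
                  y = "depth (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Depth profiles of lipid responses
#'
#' @param lipid_profiles A tibble from [quantify_lipids()] (optionally with
#'   `rel_abund`).
#' @param what `"response"` (default) or `"rel_abund"`.
#' @return A ggplot object.
#' @export
plot_lipid_profiles <- function(lipid_profiles,
                                what = c("response", "rel_abund")) {
  what <- match.arg(what)
  check_columns(lipid_profiles, c("lipid", "sample", what), "lipid profiles")
  df <- lipid_profiles %>%
    mutate(depth_m = suppressWarnings(as.numeric(.data$sample)))
  if (anyNA(df$depth_m)) {
    df$depth_m <- as.numeric(factor(df$sample,
                                    levels = sample_order(df$sample)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[what]], y = .data$depth_m,
                                   colour = .data$lipid)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = if (what == "response") "response units per litre"
                  else "relative abundance",
                  y = "depth (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mag_fractions
#' @param object A `tetra_attribution` result.
#' @param ... Unused.
#' @export
autoplot.tetra_attribution <- function(object, ...) {
  plot_mag_fractions(object$mag_fractions)
}
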