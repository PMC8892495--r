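#' Plot an excision-product length distribution
#'
#' Percent of total reads versus excision-product length.
#'
#' @param ld An `xr_length_distribution`.
#' @return A `ggplot` object.
#' @export
plot_length_distribution <- function(ld) {
  stopifnot(inherits(ld, "xr_length_distribution"))
  df <- data.frame(length_nt = as.integer(names(ld$fraction)),
                   percent = 100 * as.numeric(ld$fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_nt, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = df$length_nt) +
    ggplot2::labs(x = "Excision product length (nt)",
                  y = "Percent of total reads") +
    ggplot2::theme_classic()
}

#' Plot a per-position nucleotide frequency matrix
#'
#' Relative frequency of each nucleotide at each read position, 5' end at
#' position 1.
#'
#' @param pfm An `xr_pfm`.
#' @return A `ggplot` object.
#' @export
plot_pfm <- function(pfm) {
  stopifnot(inherits(pfm, "xr_pfm"))
  df <- data.frame(position = rep(seq_len(pfm$L), each = 4),
                   base = rep(rownames(pfm$matrix), pfm$L),
                   frequency = as.numeric(pfm$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(A = "#2ca02c", C = "#1f77b4",
                                            G = "#ff7f0e", T = "#d62728")) +
    ggplot2::labs(x = "Position (nt, 5' end = 1)",
                  y = "Relative frequency", colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot a unit-gene TS/NTS meta-profile
#'
#' TS in blue, NTS in red, over the 150-bin unit-gene axis (2-kb flanks of
#' 25 bins each around 100 gene-body bins).
#'
#' @param profile An `xr_unit_gene_profile`.
#' @return A `ggplot` object.
#' @export
plot_unit_gene_profile <- function(profile) {
  stopifnot(inherits(profile, "xr_unit_gene_profile"))
  df <- data.frame(bin = rep(1:150, 2),
                   rpkm = c(profile$ts, profile$nts),
                   strand = rep(c("TS", "NTS"), each = 150))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$rpkm,
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(25.5, 125.5), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(TS = "#1f77b4", NTS = "#d62728")) +
    ggplot2::scale_x_continuous(
      breaks = c(1, 25.5, 75, 125.5, 150),
      labels = c("-2 kb", "TSS", "gene body", "TES", "+2 kb")) +
    ggplot2::labs(x = NULL, y = "Mean RPKM per bin", colour = NULL) +
    ggplot2::theme_classic()
}

#' Overlay expected damage-site density under a repair meta-profile
#'
#' @param profile An `xr_unit_gene_profile`.
#' @param density An `xr_site_density_profile`.
#' @return A `ggplot` object with repair on the left axis and site density
#'   (rescaled) on the right.
#' @export
plot_landscape_overlay <- function(profile, density) {
  stopifnot(inherits(profile, "xr_unit_gene_profile"),
            inherits(density, "xr_site_density_profile"))
  dens <- (density$ts + density$nts) / 2
  scale <- max(c(profile$ts, profile$nts), na.rm = TRUE) /
    max(dens, na.rm = TRUE)
  df <- data.frame(bin = rep(1:150, 3),
                   value = c(profile$ts, profile$nts, dens * scale),
                   track = rep(c("TS repair", "NTS repair", "expected sites"),
                               each = 150))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                   colour = .data$track,
                                   linetype = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`TS repair` = "#1f77b4",
                                            `NTS repair` = "#d62728",
                                            `expected sites` = "grey40")) +
    ggplot2::scale_linetype_manual(values = c(`TS repair` = "solid",
                                              `NTS repair` = "solid",
                                              `expected sites` = "dashed")) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "Motif sites per bp")) +
    ggplot2::labs(x = "Unit-gene bin", y = "Mean RPKM per bin",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_classic()
}
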