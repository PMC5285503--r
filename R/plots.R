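# ggplot2 views of pipeline products.

#' Domain-architecture diagram
#'
#' One horizontal track per protein: a thin backbone line spanning the
#' sequence and colored boxes for the retained features (domains and TM
#' helices).
#'
#' @param features Assembled feature tibble ([assemble_architectures()]).
#' @param proteins Optional protein record tibble (draws full-length
#'   backbones).
#' @return A ggplot object.
#' @export
plot_architecture <- function(features, proteins = NULL) {
  ids <- unique(features$protein_id)
  ypos <- setNames(seq_along(ids), ids)
  f <- features |>
    mutate(y = ypos[.data$protein_id])
  p <- ggplot(f)
  if (!is.null(proteins)) {
    bb <- proteins |>
      filter(.data$id %in% ids) |>
      transmute(y = ypos[.data$id], xend = .data$length)
    p <- p + geom_segment(data = bb,
                          aes(x = 1, xend = .data$xend,
                              y = .data$y, yend = .data$y),
                          linewidth = 0.3, colour = "grey50")
  }
  p +
    geom_rect(aes(xmin = .data$start, xmax = .data$end,
                  ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                  fill = .data$family)) +
    ggplot2::scale_y_continuous(breaks = unname(ypos), labels = ids) +
    labs(x = "residue position", y = NULL, fill = "feature") +
    theme_minimal()
}

#' @export
autoplot.hhk_result <- function(object, ...) {
  plot_architecture(object$features, object$proteins)
}

#' @export
autoplot.hhk_census <- function(object, ...) {
  ggplot(object$counts, aes(x = .data$label, y = .data$n)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~proteome) +
    labs(x = NULL, y = "proteins") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.hhk_diagnosis <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$ref_pos), y = 1, fill = .data$status)) +
    geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      conserved = "#1b7837", similar = "#a6dba0",
      mismatch = "#c2a5cf", gap = "grey80")) +
    labs(x = "reference position", y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.hhk_profile <- function(object, ...) {
  td <- tidy(object) |>
    tidyr::pivot_longer(cols = dplyr::all_of(AA_LETTERS),
                        names_to = "residue", values_to = "bits") |>
    group_by(.data$column) |>
    summarise(max_bits = max(.data$bits))
  ggplot(td, aes(x = .data$column, y = .data$max_bits)) +
    geom_line(colour = "steelblue") +
    labs(x = "match column", y = "best score (bits)",
         title = object$family) +
    theme_minimal()
}
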