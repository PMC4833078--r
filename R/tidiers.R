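#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an annotation run
#'
#' One row per accepted protein with evidence flags and functional calls
#' unpacked into columns.
#'
#' @param x An `annotation_run` (see [run_annotate()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.annotation_run <- function(x, ...) {
  ann <- x$annotation
  if (nrow(ann) == 0) {
    return(tibble(species = character(0), protein_id = character(0),
                  family = character(0)))
  }
  func <- purrr::map_dfr(ann$functional, function(f) {
    if (length(f) == 0) return(tibble(.rows = 1))
    tibble::as_tibble_row(as.list(f))
  })
  dplyr::bind_cols(ann %>% select(-"functional"), func) %>%
    arrange(.data$species, .data$family, .data$protein_id)
}

#' Summarise an annotation run
#'
#' @param x An `annotation_run`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of annotated proteins, families,
#'   species, rejected candidates, collapsed haplotypes and family trees.
#' @export
glance.annotation_run <- function(x, ...) {
  tibble(n_annotated = nrow(x$annotation),
         n_families = length(unique(x$annotation$family)),
         n_species = length(unique(x$annotation$species)),
         n_rejected = nrow(x$rejected),
         n_collapsed = nrow(x$collapse_report),
         n_trees = length(x$trees))
}

#' Heatmap of an immunity-gene copy-number matrix
#'
#' @param cnm Copy-number tibble from [copy_number_matrix()].
#' @return A ggplot object (species rows, family columns, counts as tile
#'   labels).
#' @export
plot_copy_number <- function(cnm) {
  long <- tidyr::pivot_longer(cnm, -"species", names_to = "family",
                              values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$species,
                                     fill = .data$count)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "Gene family", y = "Species", fill = "Copies") +
    ggplot2::theme_minimal()
}

#' @rdname plot_copy_number
#' @param object An `annotation_run`.
#' @param ... Unused.
#' @export
autoplot.annotation_run <- function(object, ...) {
  plot_copy_number(object$copy_number)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-protein domain-architecture diagram
#'
#' Draws planted or detected spans (domains, motifs, TM, clusters) along
#' each protein for a small set of proteins.
#'
#' @param hits Tibble with `protein_id`, a span label column
#'   (`domain`/`motif_id`/`feature`), `start`, `end`.
#' @param lengths Optional named vector of protein lengths.
#' @return A ggplot object.
#' @export
plot_architecture <- function(hits, lengths = NULL) {
  lab_col <- intersect(c("domain", "motif_id", "feature"), names(hits))[1]
  hits <- dplyr::rename(hits, label = !!lab_col)
  p <- ggplot2::ggplot(hits) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$protein_id,
                                       yend = .data$protein_id,
                                       color = .data$label),
                          linewidth = 4) +
    ggplot2::labs(x = "Residue", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(lengths)) {
    base <- tibble(protein_id = names(lengths), len = unname(lengths))
    p <- p + ggplot2::geom_segment(
      data = base, ggplot2::aes(x = 1, xend = .data$len,
                                y = .data$protein_id,
                                yend = .data$protein_id),
      linewidth = 0.4, color = "grey60")
  }
  p
}
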