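#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a semi-directed network into an edge tibble
#'
#' @param x a [semidirected_network()].
#' @param ... unused.
#' @return A tibble with one row per edge: `from`, `to`, `directed`
#'   (reticulation edges), and endpoint labels (`NA` for internal
#'   vertices).
#' @method tidy semidirected_network
#' @export
tidy.semidirected_network <- function(x, ...) {
  tibble(
    from = x$edges[, 1L],
    to = x$edges[, 2L],
    directed = x$directed,
    from_label = x$labels[x$edges[, 1L]],
    to_label = x$labels[x$edges[, 2L]]
  )
}

#' @rdname tidy.semidirected_network
#' @method glance semidirected_network
#' @export
glance.semidirected_network <- function(x, ...) validate_network(x)

#' Tidy a 4-leaf pair verdict
#'
#' @param x a `pair_verdict4` object.
#' @param ... unused.
#' @return A two-row tibble, one per containment direction, with the
#'   number of witnessing invariants and an example witness id.
#' @method tidy pair_verdict4
#' @export
tidy.pair_verdict4 <- function(x, ...) {
  tibble(
    direction = c("V1_not_in_V2", "V2_not_in_V1"),
    witnessed = c(length(x$witnesses_12) > 0L, length(x$witnesses_21) > 0L),
    n_witnesses = c(length(x$witnesses_12), length(x$witnesses_21)),
    example_witness = c(x$witnesses_12[1L] %||% NA_character_,
                        x$witnesses_21[1L] %||% NA_character_)
  )
}

#' Tidy a non-containment certificate
#'
#' @param x an `sd_certificate`.
#' @param ... unused.
#' @return A tibble with one row per recursion step: `step`, `kind`,
#'   `n_taxa` and a human-readable `detail`.
#' @method tidy sd_certificate
#' @export
tidy.sd_certificate <- function(x, ...) {
  rows <- list()
  cur <- x
  step <- 1L
  while (!is.null(cur)) {
    detail <- switch(
      cur$kind,
      FOUR_LEAF_WITNESS = paste0("A={", paste(cur$subset, collapse = ","), "} ",
                                 cur$verdict$tags[[1L]], " vs ",
                                 cur$verdict$tags[[2L]], "; witness ",
                                 cur$verdict$witnesses_12[[1L]]),
      CONFLICTING_SPLIT_WITNESS = paste0("representatives {",
                                         paste(cur$subset, collapse = ","), "}"),
      SPLIT_RECURSION = paste0("recurse on side {",
                               paste(cur$side, collapse = ","), "}"),
      SINGLE_CYCLE_CASE = "external single-reticulation theorem",
      ""
    )
    rows[[step]] <- tibble(step = step, kind = cur$kind,
                           n_taxa = length(taxa(cur$net1)), detail = detail)
    cur <- cur$child
    step <- step + 1L
  }
  bind_rows(rows)
}

#' @rdname tidy.sd_certificate
#' @method glance sd_distinguishability
#' @export
glance.sd_distinguishability <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    constraint = x$constraint,
    n_taxa = length(taxa(x$cert_12$net1)),
    r = validate_network(x$cert_12$net1)$r,
    depth_12 = nrow(tidy(x$cert_12)),
    depth_21 = nrow(tidy(x$cert_21))
  )
}

#' Plot a semi-directed network
#'
#' Draws the skeleton with a force-directed layout; reticulation edges
#' are dashed arrows into the reticulation vertex, leaves are labelled.
#'
#' @param object a [semidirected_network()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot semidirected_network
#' @export
autoplot.semidirected_network <- function(object, ...) {
  g <- as_igraph_skeleton(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  ed <- tidy(object)
  df <- tibble(
    x = xy[ed$from, 1L], y = xy[ed$from, 2L],
    xend = xy[ed$to, 1L], yend = xy[ed$to, 2L],
    reticulation = ed$directed
  )
  lab <- tibble(x = xy[, 1L], y = xy[, 2L], label = object$labels)
  lab <- lab[!is.na(lab$label), ]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = df[!df$reticulation, ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend)
    ) +
    ggplot2::geom_segment(
      data = df[df$reticulation, ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linetype = "dashed",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches"))
    ) +
    ggplot2::geom_label(data = lab,
                        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label)) +
    ggplot2::theme_void()
}

#' Plot the leading site-pattern probabilities
#'
#' @param p a tibble from [site_pattern_distribution()].
#' @param top number of most probable patterns to show.
#' @return A ggplot bar chart.
#' @export
plot_site_patterns <- function(p, top = 20L) {
  d <- arrange(p, dplyr::desc(.data$probability))
  d <- head(d, top)
  d$pattern <- factor(d$pattern, levels = rev(d$pattern))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$probability, y = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "probability", y = "site pattern")
}
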