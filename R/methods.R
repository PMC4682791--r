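# broom-style accessors and ggplot2 methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an LFP array into a long tibble
#'
#' @param x An `lfp_array`.
#' @param ... Unused.
#' @return A tibble with columns `electrode`, `depth`, `time`, `lfp` (uV).
#' @export
tidy.lfp_array <- function(x, ...) {
  tibble(
    electrode = rep(x$electrodes$electrode, times = ncol(x$lfp)),
    depth = rep(x$electrodes$z, times = ncol(x$lfp)),
    time = rep(x$time, each = nrow(x$lfp)),
    lfp = as.vector(x$lfp)
  )
}

#' Tidy a LIF simulation into its spike table
#'
#' @param x A `lif_sim`.
#' @param ... Unused.
#' @return The spike tibble (`neuron`, `time`, `population`).
#' @export
tidy.lif_sim <- function(x, ...) x$spikes

#' @export
glance.lif_sim <- function(x, ...) {
  dur <- x$config$duration / 1000
  x$spikes %>%
    group_by(.data$population) %>%
    summarise(n_spikes = n(), .groups = "drop") %>%
    mutate(
      n_neurons = ifelse(.data$population == "exc", x$config$n_exc, x$config$n_inh),
      rate_hz = .data$n_spikes / .data$n_neurons / dur
    )
}

#' Fitted weighted-sum parameters, one row per term
#'
#' @param x A `ws_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.ws_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "tau_ampa", "tau_gaba", "b_ampa", "b_gaba", "offset"),
    estimate = c(x$alpha, x$tau_ampa, x$tau_gaba, x$b_ampa, x$b_gaba, x$offset)
  )
}

#' @export
glance.ws_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, rss = x$rss, n = x$n, k = x$k,
         bic = bic(x$rss, x$n, x$k))
}

#' Summarise proxy scores across depths
#'
#' @param x A `proxy_scores` tibble.
#' @param ... Unused.
#' @return One row per proxy with the mean R^2 and BIC across electrodes and
#'   the mean fitted parameters where applicable.
#' @export
glance.proxy_scores <- function(x, ...) {
  x %>%
    group_by(.data$proxy) %>%
    summarise(
      mean_r_squared = mean(.data$r_squared),
      mean_bic = mean(.data$bic),
      mean_alpha = mean(.data$alpha),
      mean_tau_ampa = mean(.data$tau_ampa),
      mean_lag = mean(.data$lag),
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$mean_r_squared))
}

#' @export
glance.lfp_experiment <- function(x, ...) glance(x$scores)

#' Depth-by-time LFP image
#'
#' @param object An `lfp_array`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lfp_array <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$depth, fill = .data$lfp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "time (ms)", y = "depth (um)", fill = "LFP (uV)") +
    ggplot2::theme_minimal()
}

#' Signed LFP amplitude versus depth
#'
#' @param object A `depth_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$amplitude, .data$depth)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "signed amplitude (uV)", y = "depth (um)") +
    ggplot2::theme_minimal()
  inv <- attr(object, "inversion_depth")
  if (!is.na(inv)) {
    p <- p + ggplot2::geom_hline(yintercept = inv, linetype = 2, colour = "grey50")
  }
  p
}

#' Variance explained by each proxy across depth
#'
#' @param object A `proxy_scores` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proxy_scores <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$r_squared, .data$depth, colour = .data$proxy)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(R^2), y = "depth (um)", colour = "proxy") +
    ggplot2::theme_minimal()
}

#' Spike raster of a LIF simulation
#'
#' @param sim A `lif_sim`.
#' @param n_show Neurons drawn per population (the most active ones).
#' @param window Optional time window `c(from, to)` (ms).
#' @return A ggplot.
#' @export
plot_raster <- function(sim, n_show = 50, window = NULL) {
  spk <- sim$spikes
  if (!is.null(window)) {
    spk <- filter(spk, .data$time >= window[1], .data$time <= window[2])
  }
  top <- spk %>%
    count(.data$population, .data$neuron, sort = TRUE) %>%
    group_by(.data$population) %>%
    dplyr::slice_head(n = n_show) %>%
    ungroup()
  spk <- dplyr::semi_join(spk, top, by = c("population", "neuron"))
  ggplot2::ggplot(spk, ggplot2::aes(.data$time, factor(.data$neuron),
                                    colour = .data$population)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::scale_colour_manual(values = c(exc = "firebrick", inh = "steelblue")) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Morphology projection plot
#'
#' @param trees A `morph_tree` or list of them.
#' @return A ggplot of the x-z projection.
#' @export
plot_morphology <- function(trees) {
  if (inherits(trees, "morph_tree")) trees <- list(trees)
  segs <- purrr::map_dfr(seq_along(trees), function(i) {
    nd <- trees[[i]]$nodes
    has_par <- nd$parent > 0
    p <- match(nd$parent[has_par], nd$id)
    tibble(cell = i, x = nd$x[has_par], z = nd$z[has_par],
           xend = nd$x[p], zend = nd$z[p],
           type = c("soma", "axon", "basal", "apical")[pmin(nd$type[has_par], 4L)])
  })
  ggplot2::ggplot(segs, ggplot2::aes(.data$x, .data$z, xend = .data$xend,
                                     yend = .data$zend, colour = .data$type)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "z (um)") +
    ggplot2::theme_minimal()
}
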