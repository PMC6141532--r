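#' Plot fitness over generations
#'
#' Best and median survivor fitness per generation for one trial.
#'
#' @param history History tibble from [run_trial()] (or a `voxdev_trial`).
#' @return A ggplot object.
#' @export
plot_fitness_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (inherits(history, "voxdev_trial")) history <- history$history
  surv <- history[history$survived, ]
  agg <- do.call(rbind, lapply(split(surv, surv$generation), function(d)
    data.frame(generation = d$generation[1], best = max(d$fitness),
               median = median(d$fitness))))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best, colour = "best")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median, colour = "median")) +
    ggplot2::labs(x = "generation", y = "fitness (body lengths)",
                  colour = NULL)
}

#' Plot developmental windows along a lineage
#'
#' Morphological (`W_L`) and controller (`W_Phi`) windows and fitness
#' against evolutionary time `T` from the oldest ancestor to the run
#' champion: the canalization trajectory.
#'
#' @param lineage Lineage tibble from [trace_lineage()].
#' @return A ggplot object.
#' @export
plot_lineage_windows <- function(lineage) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- data.frame(T = seq_len(nrow(lineage)) - 1L,
                  W_L = lineage$W_L, W_Phi = lineage$W_Phi,
                  fitness = lineage$fitness)
  long <- rbind(
    data.frame(T = d$T, value = d$W_L, series = "W_L"),
    data.frame(T = d$T, value = d$W_Phi, series = "W_Phi"),
    data.frame(T = d$T, value = d$fitness / max(d$fitness, 1e-12),
               series = "fitness (scaled)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$T, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "evolutionary time T (ancestors)", y = NULL,
                  colour = NULL)
}

#' Plot mutation-robustness walks
#'
#' Median fitness (with min-max band across walks) as a function of the
#' number of accumulated subsystem mutations.
#'
#' @param walk A `voxdev_walk` from [robustness_walk()].
#' @return A ggplot object.
#' @export
plot_walks <- function(walk) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  steps <- seq_len(ncol(walk$fitness)) - 1L
  d <- data.frame(step = steps,
                  med = apply(walk$fitness, 2, median),
                  lo = apply(walk$fitness, 2, min),
                  hi = apply(walk$fitness, 2, max))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$med)) +
    ggplot2::labs(x = sprintf("%s mutations", walk$kind),
                  y = "fitness (body lengths)")
}
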