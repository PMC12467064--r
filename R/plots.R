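# ggplot2 visualizations for the main result types.

#' @export
autoplot.gait_recording <- function(object, seconds = NULL, ...) {
  n <- ncol(object$emg)
  if (!is.null(seconds)) n <- min(n, round(seconds * object$fs))
  idx <- seq_len(n)
  t_s <- (idx - 1) / object$fs
  long <- tidyr::pivot_longer(
    tibble::tibble(t = t_s,
                   BF = object$emg[1, idx], TA = object$emg[2, idx],
                   VL = object$emg[3, idx], SOL = object$emg[4, idx],
                   HA = object$hip_deg[idx], KA = object$knee_deg[idx]),
    -"t", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c(CHANNELS, "HA", "KA"))
  ev <- object$events[object$events$sample <= n, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = tibble::tibble(t = (ev$sample - 1) / object$fs,
                                              type = ev$type),
                        ggplot2::aes(xintercept = .data$t, colour = .data$type),
                        linetype = "dashed", alpha = 0.6) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = "event",
                  title = paste("Synthetic gait recording", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gait_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(title = paste("Training history:", object$spec$name),
                  x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hpo_trace <- function(object, ...) {
  ok <- object$trials[!object$trials$failed, ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$P, y = .data$M,
                                   colour = .data$objective)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_point(data = object$best, shape = 1, size = 6,
                        colour = "black") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = "Bayesian hyperparameter search",
                  x = "P (BiLSTM units)", y = "M (dense units)",
                  colour = "objective") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.timing_report <- function(object, ...) {
  ggplot2::ggplot(object$per_window, ggplot2::aes(x = "", y = .data$ms)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.colour = "red",
                          outlier.shape = 4) +
    ggplot2::labs(title = "Streaming latency per window", x = NULL,
                  y = "processing time [ms]") +
    ggplot2::theme_minimal()
}
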