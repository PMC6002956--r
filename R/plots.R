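# Plot layer: a thin ggplot2 skin over the exported tables. Every figure
# can be regenerated from the CSVs alone; analyses never depend on plots.

cond_colors <- function(config) {
  cols <- vapply(config$conditions,
                 function(cn) if (is.null(cn$color)) "#333333" else cn$color,
                 character(1))
  names(cols) <- vapply(config$conditions, function(cn) cn$name, character(1))
  cols
}

save_plot <- function(p, dir, name, config) {
  ggplot2::ggsave(file.path(dir, name), p,
                  width = config$plot$width, height = config$plot$height,
                  dpi = 120)
  name
}

#' Condition bar plot of daily locomotor activity
#'
#' Mean daily beam crossings per condition with SEM error bars across
#' individuals, the standard headline summary of a DAM experiment.
#'
#' @param summary Data frame from [condition_daily_activity()]'s `summary`.
#' @param colors Named vector mapping condition to colour, or `NULL`.
#' @param ymax Optional upper y-axis limit.
#' @return A ggplot object.
#' @export
plot_condition_activity <- function(summary, colors = NULL, ymax = NULL) {
  p <- ggplot2::ggplot(summary,
         ggplot2::aes(x = .data$condition, y = .data$mean,
                      fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.25) +
    ggplot2::labs(x = NULL, y = "Mean daily activity (counts/day)") +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(colors)) p <- p + ggplot2::scale_fill_manual(values = colors)
  if (!is.null(ymax)) p <- p + ggplot2::coord_cartesian(ylim = c(0, ymax))
  p
}

#' Activity or sleep profile plot
#'
#' Mean per-bin values per condition with a SEM ribbon, over the experiment
#' or the folded 24-h LD axis.
#'
#' @param profile Long data frame from [activity_profile()] or
#'   [sleep_profile()] (columns `condition`, `bin_start`, `mean`, `sem`).
#' @param colors Named condition colour vector or `NULL`.
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, colors = NULL, ylab = "Activity (counts/bin)") {
  p <- ggplot2::ggplot(profile,
         ggplot2::aes(x = .data$bin_start, y = .data$mean,
                      colour = .data$condition, group = .data$condition)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem,
                   fill = .data$condition), alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time", y = ylab, colour = NULL, fill = NULL) +
    ggplot2::theme_classic()
  if (!is.null(colors)) {
    p <- p + ggplot2::scale_colour_manual(values = colors) +
      ggplot2::scale_fill_manual(values = colors)
  }
  p
}

#' Mean periodogram plot
#'
#' @param agg Data frame from [aggregate_periodogram()].
#' @param sig Optional data frame with `period_h`, `S` for the significance
#'   line.
#' @return A ggplot object.
#' @export
plot_periodogram <- function(agg, sig = NULL) {
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$period_h,
                                         y = .data$mean_Q)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Period (h)", y = "Chi-square Q") +
    ggplot2::theme_classic()
  if (!is.null(sig)) {
    p <- p + ggplot2::geom_line(
      data = sig, ggplot2::aes(y = .data$S), linetype = "dashed")
  }
  p
}

#' Actogram tile plot
#'
#' @param acto_long Long actogram table (`day`, `bin_h`, `value`).
#' @return A ggplot object.
#' @export
plot_actogram <- function(acto_long) {
  ggplot2::ggplot(acto_long,
    ggplot2::aes(x = .data$bin_h, y = .data$day, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(sort(unique(acto_long$day)))) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 na.value = "grey90") +
    ggplot2::labs(x = "Hours since light onset", y = NULL,
                  fill = "Counts") +
    ggplot2::theme_minimal()
}

# writes the standard figure set; returns the file names written
write_plots <- function(out_dir, config, fd, prof, sprof, pgs, acto,
                        do_ld, do_dd) {
  written <- character(0)
  cols <- cond_colors(config)
  ymax <- config$plot$ymax
  if (do_ld) {
    s <- condition_daily_activity(fd, "LD")$summary
    written <- c(written, save_plot(
      plot_condition_activity(s, cols, ymax), out_dir,
      "daily_activity_LD.png", config))
  }
  if (do_dd) {
    s <- condition_daily_activity(fd, "DD")$summary
    written <- c(written, save_plot(
      plot_condition_activity(s, cols, ymax), out_dir,
      "daily_activity_DD.png", config))
  }
  full <- prof[prof$mode == "full_experiment", , drop = FALSE]
  full$bin_start <- as.POSIXct(full$bin_start, tz = "UTC")
  written <- c(written, save_plot(plot_profile(full, cols), out_dir,
                                  "activity_profile.png", config))
  sp <- sprof
  sp$bin_start <- as.POSIXct(sp$bin_start, tz = "UTC")
  written <- c(written, save_plot(
    plot_profile(sp, cols, ylab = "Sleep fraction"), out_dir,
    "sleep_profile.png", config))
  if (!is.null(pgs) && length(pgs) > 0L) {
    rhythmic <- filter_arrhythmic(
      pgs, config$periodogram$strength_threshold)$rhythmic
    if (length(rhythmic) > 0L) {
      agg <- aggregate_periodogram(rhythmic)
      sig <- rhythmic[[1L]]$table[, c("period_h", "S")]
      written <- c(written, save_plot(plot_periodogram(agg, sig), out_dir,
                                      "mean_periodogram.png", config))
    }
  }
  if (!is.null(acto)) {
    written <- c(written, save_plot(plot_actogram(acto), out_dir,
                                    "actogram_mean.png", config))
  }
  written
}
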