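#' Bland-Altman plot of healthy-vs-diseased RBF
#'
#' Per-subject difference (healthy minus diseased) against the pair mean,
#' with the mean difference (solid) and the 1.96-SD limits of agreement
#' (dotted, population SD). Subjects without a diseased side are omitted.
#'
#' @param pc a [paired_comparison()].
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pc) {
  stopifnot(inherits(pc, "paired_comparison"))
  sel <- pc$diseased_side != "none"
  d <- pc[sel, ]
  healthy <- ifelse(d$diseased_side == "left", d$right, d$left)
  diseased <- ifelse(d$diseased_side == "left", d$left, d$right)
  df <- data.frame(mean = (healthy + diseased) / 2, diff = healthy - diseased)
  ba <- bland_altman(df$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = ba$mean_diff) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Pair mean RBF (ml/100 g/min)",
                  y = "Healthy - diseased RBF (ml/100 g/min)",
                  title = sprintf("%s: mean difference %.0f, LoA [%.0f, %.0f]",
                                  pc$method[1], ba$mean_diff, ba$loa_low,
                                  ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' Left/right RBF ratio plot across methods
#'
#' One point per subject and method; a subject with two healthy kidneys sits
#' near ratio 1, unilateral hypoperfusion below it.
#'
#' @param comparisons named list of [paired_comparison()] objects.
#' @return a ggplot object.
#' @export
plot_lr_ratios <- function(comparisons) {
  df <- do.call(rbind, lapply(comparisons, function(pc)
    data.frame(subject = factor(pc$subject), method = pc$method,
               ratio = unname(lr_ratio(pc, digits = NULL)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$ratio,
                                   colour = .data$method,
                                   shape = .data$method)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Subject", y = "Cortical RBF ratio (left / right)") +
    ggplot2::theme_minimal()
}
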