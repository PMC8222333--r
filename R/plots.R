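#' @include specificity.R selection.R responseFits.R
NULL

#' Information-content motif logo of an energy matrix
#'
#' Converts penalties to per-position Boltzmann base probabilities via
#' [matrixToPwm()], scales letter heights by position information content
#' (2 - Shannon entropy, in bits) and stacks them, most probable base on
#' top.  Letters are drawn as scaled text, which keeps the figure a plain
#' ggplot object.
#'
#' @param matrix an [EnergyMatrix-class]
#' @param temperatureScale passed to [matrixToPwm()]
#' @return a ggplot object
#' @export
plotEnergyLogo <- function(matrix, temperatureScale = 1) {
  p <- matrixToPwm(matrix, temperatureScale)
  P <- ncol(p)
  labels <- positionLabels(matrix)
  dfs <- lapply(seq_len(P), function(j) {
    pj <- p[, j]
    pj[is.na(pj)] <- 0
    ent <- -sum(ifelse(pj > 0, pj * log2(pj), 0))
    ic <- max(2 - ent, 0)
    h <- pj * ic
    ord <- order(h)                      # stack small to large
    data.frame(pos = j, base = names(pj)[ord], height = h[ord],
               y0 = cumsum(c(0, h[ord]))[seq_len(4L)])
  })
  df <- do.call(rbind, dfs)
  df <- df[df$height > 1e-3, , drop = FALSE]
  baseCols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  ggplot2::ggplot(df) +
    ggplot2::geom_text(ggplot2::aes(
      x = pos, y = y0 + height / 2, label = base,
      colour = base, size = height), fontface = "bold",
      show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 10)) +
    ggplot2::scale_colour_manual(values = baseCols) +
    ggplot2::scale_x_continuous(breaks = seq_len(P), labels = labels) +
    ggplot2::labs(x = "position", y = "information (bits)") +
    ggplot2::theme_classic()
}

#' Plot mutation enrichment trajectories
#'
#' Frequency of each mutation across selection rounds; the top
#' \code{nLabel} mutations by final-round frequency are coloured and
#' labelled by residue change.
#'
#' @param trajectories DataFrame from [enrichmentTrajectories()]
#' @param nLabel number of top trajectories to highlight (default 5)
#' @return a ggplot object
#' @export
plotTrajectories <- function(trajectories, nLabel = 5L) {
  fm <- trajectories$freqs
  rounds <- as.integer(sub("freq_", "", colnames(fm)))
  ord <- order(-fm[, ncol(fm)])
  lab <- ifelse(seq_len(nrow(fm)) %in% ord[seq_len(min(nLabel, nrow(fm)))],
                ifelse(is.na(trajectories$aaLabel), trajectories$label,
                       trajectories$aaLabel), "other")
  df <- data.frame(
    round = rep(rounds, each = nrow(fm)),
    freq = as.vector(fm),
    mutation = rep(trajectories$label, ncol(fm)),
    highlight = rep(lab, ncol(fm)))
  ggplot2::ggplot(df, ggplot2::aes(x = round, y = freq,
                                   group = mutation,
                                   colour = highlight)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "selection round", y = "mutation frequency",
                  colour = "mutation") +
    ggplot2::theme_classic()
}

#' Plot a dose-response fit with its data
#'
#' @param fit a [DoseResponseFit-class]
#' @param doses,responses the fitted data
#' @return a ggplot object
#' @export
plotDoseResponse <- function(fit, doses, responses) {
  e <- fitEstimates(fit)
  grid <- exp(seq(log(min(doses[doses > 0])), log(max(doses)),
                  length.out = 200))
  curve <- e[["bottom"]] + (e[["top"]] - e[["bottom"]]) /
    (1 + (e[["EC50"]] / grid)^e[["hill"]])
  ggplot2::ggplot() +
    ggplot2::geom_point(ggplot2::aes(x = doses, y = responses)) +
    ggplot2::geom_line(ggplot2::aes(x = grid, y = curve),
                       colour = "#255C99") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response") +
    ggplot2::theme_classic()
}
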