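#' Quantify gel bands against a standard curve
#'
#' Ordinary least-squares line fitted to the standards (known mass loaded vs
#' measured band intensity); unknown band masses are read off the line.
#' Values falling outside the standard mass range are returned but flagged
#' as extrapolated. Typical use: a recombinant-protein dilution series
#' (e.g. 6.25, 12.5, 20 and 50 ng) on the same membrane as the unknowns.
#'
#' @param bandIntensities numeric vector of unknown band intensities.
#' @param standards data.frame with columns \code{intensity} and \code{ng};
#'   at least two standards with distinct intensities.
#' @return data.frame: \code{intensity}, \code{ng}, \code{extrapolated};
#'   attributes \code{slope}, \code{intercept}, \code{r.squared}.
#' @examples
#' std <- data.frame(intensity = c(1, 2), ng = c(10, 20))
#' standardCurveQuantify(1.5, std)$ng  # 15
#' @export
standardCurveQuantify <- function(bandIntensities, standards) {
  if (nrow(standards) < 2L) stop("at least two standards are required")
  if (length(unique(standards$intensity)) < 2L ||
      length(unique(standards$ng)) < 2L)
    stop("degenerate standards: intensities or masses are identical")
  fit <- lm(ng ~ intensity, data = standards)
  ng <- as.numeric(predict(fit, data.frame(intensity = bandIntensities)))
  out <- data.frame(intensity = bandIntensities, ng = ng,
                    extrapolated = ng < min(standards$ng) |
                      ng > max(standards$ng))
  attr(out, "slope") <- unname(coef(fit)[2L])
  attr(out, "intercept") <- unname(coef(fit)[1L])
  attr(out, "r.squared") <- summary(fit)$r.squared
  out
}
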