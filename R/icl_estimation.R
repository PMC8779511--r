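#' Clothing insulation rate from temperature differences
#'
#' Computes the clothing insulation rate, in clo, from the mean skin
#' temperature `Ts`, mean clothes-surface temperature `Tc` and operative
#' temperature `To` (all in degrees C):
#'
#' \deqn{I_{cl} = \frac{1}{0.155\,h} \cdot \frac{T_s - T_c}{T_c - T_o}}
#'
#' where `h` is the human heat-transfer coefficient in W/(m^2 K) and
#' 0.155 m^2 K/W is one clo. A negative result (skin cooler than clothes)
#' is returned as-is: it usually diagnoses bad region localization upstream
#' and clamping it would hide that.
#'
#' @param ts Mean skin temperature, degrees C.
#' @param tc Mean clothes temperature, degrees C.
#' @param to Operative (background) temperature, degrees C.
#' @param h Heat-transfer coefficient, W/(m^2 K); default 8.6.
#' @param epsilon Minimum `|tc - to|` (degrees C); smaller gaps raise an
#'   ill-conditioned error instead of returning a number.
#' @return Clothing insulation rate in clo.
#' @examples
#' compute_icl(34.73, 33.48, 25.58)  # ~0.119 clo, a light T-shirt
#' @export
compute_icl <- function(ts, tc, to, h = 8.6, epsilon = 0.1) {
  stopifnot(is.numeric(ts), is.numeric(tc), is.numeric(to),
            length(ts) == 1L, length(tc) == 1L, length(to) == 1L)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (abs(tc - to) < epsilon) {
    cond <- structure(
      class = c("thermotrack_ill_conditioned", "error", "condition"),
      list(message = sprintf(
        "ill-conditioned Icl: |Tc - To| = %.4f below epsilon = %.4f",
        abs(tc - to), epsilon), call = NULL))
    stop(cond)
  }
  (ts - tc) / (0.155 * h * (tc - to))
}

#' Icl estimate bundled with its inputs
#'
#' @param summary A `thermal_summary` from [summarize_regions()].
#' @param config A [pipeline_config()] supplying `h` and the conditioning
#'   epsilon.
#' @param window_frames Length of the accumulation window, frames.
#' @return A list of class `icl_result` with fields `icl` (clo), `summary`,
#'   `h` and `window_frames`.
#' @export
estimate_icl <- function(summary, config = pipeline_config(),
                         window_frames = config$icl_window_frames) {
  stopifnot(inherits(summary, "thermal_summary"))
  icl <- compute_icl(summary$ts, summary$tc, summary$to,
                     h = config$h_coefficient, epsilon = config$icl_epsilon)
  structure(list(icl = icl, summary = summary, h = config$h_coefficient,
                 window_frames = as.integer(window_frames)),
            class = "icl_result")
}

#' @export
print.icl_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Icl = %.4f clo  (Ts %.2f, Tc %.2f, To %.2f degC; ns %d, nc %d; h %.1f)\n",
    x$icl, s$ts, s$tc, s$to, s$n_skin, s$n_clothes, x$h))
  if (x$icl < 0)
    cat("  note: negative Icl; check region localization upstream\n")
  invisible(x)
}
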