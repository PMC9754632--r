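#' Magnetization context of a tensiometry experiment
#'
#' Bundles the magnetization per unit volume of the nanoparticle-labelled
#' spheroid and the field-gradient magnitude of the permanent magnet. Their
#' product is the volumetric body-force density that flattens the spheroid,
#' playing the role of an enhanced gravity.
#'
#' @param Mv Magnetization per unit volume (A/m). Must be positive; typical
#'   values for labelled C2C12 spheroids are 150-500 A/m.
#' @param gradB Field-gradient magnitude (T/m). Must be positive; 170 T/m for
#'   the reference 6 mm neodymium magnet.
#' @param B Field magnitude (T), informational only. Default `NA`.
#' @return An object of class `magnetic_context` with elements `Mv`, `gradB`,
#'   `B` and the derived force density `f` (N/m^3).
#' @examples
#' ctx <- magnetic_context(Mv = 250, gradB = 170)
#' force_density(ctx)  # 4.25e4 N/m^3
#' @export
magnetic_context <- function(Mv, gradB, B = NA_real_) {
  if (!is.numeric(Mv) || length(Mv) != 1L || !is.finite(Mv) || Mv <= 0)
    stop("invalid magnetic context: Mv must be a single finite positive number (A/m)")
  if (!is.numeric(gradB) || length(gradB) != 1L || !is.finite(gradB) || gradB <= 0)
    stop("invalid magnetic context: gradB must be a single finite positive number (T/m)")
  structure(
    list(Mv = as.numeric(Mv), gradB = as.numeric(gradB), B = as.numeric(B),
         f = as.numeric(Mv) * as.numeric(gradB)),
    class = "magnetic_context"
  )
}

#' Volumetric magnetic force density
#'
#' The body-force density exerted on a magnetically labelled spheroid,
#' `f = Mv * grad(B)` in N/m^3.
#'
#' @param ctx A [magnetic_context()].
#' @return Force density in N/m^3.
#' @examples
#' force_density(magnetic_context(Mv = 500, gradB = 170))  # 8.5e4
#' @export
force_density <- function(ctx) {
  stopifnot(inherits(ctx, "magnetic_context"))
  ctx$f
}

#' @export
print.magnetic_context <- function(x, ...) {
  cat("Magnetic context: Mv =", x$Mv, "A/m, grad(B) =", x$gradB, "T/m",
      if (is.finite(x$B)) paste0("(B = ", x$B, " T)") else "", "\n")
  cat("  force density f = Mv*grad(B) =", format(x$f, digits = 6), "N/m^3\n")
  invisible(x)
}
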