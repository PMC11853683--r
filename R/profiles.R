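# Intracristal ADP profiles, area-based depletion, the quadratic gradient
# law and the Rule of 2.

#' Extract the midline intracristal ADP profile of a crista
#'
#' Samples the steady-state external ADP field along the crista midline,
#' ordered by distance from the CJ opening (for a crista with CJs at both
#' ends, distance from one of them).
#'
#' @param st a `crista_steady`
#' @param crista crista index within the model
#' @return object of class `adp_profile` with fields `x` (um), `adp` (mM),
#'   `ADP0` (concentration at the boundary-adjacent station), `L`
#' @export
adp_profile <- function(st, crista = 1L) {
  stopifnot(inherits(st, "crista_steady"))
  cr <- st$model$cristae[[crista]]
  if (is.null(cr)) stop("adp_profile: no crista ", crista, " in the model",
                        call. = FALSE)
  rk <- matrix(st$ext_rank[cr$midline], nrow = nrow(cr$midline))
  if (any(rk == 0L))
    stop("adp_profile: midline leaves the external domain", call. = FALSE)
  adp <- rowMeans(matrix(st$ADP_e[rk], nrow = nrow(rk)))
  structure(list(x = cr$x, adp = adp, ADP0 = adp[1], L = cr$L,
                 crista = cr$id, cj = cr$cj),
            class = "adp_profile")
}

#' @export
print.adp_profile <- function(x, ...) {
  cat(sprintf("ADP profile, crista %d (%s), L = %g um\n", x$crista, x$cj, x$L))
  cat(sprintf("  ADP0 = %.5f mM; min = %.5f mM; depletion = %.3f\n",
              x$ADP0, min(x$adp), depletion(x)))
  invisible(x)
}

#' @export
plot.adp_profile <- function(x, ...) {
  graphics::plot(x$x, x$adp, type = "l", xlab = "distance from CJ (um)",
                 ylab = "[ADP] (mM)", ...)
  invisible(x)
}

#' Area-based intracristal ADP depletion
#'
#' `1 - (integral of the profile) / (ADP0 * L)`, trapezoid quadrature with
#' flat extension over the half-cells at the profile ends.
#'
#' @param profile an [adp_profile()]
#' @return depletion fraction in `[0, 1)`
#' @export
depletion <- function(profile) {
  stopifnot(inherits(profile, "adp_profile"))
  if (length(profile$x) == 0L) stop("depletion: empty profile", call. = FALSE)
  if (profile$ADP0 <= 0)
    stop("depletion: ADP0 must be > 0", call. = FALSE)
  x <- c(0, profile$x, profile$L)
  y <- c(profile$adp[1], profile$adp, profile$adp[length(profile$adp)])
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  1 - auc / (profile$ADP0 * profile$L)
}

#' Mirror a one-CJ profile into an equivalent two-CJ profile of length 2L
#'
#' By the Rule of 2, the ADP gradient in a crista with a single CJ follows
#' the first half of the gradient in a crista twice as long with CJs at
#' both ends; mirroring makes a one-CJ profile fittable by the quadratic
#' gradient law.
#'
#' @param profile an [adp_profile()]
#' @return an [adp_profile()] of length `2L`
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "adp_profile"))
  structure(list(x = c(profile$x, 2 * profile$L - rev(profile$x)),
                 adp = c(profile$adp, rev(profile$adp)),
                 ADP0 = profile$ADP0, L = 2 * profile$L,
                 crista = profile$crista, cj = "mirrored"),
            class = "adp_profile")
}

#' Fit the quadratic intracristal ADP gradient law
#'
#' Least-squares fit of `ADP(x) = ADP0 - a * x * (L - x)` with `ADP0` fixed
#' from the profile; the steepness is `k = a * L / ADP0` (1/um).
#'
#' @param profile an [adp_profile()] from a both-ends crista (mirror a
#'   one-CJ profile first with [mirror_profile()])
#' @return object of class `quad_fit` with `a` (mM/um^2), `k` (1/um), `R2`
#' @export
fit_quadratic <- function(profile) {
  stopifnot(inherits(profile, "adp_profile"))
  if (length(profile$x) < 4L)
    stop("fit_quadratic: need at least 4 profile points", call. = FALSE)
  w <- profile$x * (profile$L - profile$x)
  z <- profile$ADP0 - profile$adp
  a <- sum(w * z) / sum(w * w)
  pred <- profile$ADP0 - a * w
  ss_res <- sum((profile$adp - pred)^2)
  ss_tot <- sum((profile$adp - mean(profile$adp))^2)
  R2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(a = a, k = a * profile$L / profile$ADP0, R2 = R2,
                 ADP0 = profile$ADP0, L = profile$L),
            class = "quad_fit")
}

#' @export
coef.quad_fit <- function(object, ...) {
  c(a = object$a, k = object$k, R2 = object$R2)
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("Quadratic ADP gradient fit: a = %.4g mM/um^2, k = %.3f /um, R2 = %.5f\n",
              x$a, x$k, x$R2))
  invisible(x)
}

#' Check the Rule of 2 on a pair of profiles
#'
#' Compares the ADP profile of a one-CJ crista of length `L` against the
#' first half of the profile of a both-ends crista of length `2L`, solved
#' under the same cytosolic composition and parameters. Returns the maximum
#' absolute deviation relative to `ADP0`.
#'
#' @param profile_1cj profile of the one-CJ crista (length `L`)
#' @param profile_2cj profile of the both-ends crista (length `2L`)
#' @return maximum relative deviation (fraction of `ADP0`)
#' @export
rule_of_two_check <- function(profile_1cj, profile_2cj) {
  stopifnot(inherits(profile_1cj, "adp_profile"),
            inherits(profile_2cj, "adp_profile"))
  if (abs(profile_2cj$L - 2 * profile_1cj$L) > 0.05 * profile_2cj$L + 1e-9)
    stop("rule_of_two_check: second profile must come from a crista twice as long",
         call. = FALSE)
  on_half <- stats::approx(profile_2cj$x, profile_2cj$adp,
                           xout = profile_1cj$x, rule = 2)$y
  max(abs(profile_1cj$adp - on_half)) / profile_1cj$ADP0
}
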