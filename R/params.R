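#' Bivariate variance-component parameter set
#'
#' Describes the generative architecture of two liability traits. Each
#' trait's liability has unit total variance decomposed into additive-genetic
#' (A), shared-environment (C), dominant-genetic (D) and unique-environment
#' (E) fractions, with A + C + D + E = 1. The cross-trait structure is given
#' by component correlations \code{r_A}, \code{r_C}, \code{r_D}, \code{r_E},
#' each in [-1, 1]. A fitted model family uses at most one of C and D (ACE
#' xor ADE); the simulator accepts both nonzero so that misspecification can
#' be studied.
#'
#' @param A,C,D,E numeric length-2 vectors of variance fractions, one entry
#'   per trait (order: trait 1, trait 2; the canonical application is
#'   asthma then ASD).
#' @param r_A,r_C,r_D,r_E cross-trait correlations of the corresponding
#'   latent components.
#' @param traits character length-2, trait names used in output tables.
#' @return an object of class \code{acde_params}.
#' @export
#' @examples
#' # sibling-design architecture: A = 0.59/0.75, r_A = 0.20
#' acde_params(A = c(0.59, 0.75), C = c(0.04, 0.05), r_A = 0.2, r_C = 0.03,
#'             r_E = -0.14)
acde_params <- function(A = c(0.5, 0.5), C = c(0, 0), D = c(0, 0),
                        E = NULL, r_A = 0, r_C = 0, r_D = 0, r_E = 0,
                        traits = c("asthma", "asd")) {
  A <- rep_len(as.numeric(A), 2)
  C <- rep_len(as.numeric(C), 2)
  D <- rep_len(as.numeric(D), 2)
  if (is.null(E)) E <- 1 - A - C - D else E <- rep_len(as.numeric(E), 2)
  fr <- rbind(A = A, C = C, D = D, E = E)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12)) {
    stop("variance fractions must lie in [0, 1]; got A=", toString(A),
         " C=", toString(C), " D=", toString(D), " E=", toString(E))
  }
  if (any(abs(A + C + D + E - 1) > 1e-12)) {
    stop("A + C + D + E must equal 1 per trait (tolerance 1e-12)")
  }
  if (any(E <= 0)) stop("E must be strictly positive for both traits")
  for (r in c(r_A, r_C, r_D, r_E)) {
    if (!is.finite(r) || abs(r) > 1) stop("component correlations must be in [-1, 1]")
  }
  structure(
    list(A = A, C = C, D = D, E = E,
         r_A = r_A, r_C = r_C, r_D = r_D, r_E = r_E,
         traits = as.character(traits)),
    class = "acde_params"
  )
}

#' @export
print.acde_params <- function(x, ...) {
  cat("Bivariate ACDE parameter set (traits:",
      paste(x$traits, collapse = ", "), ")\n")
  m <- rbind(A = x$A, C = x$C, D = x$D, E = x$E)
  colnames(m) <- x$traits
  print(round(m, 4))
  cat(sprintf("cross-trait: r_A=%.3f r_C=%.3f r_D=%.3f r_E=%.3f\n",
              x$r_A, x$r_C, x$r_D, x$r_E))
  h <- derived_H(x)
  cat(sprintf("broad-sense H: %.3f / %.3f; r_H=%.3f\n",
              h$H[1], h$H[2], h$r_H))
  invisible(x)
}

#' Broad-sense heritability and combined genetic correlation
#'
#' H_t = A_t + D_t per trait, and the correlation of the combined
#' (additive + dominant) genetic factor,
#' r_H = (r_A sqrt(A1 A2) + r_D sqrt(D1 D2)) / sqrt(H1 H2).
#' When D is zero for both traits, r_H reduces to r_A exactly.
#'
#' @param params an \code{\link{acde_params}} object.
#' @return list with \code{H} (length 2) and \code{r_H} (NA when either
#'   H is zero).
#' @export
derived_H <- function(params) {
  H <- params$A + params$D
  r_H <- if (all(H > 0)) {
    (params$r_A * sqrt(params$A[1] * params$A[2]) +
       params$r_D * sqrt(params$D[1] * params$D[2])) / sqrt(H[1] * H[2])
  } else NA_real_
  list(H = H, r_H = r_H)
}

#' Liability thresholds implied by target prevalences
#'
#' Under the liability-threshold model a binary trait is present when a
#' standard-normal liability exceeds a threshold; a target prevalence p
#' implies threshold qnorm(1 - p). Prevalences may differ by sex, as both
#' asthma and ASD are more common in males.
#'
#' @param prev named list or matrix of prevalences. Either a length-2
#'   vector (one prevalence per trait, shared across sexes) or a 2 x 2
#'   matrix with rows = traits and columns = c("female", "male").
#' @param traits trait names (row order of \code{prev}).
#' @return object of class \code{threshold_spec}: a 2 x 2 matrix of
#'   thresholds (traits x sexes) with the prevalence matrix attached.
#' @export
#' @examples
#' # register-like prevalences: asthma ~13% F / 17% M, ASD ~1.1% F / 2.6% M
#' threshold_spec(matrix(c(0.13, 0.17, 0.011, 0.026), nrow = 2,
#'                byrow = TRUE))
threshold_spec <- function(prev, traits = c("asthma", "asd")) {
  if (is.vector(prev)) prev <- cbind(female = prev, male = prev)
  prev <- as.matrix(prev)
  if (!all(dim(prev) == c(2L, 2L))) {
    stop("prev must be a length-2 vector or a 2 x 2 (trait x sex) matrix")
  }
  if (any(prev <= 0) || any(prev >= 1)) {
    stop("prevalences must lie strictly between 0 and 1")
  }
  dimnames(prev) <- list(traits, c("female", "male"))
  thr <- stats::qnorm(1 - prev)
  stopifnot(all(is.finite(thr)))
  structure(thr, prevalence = prev, class = "threshold_spec")
}
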