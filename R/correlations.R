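#' Maximum-likelihood tetrachoric correlation from a 2x2 table
#'
#' Assumes both binary variables arise by thresholding a standard bivariate
#' normal. The 2x2 multinomial is just-identified by (rho, tau1, tau2), so
#' the ML thresholds are the inverse-normal margins and rho solves
#' P(L1 > tau1, L2 > tau2) = p11; the root is found by bisection on the
#' monotone orthant probability. The SE comes from the observed information
#' of the three-parameter multinomial likelihood. Tables whose likelihood is
#' maximized at |rho| = 1 (e.g. an empty discordant diagonal) are returned
#' as +/-1 with \code{boundary = TRUE} rather than clamped silently.
#'
#' @param n11,n10,n01,n00 cell counts: first index is variable 1, second
#'   variable 2; \code{n11} counts pairs positive on both.
#' @return object of class \code{tetrachoric}: list with \code{rho},
#'   \code{tau1}, \code{tau2}, \code{se}, \code{boundary}, \code{n}.
#' @export
#' @examples
#' tetrachoric(40, 10, 20, 30)
tetrachoric <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("empty table")
  p1 <- (n11 + n10) / n
  p2 <- (n11 + n01) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("a margin is zero: one variable is constant, ",
         "tetrachoric correlation undefined")
  }
  tau1 <- stats::qnorm(1 - p1)
  tau2 <- stats::qnorm(1 - p2)
  p11 <- n11 / n
  f <- function(r) pbvn(-tau1, -tau2, r) - p11
  lim <- 1 - 1e-12
  if (f(lim) <= 0) {
    out <- list(rho = 1, tau1 = tau1, tau2 = tau2, se = NA_real_,
                boundary = TRUE, n = n)
  } else if (f(-lim) >= 0) {
    out <- list(rho = -1, tau1 = tau1, tau2 = tau2, se = NA_real_,
                boundary = TRUE, n = n)
  } else {
    rho <- stats::uniroot(f, c(-lim, lim), tol = 1e-12)$root
    se <- tryCatch({
      nll <- function(th) {
        pr <- c(
          quadrant_prob(1, 1, th[2], th[3], th[1]),
          quadrant_prob(1, 0, th[2], th[3], th[1]),
          quadrant_prob(0, 1, th[2], th[3], th[1]),
          quadrant_prob(0, 0, th[2], th[3], th[1])
        )
        -sum(cells * log(pmax(pr, 1e-300)))
      }
      H <- numDeriv::hessian(nll, c(rho, tau1, tau2))
      sqrt(solve(H)[1, 1])
    }, error = function(e) NA_real_)
    out <- list(rho = rho, tau1 = tau1, tau2 = tau2, se = se,
                boundary = FALSE, n = n)
  }
  class(out) <- "tetrachoric"
  out
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf("tetrachoric rho = %.4f (SE %.4f)%s; tau = (%.3f, %.3f), n = %d\n",
              x$rho, x$se, if (x$boundary) " [boundary]" else "",
              x$tau1, x$tau2, x$n))
  invisible(x)
}

#' Maximum-likelihood biserial correlation
#'
#' Latent bivariate-normal model: the continuous variable X is observed
#' directly (mean mu, SD sigma) and the binary variable arises by
#' thresholding the second latent coordinate at tau; rho is the latent
#' correlation. The likelihood factorizes into the normal density of X and
#' the probit conditional P(Y = 1 | X); all four parameters are maximized
#' jointly (rho on the atanh scale) and the SE of rho comes from the
#' observed information with a delta-method back-transform.
#'
#' @param binary 0/1 vector.
#' @param continuous numeric vector, same length.
#' @return list with \code{rho}, \code{se}, \code{tau}, \code{mu},
#'   \code{sigma}, \code{convergence}.
#' @export
biserial <- function(binary, continuous) {
  ok <- !is.na(binary) & !is.na(continuous)
  y <- as.numeric(binary[ok]); x <- as.numeric(continuous[ok])
  if (!all(y %in% c(0, 1))) stop("binary must be 0/1")
  if (length(unique(y)) < 2) stop("binary variable has a single class")
  if (stats::sd(x) == 0) stop("continuous variable is constant")
  n <- length(y)
  mu0 <- mean(x); s0 <- stats::sd(x)
  tau0 <- stats::qnorm(1 - mean(y))
  # two-step moment start: point-biserial rescaled by phi(tau)/(p(1-p))
  p <- mean(y)
  r_pb <- stats::cor(x, y)
  rho0 <- max(-0.99, min(0.99, r_pb * sqrt(p * (1 - p)) / stats::dnorm(tau0)))
  nll <- function(th) {
    mu <- th[1]; sg <- exp(th[2]); tau <- th[3]; rho <- tanh(th[4])
    z <- (x - mu) / sg
    q <- (rho * z - tau) / sqrt(1 - rho^2)
    ll <- sum(stats::dnorm(x, mu, sg, log = TRUE)) +
      sum(stats::pnorm(ifelse(y == 1, q, -q), log.p = TRUE))
    -ll
  }
  opt <- stats::optim(c(mu0, log(s0), tau0, atanh(rho0)), nll,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  rho <- tanh(th[4])
  se <- tryCatch({
    H <- numDeriv::hessian(nll, th)
    v <- solve(H)[4, 4]
    sqrt(v) * (1 - rho^2)  # d tanh / d z
  }, error = function(e) NA_real_)
  list(rho = rho, se = se, tau = th[3], mu = th[1], sigma = exp(th[2]),
       convergence = opt$convergence, n = n)
}

# double-entered 2x2 table of (trait of member 1) x (trait of member 2);
# v1/w1 are the traits of member 1, v2/w2 of member 2
.pooled_table <- function(v1, w2, v2, w1) {
  a <- c(v1, v2)  # "index" trait, both orientations
  b <- c(w2, w1)  # "relative" trait
  c(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
    n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
}

#' Familial correlation set for one pair kind
#'
#' Computes the correlation taxonomy of a classical familial-aggregation
#' table: the phenotypic (within-individual cross-trait) correlation, the
#' intraclass correlation (ICC) of each trait across the pair, and the
#' cross-relative cross-trait (CRCT) correlation (trait 1 in one member
#' against trait 2 in the other, pooled over both orientations). Binary
#' traits use tetrachoric ML; for twins, where the second trait is a
#' continuous score, biserial ML replaces it (and the score ICC is the
#' double-entry Pearson correlation). Pooled-orientation SEs treat entries
#' as independent and are therefore slightly optimistic for double-entered
#' tables.
#'
#' @param registry phenotyped registry.
#' @param pairs relative-pair table.
#' @param kind pair kind.
#' @param use_score if TRUE use the continuous \code{asd_score} (twin
#'   kinds); default automatically for twin kinds when scores are present.
#' @param min_pairs minimum pair count required.
#' @return one-row data frame with estimates and SEs.
#' @export
pair_correlation_set <- function(registry, pairs, kind, use_score = NULL,
                                 min_pairs = 30) {
  pp <- pairs[pairs$kind == kind, , drop = FALSE]
  if (nrow(pp) < min_pairs) {
    stop("only ", nrow(pp), " pairs of kind '", kind,
         "' (minimum ", min_pairs, ")")
  }
  i1 <- match(pp$id_1, registry$id)
  i2 <- match(pp$id_2, registry$id)
  a1 <- registry$asthma[i1]; a2 <- registry$asthma[i2]
  d1 <- registry$asd[i1]; d2 <- registry$asd[i2]
  if (is.null(use_score)) {
    use_score <- kind %in% c("MZ_twin", "DZ_twin") &&
      !all(is.na(registry$asd_score[i1]))
  }
  wrap <- function(tt) c(est = tt$rho, se = tt$se)
  if (use_score) {
    s1 <- registry$asd_score[i1]; s2 <- registry$asd_score[i2]
    ph <- biserial(c(a1, a2), c(s1, s2))
    phen <- c(est = ph$rho, se = ph$se)
    ia <- wrap(do.call(tetrachoric, as.list(.pooled_table(a1, a2, a2, a1))))
    r <- stats::cor(c(s1, s2), c(s2, s1))
    id_ <- c(est = r, se = (1 - r^2) / sqrt(length(s1) * 2))
    cb <- biserial(c(a1, a2), c(s2, s1))
    crct <- c(est = cb$rho, se = cb$se)
    conc <- c(NA_integer_, NA_integer_)
  } else {
    ph <- do.call(tetrachoric,
                  as.list(.pooled_table(c(a1, a2), c(d1, d2),
                                        integer(0), integer(0))))
    phen <- wrap(ph)
    ia <- wrap(do.call(tetrachoric, as.list(.pooled_table(a1, a2, a2, a1))))
    id_ <- wrap(do.call(tetrachoric, as.list(.pooled_table(d1, d2, d2, d1))))
    crct <- wrap(do.call(tetrachoric, as.list(.pooled_table(a1, d2, a2, d1))))
    conc <- c(sum((a1 == 1 & d2 == 1) | (a2 == 1 & d1 == 1)),
              sum(a1 == 1 & d1 == 1 & a2 == 1 & d2 == 1))
  }
  data.frame(
    kind = kind, n_pairs = nrow(pp),
    concordant = conc[1], double_concordant = conc[2],
    phenotypic = phen["est"], phenotypic_se = phen["se"],
    icc_asthma = ia["est"], icc_asthma_se = ia["se"],
    icc_asd = id_["est"], icc_asd_se = id_["se"],
    crct = crct["est"], crct_se = crct["se"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Familial correlation table across pair kinds
#'
#' @param registry phenotyped registry.
#' @param pairs relative-pair table.
#' @param kinds pair kinds to include (default: all present).
#' @param min_pairs minimum pairs per kind.
#' @return data frame, one row per kind.
#' @export
familial_correlation_table <- function(registry, pairs, kinds = NULL,
                                       min_pairs = 30) {
  if (is.null(kinds)) kinds <- intersect(pair_kinds()$kind, unique(pairs$kind))
  do.call(rbind, lapply(kinds, function(k) {
    pair_correlation_set(registry, pairs, k, min_pairs = min_pairs)
  }))
}
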