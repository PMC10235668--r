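#' Implied 4x4 liability correlation structure for a relative pair
#'
#' Two traits per member, ordered (member1 trait1, member1 trait2,
#' member2 trait1, member2 trait2). Diagonal entries are 1; the
#' within-person cross-trait entry is
#' \eqn{r_A\sqrt{A_1A_2} + r_X\sqrt{X_1X_2} + r_E\sqrt{E_1E_2}} (X = C or
#' D), and cross-person entries are weighted by the pair kind's sharing
#' coefficients.
#'
#' @param params an \code{\link{acde_params}}.
#' @param kind a pair kind label or a \code{\link{pair_kind}} list.
#' @param kinds optional \code{\link{pair_kinds}} table with overrides.
#' @return 4x4 correlation matrix; errors if not positive semi-definite.
#' @export
implied_pair_covariance <- function(params, kind, kinds = pair_kinds()) {
  if (is.character(kind)) kind <- pair_kind(kind, kinds)
  S <- matrix(0, 4, 4)
  for (i in 1:2) for (j in 1:2) for (t in 1:2) for (u in 1:2) {
    S[2 * (i - 1) + t, 2 * (j - 1) + u] <-
      .cross_cov(params, if (i == j) 1 else kind$k_A,
                 if (i == j) 1 else kind$k_D,
                 if (i == j) 1 else kind$k_C, t, u, same_person = i == j)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("implied pair correlation matrix for kind '", kind$kind,
         "' is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  }
  S
}

# cross-person (Gamma) and within-person (W) 2x2 trait covariance blocks of
# the exchangeable pair structure [[W, Gamma], [Gamma, W]]
.pair_blocks <- function(params, kind) {
  sq <- function(v, t, u) sqrt(v[t] * v[u])
  G <- W <- matrix(0, 2, 2)
  for (t in 1:2) for (u in 1:2) {
    rA <- if (t == u) 1 else params$r_A
    rC <- if (t == u) 1 else params$r_C
    rD <- if (t == u) 1 else params$r_D
    rE <- if (t == u) 1 else params$r_E
    G[t, u] <- kind$k_A * rA * sq(params$A, t, u) +
      kind$k_D * rD * sq(params$D, t, u) +
      kind$k_C * rC * sq(params$C, t, u)
    W[t, u] <- rA * sq(params$A, t, u) + rD * sq(params$D, t, u) +
      rC * sq(params$C, t, u) + rE * sq(params$E, t, u)
  }
  list(G = G, W = W)
}

#' All 16 binary response-pattern probabilities for a pair kind
#'
#' Exploits the exchangeable structure of a relative pair: conditional on
#' the shared familial factor s ~ N(0, Gamma) (Gamma = cross-person trait
#' covariance), the two members are independent, each with residual
#' covariance W - Gamma. Every pattern probability is then a 2-d
#' Gauss-Hermite integral of products of bivariate-normal quadrant
#' probabilities; the node count adapts to the shared-variance fraction
#' (peakier integrands for MZ-like sharing) keeping absolute accuracy
#' better than 1e-6.
#'
#' @param params \code{\link{acde_params}}.
#' @param thresholds length-2 numeric, per-trait liability thresholds.
#' @param kind pair kind label.
#' @param kinds optional sharing-coefficient table.
#' @return data frame with columns \code{y1_1}, \code{y2_1}, \code{y1_2},
#'   \code{y2_2}, \code{p} (16 rows summing to 1).
#' @export
pattern_probs_binary <- function(params, thresholds, kind,
                                 kinds = pair_kinds()) {
  kk <- pair_kind(kind, kinds)
  bl <- .pair_blocks(params, kk)
  R <- bl$W - bl$G
  eg <- eigen(bl$G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("residual within-person covariance not PSD for kind '", kind, "'")
  }
  n_gh <- if (max(lam) <= 0.45) 24L else if (max(lam) <= 0.65) 48L else 96L
  gh <- .gh_rules[[as.character(n_gh)]]
  keep <- lam > 1e-12
  if (sum(keep) == 2) {
    nodes <- as.matrix(expand.grid(gh$x, gh$x))
    wts <- as.vector(outer(gh$w, gh$w))
    S <- nodes %*% (t(eg$vectors) * sqrt(lam))
  } else if (sum(keep) == 1) {
    wts <- gh$w
    S <- cbind(gh$x) %*% t(eg$vectors[, keep, drop = FALSE] * sqrt(lam[keep]))
  } else {
    S <- matrix(0, 1, 2)
    wts <- 1
  }
  v1 <- R[1, 1]; v2 <- R[2, 2]
  rho_e <- R[1, 2] / sqrt(v1 * v2)
  t1 <- (thresholds[1] - S[, 1]) / sqrt(v1)
  t2 <- (thresholds[2] - S[, 2]) / sqrt(v2)
  # member-conditional probabilities for the 4 single-member patterns
  pm <- vapply(1:4, function(j) {
    y1 <- (j - 1) %% 2; y2 <- (j - 1) %/% 2
    quadrant_prob(y1, y2, t1, t2, rho_e)
  }, numeric(length(wts)))
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1)
  g <- expand.grid(y1_1 = 0:1, y2_1 = 0:1, y1_2 = 0:1, y2_2 = 0:1)
  g$p <- vapply(seq_len(16), function(r) {
    j1 <- 1L + g$y1_1[r] + 2L * g$y2_1[r]
    j2 <- 1L + g$y1_2[r] + 2L * g$y2_2[r]
    sum(wts * pm[, j1] * pm[, j2])
  }, numeric(1))
  g
}

#' Log-likelihood of binary response patterns for relative pairs
#'
#' For a pair with two binary traits per member, each observed response
#' pattern's probability is the 4-dimensional normal rectangle probability
#' of the matching orthant, computed via the shared-factor Gauss-Hermite
#' scheme of \code{\link{pattern_probs_binary}} (absolute accuracy better
#' than 1e-6).
#'
#' @param params \code{\link{acde_params}}.
#' @param thresholds length-2 numeric, liability thresholds per trait.
#' @param patterns data frame with columns \code{y1_1}, \code{y2_1},
#'   \code{y1_2}, \code{y2_2} (trait then member) and \code{count}.
#' @param kind pair kind label.
#' @param kinds optional sharing-coefficient table.
#' @return total log-likelihood (sum of count-weighted pattern log-probs).
#' @export
pair_loglik_binary <- function(params, thresholds, patterns, kind,
                               kinds = pair_kinds()) {
  tab <- pattern_probs_binary(params, thresholds, kind, kinds)
  key <- function(d) paste(d$y1_1, d$y2_1, d$y1_2, d$y2_2)
  p <- tab$p[match(key(patterns), key(tab))]
  sum(patterns$count * log(pmax(p, 1e-300)))
}

#' Log-likelihood of mixed continuous/binary twin observations
#'
#' Trait 1 is binary (liability-threshold), trait 2 is a continuous score
#' equal to \code{mean + sd * liability}. The joint likelihood of a pair is
#' the bivariate normal density of the two scores times the conditional
#' bivariate-normal rectangle probability of the two binary responses given
#' the scores (conditional mean and covariance from the implied 4x4
#' structure). Vectorized over pairs.
#'
#' @param params \code{\link{acde_params}}.
#' @param tau1 threshold of the binary trait.
#' @param score_mean,score_sd location and scale of the continuous score.
#' @param data data frame with columns \code{y1_1}, \code{y1_2} (binary) and
#'   \code{s_1}, \code{s_2} (scores).
#' @param kind pair kind label ("MZ_twin"/"DZ_twin").
#' @param kinds optional sharing-coefficient table.
#' @return total log-likelihood.
#' @export
pair_loglik_mixed <- function(params, tau1, score_mean, score_sd, data, kind,
                              kinds = pair_kinds()) {
  if (score_sd <= 0) stop("score_sd must be positive")
  S <- implied_pair_covariance(params, kind, kinds)
  cc <- c(2, 4)  # continuous trait coordinates (trait 2 of members 1, 2)
  bb <- c(1, 3)
  Scc <- S[cc, cc]; Sbb <- S[bb, bb]; Sbc <- S[bb, cc]
  z1 <- (data$s_1 - score_mean) / score_sd
  z2 <- (data$s_2 - score_mean) / score_sd
  c2 <- Scc[1, 2]
  if (abs(c2) >= 1) stop("continuous-trait pair correlation at boundary")
  # marginal density of the two scores
  ld <- -log(2 * pi) - 2 * log(score_sd) - 0.5 * log(1 - c2^2) -
    (z1^2 - 2 * c2 * z1 * z2 + z2^2) / (2 * (1 - c2^2))
  # conditional distribution of the binary liabilities given the scores
  B <- Sbc %*% solve(Scc)
  V <- Sbb - B %*% t(Sbc)
  mu1 <- B[1, 1] * z1 + B[1, 2] * z2
  mu2 <- B[2, 1] * z1 + B[2, 2] * z2
  rho_c <- V[1, 2] / sqrt(V[1, 1] * V[2, 2])
  t1 <- (tau1 - mu1) / sqrt(V[1, 1])
  t2 <- (tau1 - mu2) / sqrt(V[2, 2])
  pr <- quadrant_prob(data$y1_1, data$y1_2, t1, t2, rho_c)
  sum(ld) + sum(log(pmax(pr, 1e-300)))
}

#' Model specification for liability-threshold fitting
#'
#' @param family \code{"ACE"}, \code{"ADE"} or \code{"AE"}. ACE fixes D = 0,
#'   ADE fixes C = 0, AE fixes both. A joint ACDE model is not identified
#'   from twin/sibling designs and is refused.
#' @param design \code{"sibling_binary"} (two binary traits, full +
#'   maternal-half + paternal-half pairs) or \code{"twin_mixed"} (binary
#'   trait 1 + continuous trait 2, MZ + DZ pairs).
#' @param trait \code{"both"} for the bivariate model, or 1/2 for a
#'   univariate model of one trait.
#' @return a \code{model_spec} list.
#' @export
model_spec <- function(family = c("ACE", "ADE", "AE"),
                       design = c("sibling_binary", "twin_mixed"),
                       trait = "both") {
  family <- match.arg(family)
  design <- match.arg(design)
  if (!identical(trait, "both")) trait <- as.integer(trait)
  structure(list(family = family, design = design, trait = trait),
            class = "model_spec")
}

# --- parameter packing -----------------------------------------------------
# Estimation scale: variance fractions through a softmax anchored at E
# (logits a = log(A/E), x = log(X/E)), cross-trait correlations through
# atanh, score SD through log. This enforces A + X + E = 1, E > 0 and
# |r| < 1 without constrained optimization.

.par_names <- function(spec) {
  has_x <- spec$family != "AE"
  biv <- identical(spec$trait, "both")
  nm <- character(0)
  traits <- if (biv) 1:2 else spec$trait
  for (t in traits) {
    nm <- c(nm, paste0("a", t))
    if (has_x) nm <- c(nm, paste0("x", t))
  }
  if (biv) {
    nm <- c(nm, "zr_A")
    if (has_x) nm <- c(nm, "zr_X")
    nm <- c(nm, "zr_E")
  }
  cont2 <- spec$design == "twin_mixed" & (biv || identical(spec$trait, 2L))
  bin1 <- !identical(spec$trait, 2L)
  bin2 <- spec$design == "sibling_binary" & (biv || identical(spec$trait, 2L))
  if (bin1) nm <- c(nm, "tau1")
  if (bin2) nm <- c(nm, "tau2")
  if (cont2) nm <- c(nm, "m", "log_s")
  nm
}

.unpack <- function(theta, spec) {
  names(theta) <- .par_names(spec)
  has_x <- spec$family != "AE"
  biv <- identical(spec$trait, "both")
  traits <- if (biv) 1:2 else spec$trait
  A <- c(0, 0); X <- c(0, 0); E <- c(1, 1)
  for (t in traits) {
    ea <- exp(theta[paste0("a", t)])
    ex <- if (has_x) exp(theta[paste0("x", t)]) else 0
    Z <- 1 + ea + ex
    A[t] <- ea / Z; X[t] <- ex / Z; E[t] <- 1 / Z
  }
  r_A <- if (biv) tanh(theta["zr_A"]) else 0
  r_X <- if (biv && has_x) tanh(theta["zr_X"]) else 0
  r_E <- if (biv) tanh(theta["zr_E"]) else 0
  params <- acde_params(
    A = A,
    C = if (spec$family == "ACE") X else c(0, 0),
    D = if (spec$family == "ADE") X else c(0, 0),
    E = E,
    r_A = r_A,
    r_C = if (spec$family == "ACE") r_X else 0,
    r_D = if (spec$family == "ADE") r_X else 0,
    r_E = r_E
  )
  list(params = params,
       tau1 = if ("tau1" %in% names(theta)) unname(theta["tau1"]) else NA_real_,
       tau2 = if ("tau2" %in% names(theta)) unname(theta["tau2"]) else NA_real_,
       m = if ("m" %in% names(theta)) unname(theta["m"]) else NA_real_,
       s = if ("log_s" %in% names(theta)) exp(unname(theta["log_s"])) else NA_real_)
}

# reporting-scale transform used for delta-method SEs; includes derived
# broad-sense quantities
.report <- function(theta, spec) {
  u <- .unpack(theta, spec)
  p <- u$params
  xname <- switch(spec$family, ACE = "C", ADE = "D", AE = NULL)
  biv <- identical(spec$trait, "both")
  traits <- if (biv) 1:2 else spec$trait
  out <- c()
  for (t in traits) {
    out[paste0("A", t)] <- p$A[t]
    if (!is.null(xname)) {
      out[paste0(xname, t)] <- if (xname == "C") p$C[t] else p$D[t]
    }
    out[paste0("E", t)] <- p$E[t]
    out[paste0("H", t)] <- p$A[t] + p$D[t]
  }
  if (biv) {
    out["r_A"] <- p$r_A
    if (identical(xname, "C")) out["r_C"] <- p$r_C
    if (identical(xname, "D")) out["r_D"] <- p$r_D
    out["r_E"] <- p$r_E
    h <- derived_H(p)
    out["r_H"] <- if (is.na(h$r_H)) 0 else h$r_H
  }
  if (!is.na(u$tau1)) out["tau1"] <- u$tau1
  if (!is.na(u$tau2)) out["tau2"] <- u$tau2
  if (!is.na(u$m)) { out["mean"] <- u$m; out["sd"] <- u$s }
  out
}

# --- data preparation ------------------------------------------------------

#' Prepare sibling pairs for liability-model fitting
#'
#' Selects one random sibling-type pair (full, maternal-half or
#' paternal-half) per family cluster — families with several siblings would
#' otherwise be over-weighted — and returns the binary response patterns.
#'
#' @param registry phenotyped registry.
#' @param pairs relative-pair table.
#' @param seed seed for the within-family pair selection.
#' @return data frame with columns \code{kind}, \code{y1_1}, \code{y2_1},
#'   \code{y1_2}, \code{y2_2} (trait-then-member; trait 1 = asthma).
#' @export
prepare_sibling_pairs <- function(registry, pairs, seed = 1L) {
  sib_kinds <- c("full_sibling", "maternal_half_sibling",
                 "paternal_half_sibling")
  pp <- pairs[pairs$kind %in% sib_kinds, , drop = FALSE]
  if (nrow(pp) == 0) stop("no sibling-type pairs in pair table")
  pp <- with_seed(seed, {
    ord <- sample(nrow(pp))
    ppo <- pp[ord, , drop = FALSE]
    ppo[!duplicated(ppo$cluster), , drop = FALSE]
  })
  i1 <- match(pp$id_1, registry$id)
  i2 <- match(pp$id_2, registry$id)
  data.frame(kind = pp$kind,
             y1_1 = registry$asthma[i1], y2_1 = registry$asd[i1],
             y1_2 = registry$asthma[i2], y2_2 = registry$asd[i2],
             stringsAsFactors = FALSE)
}

#' Prepare twin pairs for liability-model fitting
#'
#' @param registry phenotyped registry (twins must carry \code{asd_score}).
#' @param pairs relative-pair table.
#' @return data frame with columns \code{kind}, binary \code{y1_1},
#'   \code{y1_2} (asthma) and continuous \code{s_1}, \code{s_2} (scores).
#' @export
prepare_twin_pairs <- function(registry, pairs) {
  pp <- pairs[pairs$kind %in% c("MZ_twin", "DZ_twin"), , drop = FALSE]
  if (nrow(pp) == 0) stop("no twin pairs in pair table")
  i1 <- match(pp$id_1, registry$id)
  i2 <- match(pp$id_2, registry$id)
  data.frame(kind = pp$kind,
             y1_1 = registry$asthma[i1], y1_2 = registry$asthma[i2],
             s_1 = registry$asd_score[i1], s_2 = registry$asd_score[i2],
             stringsAsFactors = FALSE)
}

# aggregated binary pattern counts by kind
.aggregate_patterns <- function(data, cols) {
  ag <- stats::aggregate(list(count = rep(1L, nrow(data))),
                         by = data[, c("kind", cols)], FUN = sum)
  ag
}

.neg_loglik <- function(theta, spec, prep) {
  u <- tryCatch(.unpack(theta, spec), error = function(e) NULL)
  if (is.null(u)) return(1e10)
  p <- u$params
  ll <- 0
  if (spec$design == "sibling_binary") {
    if (identical(spec$trait, "both")) {
      for (k in names(prep$by_kind)) {
        ll <- ll + pair_loglik_binary(p, c(u$tau1, u$tau2),
                                      prep$by_kind[[k]], k, prep$kinds)
      }
    } else {
      t <- spec$trait
      tau <- if (t == 1L) u$tau1 else u$tau2
      for (k in names(prep$by_kind)) {
        kk <- pair_kind(k, prep$kinds)
        r <- kk$k_A * p$A[t] + kk$k_D * p$D[t] + kk$k_C * p$C[t]
        pt <- prep$by_kind[[k]]
        pr <- quadrant_prob(pt[[prep$ycols[1]]], pt[[prep$ycols[2]]],
                            tau, tau, r)
        ll <- ll + sum(pt$count * log(pmax(pr, 1e-300)))
      }
    }
  } else {  # twin_mixed
    if (identical(spec$trait, "both")) {
      for (k in names(prep$by_kind)) {
        ll <- ll + pair_loglik_mixed(p, u$tau1, u$m, u$s,
                                     prep$by_kind[[k]], k, prep$kinds)
      }
    } else if (spec$trait == 1L) {
      for (k in names(prep$by_kind)) {
        kk <- pair_kind(k, prep$kinds)
        r <- kk$k_A * p$A[1] + kk$k_D * p$D[1] + kk$k_C * p$C[1]
        pt <- prep$by_kind[[k]]
        pr <- quadrant_prob(pt$y1_1, pt$y1_2, u$tau1, u$tau1, r)
        ll <- ll + sum(pt$count * log(pmax(pr, 1e-300)))
      }
    } else {  # univariate continuous
      for (k in names(prep$by_kind)) {
        kk <- pair_kind(k, prep$kinds)
        c2 <- kk$k_A * p$A[2] + kk$k_D * p$D[2] + kk$k_C * p$C[2]
        d <- prep$by_kind[[k]]
        z1 <- (d$s_1 - u$m) / u$s; z2 <- (d$s_2 - u$m) / u$s
        ll <- ll + sum(-log(2 * pi) - 2 * log(u$s) - 0.5 * log(1 - c2^2) -
                         (z1^2 - 2 * c2 * z1 * z2 + z2^2) / (2 * (1 - c2^2)))
      }
    }
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

.start_values <- function(spec, prep) {
  nm <- .par_names(spec)
  th <- stats::setNames(numeric(length(nm)), nm)
  # fractions: A = 0.45, X = 0.15, E = 0.4 as a neutral interior start
  th[grepl("^a", nm)] <- log(0.45 / 0.4)
  th[grepl("^x", nm)] <- log(0.15 / 0.4)
  if ("tau1" %in% nm) th["tau1"] <- stats::qnorm(1 - prep$marg1)
  if ("tau2" %in% nm) th["tau2"] <- stats::qnorm(1 - prep$marg2)
  if ("m" %in% nm) { th["m"] <- prep$score_mean; th["log_s"] <- log(prep$score_sd) }
  th
}

#' Fit a liability-threshold variance-component model
#'
#' Maximizes the summed pair log-likelihoods over an unconstrained
#' parameterization (softmax variance fractions with A + C/D + E = 1 and
#' E > 0; atanh cross-trait correlations; free thresholds shared across
#' sexes; free mean/SD for a continuous twin trait). A deterministic
#' multi-start (default 5 starts: a neutral start plus seeded jitters,
#' screened by Nelder-Mead and polished by BFGS from the best) guards
#' against local optima. Wald covariance comes from the inverted observed
#' information on the estimation scale, delta-methoded to the reporting
#' scale; if the Hessian is not positive definite the fit is returned with
#' an \code{se_available = FALSE} flag.
#'
#' @param data output of \code{\link{prepare_sibling_pairs}} or
#'   \code{\link{prepare_twin_pairs}}.
#' @param spec a \code{\link{model_spec}}.
#' @param kinds optional sharing-coefficient table.
#' @param n_starts number of optimizer starts.
#' @param start_seed seed for the start jitter.
#' @return a \code{model_fit} object.
#' @export
fit_model <- function(data, spec, kinds = pair_kinds(), n_starts = 5,
                      start_seed = 20260101) {
  stopifnot(inherits(spec, "model_spec"))
  expected <- if (spec$design == "sibling_binary") {
    c("full_sibling", "maternal_half_sibling", "paternal_half_sibling")
  } else c("MZ_twin", "DZ_twin")
  present <- intersect(expected, unique(data$kind))
  if (length(present) < 2 && spec$family != "AE") {
    stop("at least two pair kinds are needed to separate A from ",
         if (spec$family == "ACE") "C" else "D",
         "; found: ", paste(present, collapse = ", "))
  }
  prep <- list(kinds = kinds)
  if (spec$design == "sibling_binary") {
    prep$ycols <- if (identical(spec$trait, 2L)) c("y2_1", "y2_2") else c("y1_1", "y1_2")
    cols <- if (identical(spec$trait, "both")) {
      c("y1_1", "y2_1", "y1_2", "y2_2")
    } else prep$ycols
    ag <- .aggregate_patterns(data, cols)
    prep$by_kind <- split(ag, ag$kind)
    prep$marg1 <- mean(c(data$y1_1, data$y1_2))
    prep$marg2 <- mean(c(data$y2_1, data$y2_2))
    n_units <- nrow(data)
  } else {
    if (identical(spec$trait, 1L)) {
      ag <- .aggregate_patterns(data, c("y1_1", "y1_2"))
      prep$by_kind <- split(ag, ag$kind)
    } else {
      prep$by_kind <- split(data, data$kind)
    }
    prep$marg1 <- mean(c(data$y1_1, data$y1_2))
    prep$marg2 <- 0.5
    prep$score_mean <- mean(c(data$s_1, data$s_2))
    prep$score_sd <- stats::sd(c(data$s_1, data$s_2))
    n_units <- nrow(data)
  }
  prep$by_kind <- prep$by_kind[intersect(expected, names(prep$by_kind))]

  th0 <- .start_values(spec, prep)
  if (identical(spec$trait, "both")) {
    # warm start: univariate fits pin the variance fractions and
    # thresholds/moments well; only the cross-trait correlations remain
    for (t in 1:2) {
      sub <- model_spec(spec$family, spec$design, t)
      fsub <- fit_model(data, sub, kinds = kinds, n_starts = 2,
                        start_seed = start_seed)
      common <- intersect(names(fsub$theta), names(th0))
      th0[common] <- fsub$theta[common]
    }
  }
  starts <- list(th0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- with_seed(start_seed + i, {
        jit <- stats::rnorm(length(th0), 0, 0.6)
        # do not jitter thresholds/moments: margins pin them well
        jit[grepl("^(tau|m$|log_s)", names(th0))] <- 0
        th0 + jit
      })
    }
  }
  fn <- function(th) .neg_loglik(th, spec, prep)
  screened <- lapply(starts, function(s) {
    stats::optim(s, fn, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9))
  })
  best0 <- screened[[which.min(vapply(screened, `[[`, numeric(1), "value"))]]
  opt <- stats::optim(best0$par, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  for (round in 1:2) {
    # restarting BFGS resets its curvature approximation; repeat until the
    # objective stops improving
    opt2 <- stats::optim(opt$par, fn, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-6) break
  }
  if (opt$value >= 1e10) stop("liability-model fit did not converge")
  theta <- opt$par
  grad <- numDeriv::grad(fn, theta)
  H <- stats::optimHess(theta, fn)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  se_available <- all(ev > 1e-10)
  rep_est <- .report(theta, spec)
  if (se_available) {
    V <- solve(H)
    J <- numDeriv::jacobian(function(t) .report(t, spec), theta)
    Vr <- J %*% V %*% t(J)
    se <- sqrt(pmax(diag(Vr), 0))
  } else {
    Vr <- NULL
    se <- rep(NA_real_, length(rep_est))
  }
  z975 <- 1.959963984540054
  est_tab <- data.frame(
    parameter = names(rep_est), estimate = unname(rep_est), se = se,
    ci_low = unname(rep_est) - z975 * se,
    ci_high = unname(rep_est) + z975 * se,
    stringsAsFactors = FALSE
  )
  u <- .unpack(theta, spec)
  k_free <- length(theta)
  ll <- -opt$value
  boundary <- any(abs(theta[grepl("^[ax]", names(theta))]) > 10)
  fit <- list(
    spec = spec, theta = theta, params = u$params,
    tau1 = u$tau1, tau2 = u$tau2, score_mean = u$m, score_sd = u$s,
    estimates = est_tab, vcov_report = Vr,
    loglik = ll, n_free = k_free, aic = 2 * k_free - 2 * ll,
    n_units = n_units, gradient_norm = sqrt(sum(grad^2)),
    se_available = se_available, boundary = boundary,
    convergence = opt$convergence
  )
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model, design %s, trait %s: loglik %.2f, AIC %.2f (%d free)%s\n",
              x$spec$family, x$spec$design, paste(x$spec$trait, collapse = ""),
              x$loglik, x$aic, x$n_free,
              if (x$boundary) " [boundary]" else ""))
  print(transform(x$estimates,
                  estimate = round(estimate, 4), se = round(se, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4)))
  invisible(x)
}

#' Likelihood-ratio / AIC model selection
#'
#' Compares fits of the same data: the LRT is computed for nested drops
#' (ACE to AE and ADE to AE, chi-squared with df equal to the difference in
#' free parameters) and the AIC ranks all families. Because the dropped
#' variance fraction sits on the boundary of its parameter space (C, D >= 0),
#' the naive chi-squared p-value is conservative; set
#' \code{boundary_mixture = TRUE} to apply the 50:50 point-mass/chi-squared
#' mixture correction instead. Ties in AIC break toward fewer parameters.
#'
#' @param fits named or unnamed list of \code{model_fit} objects on the
#'   same data.
#' @param boundary_mixture apply the mixture correction to boundary LRTs.
#' @return list with \code{table} (comparison data frame) and \code{best}
#'   (the selected fit).
#' @export
select_model <- function(fits, boundary_mixture = FALSE) {
  stopifnot(length(fits) >= 1)
  fams <- vapply(fits, function(f) f$spec$family, character(1))
  if (length(unique(vapply(fits, `[[`, numeric(1), "n_units"))) > 1) {
    stop("fits must be on identical data (n differs)")
  }
  tab <- data.frame(
    family = fams,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_free = vapply(fits, `[[`, numeric(1), "n_free"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    lrt_stat = NA_real_, lrt_df = NA_real_, lrt_p = NA_real_,
    boundary_note = "", stringsAsFactors = FALSE
  )
  ae <- which(fams == "AE")
  if (length(ae) == 1) {
    for (i in which(fams %in% c("ACE", "ADE"))) {
      stat <- max(0, 2 * (tab$loglik[i] - tab$loglik[ae]))
      df <- tab$n_free[i] - tab$n_free[ae]
      p <- if (stat <= 1e-12) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
      if (boundary_mixture && stat > 1e-12) {
        p <- 0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
          (if (df > 1) 0.5 * stats::pchisq(stat, df - 1, lower.tail = FALSE)
           else 0)
      }
      tab$lrt_stat[i] <- stat; tab$lrt_df[i] <- df; tab$lrt_p[i] <- p
      tab$boundary_note[i] <- if (boundary_mixture) {
        "50:50 mixture correction applied"
      } else "boundary LRT: naive chi-squared p is conservative"
    }
  }
  ord <- order(tab$aic, tab$n_free)
  list(table = tab[ord, ], best = fits[[ord[1]]])
}

#' Broad-sense heritability and combined genetic correlation from a fit
#'
#' H = A + D per trait, and r_H, the correlation of the combined genetic
#' factor: \eqn{r_H = (r_A\sqrt{A_1A_2} + r_D\sqrt{D_1D_2})/\sqrt{H_1H_2}},
#' with delta-method SEs taken from the fit's reporting-scale covariance.
#' r_H equals r_A exactly when D is zero for both traits.
#'
#' @param fit a \code{model_fit} from an ADE or AE family.
#' @return data frame with rows H1, H2 and (bivariate fits) r_H.
#' @export
derived_genetics <- function(fit) {
  if (!fit$spec$family %in% c("ADE", "AE")) {
    stop("broad-sense summaries are defined for ADE/AE fits")
  }
  want <- intersect(c("H1", "H2", "r_H"), fit$estimates$parameter)
  out <- fit$estimates[fit$estimates$parameter %in% want, , drop = FALSE]
  rownames(out) <- NULL
  out
}
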