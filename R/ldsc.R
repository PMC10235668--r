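#' LD-score panel from a block-diagonal LD model
#'
#' SNPs come in blocks of size \code{block_size}; within a block every pair
#' of SNPs has squared correlation \code{r2}, so each SNP's LD score is
#' l = 1 + (block_size - 1) * r2 (the 1 is self-LD). Per-block r2 values
#' can be drawn from a range to give the panel a realistic LD-score spread.
#'
#' @param M number of SNPs.
#' @param block_size SNPs per LD block.
#' @param r2_range length-2 range of within-block squared correlations;
#'   one value per block is drawn uniformly (deterministic given seed).
#' @param seed integer seed.
#' @return \code{ld_panel} data frame with columns \code{snp}, \code{l2}.
#' @export
make_ld_panel <- function(M, block_size = 50, r2_range = c(0, 0.9),
                          seed = 1L) {
  if (M <= 0) stop("M must be positive")
  n_block <- ceiling(M / block_size)
  with_seed(seed, {
    r2 <- stats::runif(n_block, r2_range[1], r2_range[2])
    l2 <- 1 + (block_size - 1) * rep(r2, each = block_size)[seq_len(M)]
    out <- data.frame(snp = paste0("rs", seq_len(M)), l2 = l2,
                      stringsAsFactors = FALSE)
    class(out) <- c("ld_panel", class(out))
    out
  })
}

.check_panel <- function(panel) {
  if (!all(c("snp", "l2") %in% names(panel))) {
    stop("LD panel needs columns snp, l2")
  }
  if (any(panel$l2 < 1)) stop("LD scores must be >= 1 (self-LD)")
  if (nrow(panel) == 0) stop("empty LD panel")
  invisible(panel)
}

#' Simulate GWAS summary statistics for two traits with known h2 and r_g
#'
#' Under the polygenic model behind LD score regression, the Z statistic of
#' SNP j for trait t has variance 1 + N_t h2_t l_j / M and, across traits,
#' covariance r_g sqrt(h2_1 h2_2) sqrt(N_1 N_2) l_j / M plus a sample-overlap
#' cross-intercept term (overlap fraction times the phenotypic correlation
#' in the overlapping sample). Z pairs are drawn independently across SNPs
#' from the implied bivariate normal.
#'
#' @param panel an \code{ld_panel}.
#' @param h2 length-2 SNP heritabilities in [0, 1].
#' @param r_g genetic correlation in [-1, 1].
#' @param N length-2 GWAS sample sizes.
#' @param overlap_frac fraction of overlapping samples
#'   (N_overlap / sqrt(N1 N2)).
#' @param pheno_cor phenotypic correlation in the overlapping sample.
#' @param seed integer seed.
#' @return list of two \code{sumstats} data frames (\code{snp}, \code{Z},
#'   \code{N}).
#' @export
simulate_sumstats <- function(panel, h2, r_g, N, overlap_frac = 0,
                              pheno_cor = 0, seed = 1L) {
  .check_panel(panel)
  h2 <- rep_len(h2, 2); N <- rep_len(N, 2)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]")
  if (abs(r_g) > 1) stop("|r_g| must be <= 1")
  M <- nrow(panel)
  v1 <- 1 + N[1] * h2[1] * panel$l2 / M
  v2 <- 1 + N[2] * h2[2] * panel$l2 / M
  cv <- r_g * sqrt(h2[1] * h2[2]) * sqrt(N[1] * N[2]) * panel$l2 / M +
    overlap_frac * pheno_cor
  rho <- cv / sqrt(v1 * v2)
  if (any(abs(rho) > 1)) {
    stop("implied Z covariance is not positive semi-definite ",
         "(|correlation| > 1 at some SNPs); reduce overlap/r_g")
  }
  with_seed(seed, {
    e1 <- stats::rnorm(M)
    e2 <- stats::rnorm(M)
    z1 <- sqrt(v1) * e1
    z2 <- sqrt(v2) * (rho * e1 + sqrt(1 - rho^2) * e2)
    ss <- function(z, n) {
      out <- data.frame(snp = panel$snp, Z = z, N = n,
                        stringsAsFactors = FALSE)
      class(out) <- c("sumstats", class(out))
      out
    }
    list(ss(z1, N[1]), ss(z2, N[2]))
  })
}

# weighted least squares of y on x (+ optional intercept), returning
# coefficients; weights are fixed by the caller
.wls <- function(x, y, w, intercept = TRUE) {
  if (intercept) {
    X <- cbind(1, x)
    XtW <- t(X * w)
    cf <- solve(XtW %*% X, XtW %*% y)
    c(intercept = cf[1], slope = cf[2])
  } else {
    c(intercept = 0, slope = sum(w * x * y) / sum(w * x^2))
  }
}

.block_ids <- function(M, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, M))
  sort(rep_len(seq_len(n_blocks), M))
}

# delete-a-block jackknife of an estimator est_fn(keep_index)
.jackknife <- function(est_fn, blocks) {
  ids <- unique(blocks)
  full <- est_fn(rep(TRUE, length(blocks)))
  loo <- vapply(ids, function(b) est_fn(blocks != b), numeric(length(full)))
  if (is.null(dim(loo))) loo <- matrix(loo, nrow = 1)
  g <- length(ids)
  ps <- g * full - (g - 1) * loo  # pseudovalues
  est <- rowMeans(ps)
  se <- sqrt(apply(ps, 1, stats::var) / g)
  list(est = full, jk_est = est, se = se, n_blocks = g)
}

#' LD score regression: SNP heritability
#'
#' Regresses chi-squared statistics on N l_j / M. The slope estimates h2
#' and the intercept captures confounding inflation (1 under a clean
#' polygenic model); the intercept may instead be fixed at a supplied
#' value. Weights follow the standard heteroscedasticity/overcounting
#' scheme 1 / (l_j (1 + N h2 l_j / M)^2), with h2 taken from an unweighted
#' first pass and iterated once. Standard errors come from a
#' delete-a-block jackknife over contiguous SNP blocks. A negative fitted
#' h2 is reported as-is with a warning.
#'
#' @param sumstats a \code{sumstats} data frame (snp, Z, N).
#' @param panel matching \code{ld_panel}.
#' @param intercept \code{"free"} or a fixed numeric value.
#' @param n_blocks jackknife block count (default 200).
#' @return \code{ldsc_result} list with \code{h2}, \code{h2_se},
#'   \code{intercept}, \code{intercept_se}, \code{n_blocks}, \code{M}.
#' @export
ldsc_h2 <- function(sumstats, panel, intercept = "free", n_blocks = 200) {
  .check_panel(panel)
  if (!all(sumstats$snp == panel$snp)) {
    sumstats <- sumstats[match(panel$snp, sumstats$snp), ]
    if (anyNA(sumstats$Z)) stop("sumstats and panel SNP sets differ")
  }
  M <- nrow(panel)
  if (M < 2 * 2) stop("too few SNPs for jackknife")
  chi2 <- sumstats$Z^2
  N <- sumstats$N
  x <- N * panel$l2 / M
  fixed <- !identical(intercept, "free")
  c0 <- if (fixed) as.numeric(intercept) else NA_real_
  # first pass: unweighted, to set the weights
  h2_pass <- if (fixed) {
    sum(x * (chi2 - c0)) / sum(x^2)
  } else {
    stats::coef(stats::lm(chi2 ~ x))[2]
  }
  w <- 1 / (pmax(panel$l2, 1) *
              (1 + min(max(h2_pass, 0), 1) * x)^2)
  est_fn <- function(keep) {
    if (fixed) {
      sl <- sum((w * x * (chi2 - c0))[keep]) / sum((w * x^2)[keep])
      c(h2 = sl, intercept = c0)
    } else {
      cf <- .wls(x[keep], chi2[keep], w[keep], intercept = TRUE)
      c(h2 = unname(cf["slope"]), intercept = unname(cf["intercept"]))
    }
  }
  blocks <- .block_ids(M, n_blocks)
  jk <- .jackknife(est_fn, blocks)
  h2 <- unname(jk$est["h2"])
  if (h2 < 0) warning("negative fitted SNP heritability (", signif(h2, 3),
                      "); reported as-is")
  out <- list(h2 = h2, h2_se = unname(jk$se[1]),
              intercept = unname(jk$est["intercept"]),
              intercept_se = if (fixed) 0 else unname(jk$se[2]),
              intercept_fixed = fixed, n_blocks = jk$n_blocks, M = M)
  class(out) <- "ldsc_result"
  out
}

#' LD score regression: genetic correlation between two traits
#'
#' Regresses the per-SNP Z-score products on sqrt(N1 N2) l_j / M; the slope
#' estimates the genetic covariance and the intercept the sample-overlap
#' term. r_g = gencov / sqrt(h2_1 h2_2) with the two heritabilities
#' estimated on the same panel; the jackknife recomputes the full ratio per
#' deleted block so the SE accounts for correlation between numerator and
#' denominators.
#'
#' @param ss1,ss2 \code{sumstats} for the two traits.
#' @param panel shared \code{ld_panel}.
#' @param intercepts \code{"free"} or numeric: length-3 (h2 intercept 1, h2
#'   intercept 2, cross intercept) or a single value recycled for the two
#'   h2 intercepts with a free cross intercept.
#' @param n_blocks jackknife block count.
#' @return \code{ldsc_result} list with \code{rg}, \code{rg_se},
#'   \code{gencov}, \code{h2_1}, \code{h2_2}, intercepts and SEs.
#' @export
ldsc_rg <- function(ss1, ss2, panel, intercepts = "free", n_blocks = 200) {
  .check_panel(panel)
  M <- nrow(panel)
  for (ss in list(ss1, ss2)) {
    if (!all(ss$snp == panel$snp)) stop("sumstats must match the panel SNPs")
  }
  free <- identical(intercepts, "free")
  ic <- if (free) c(NA, NA, NA) else rep_len(as.numeric(intercepts), 3)
  cross_free <- free || length(intercepts) < 3
  z1 <- ss1$Z; z2 <- ss2$Z
  x1 <- ss1$N * panel$l2 / M
  x2 <- ss2$N * panel$l2 / M
  xc <- sqrt(ss1$N * ss2$N) * panel$l2 / M
  # first-pass slopes for weights
  p1 <- stats::coef(stats::lm(z1^2 ~ x1))[2]
  p2 <- stats::coef(stats::lm(z2^2 ~ x2))[2]
  w1 <- 1 / (pmax(panel$l2, 1) * (1 + min(max(p1, 0), 1) * x1)^2)
  w2 <- 1 / (pmax(panel$l2, 1) * (1 + min(max(p2, 0), 1) * x2)^2)
  wc <- sqrt(w1 * w2)
  slope <- function(x, y, w, keep, fix) {
    if (is.na(fix)) {
      unname(.wls(x[keep], y[keep], w[keep], TRUE)["slope"])
    } else {
      sum((w * x * (y - fix))[keep]) / sum((w * x^2)[keep])
    }
  }
  intercept_of <- function(x, y, w, keep, fix) {
    if (is.na(fix)) unname(.wls(x[keep], y[keep], w[keep], TRUE)["intercept"])
    else fix
  }
  cross_fix <- if (cross_free) NA_real_ else ic[3]
  est_fn <- function(keep) {
    h1 <- slope(x1, z1^2, w1, keep, ic[1])
    h2 <- slope(x2, z2^2, w2, keep, ic[2])
    gc <- slope(xc, z1 * z2, wc, keep, cross_fix)
    rg <- if (h1 > 0 && h2 > 0) gc / sqrt(h1 * h2) else NA_real_
    c(h1 = h1, h2 = h2, gencov = gc, rg = rg)
  }
  blocks <- .block_ids(M, n_blocks)
  full <- est_fn(rep(TRUE, M))
  if (is.na(full["rg"])) {
    stop("genetic correlation undefined: a heritability estimate is <= 0 ",
         "(h2_1 = ", signif(full["h1"], 3),
         ", h2_2 = ", signif(full["h2"], 3), ")")
  }
  jk <- .jackknife(est_fn, blocks)
  out <- list(
    rg = unname(full["rg"]), rg_se = unname(jk$se[4]),
    gencov = unname(full["gencov"]), gencov_se = unname(jk$se[3]),
    h2_1 = unname(full["h1"]), h2_1_se = unname(jk$se[1]),
    h2_2 = unname(full["h2"]), h2_2_se = unname(jk$se[2]),
    cross_intercept = intercept_of(xc, z1 * z2, wc, rep(TRUE, M), cross_fix),
    intercepts_fixed = !free, n_blocks = jk$n_blocks, M = M
  )
  class(out) <- "ldsc_result"
  out
}

#' @export
print.ldsc_result <- function(x, ...) {
  if (!is.null(x$rg)) {
    cat(sprintf("LDSC rg = %.4f (SE %.4f); h2 = %.4f / %.4f; %d blocks\n",
                x$rg, x$rg_se, x$h2_1, x$h2_2, x$n_blocks))
  } else {
    cat(sprintf("LDSC h2 = %.4f (SE %.4f); intercept %.4f%s; %d blocks\n",
                x$h2, x$h2_se, x$intercept,
                if (x$intercept_fixed) " (fixed)" else "", x$n_blocks))
  }
  invisible(x)
}

#' Fixed-intercept sensitivity sweep
#'
#' Re-estimates SNP heritability with the regression intercept constrained
#' to each value of a grid (the classic robustness check runs from 1 down
#' to 0.7, reallocating inflation between confounding and polygenicity).
#' On fixed data the fitted slope is monotone nonincreasing in the fixed
#' intercept.
#'
#' @param sumstats a \code{sumstats} data frame.
#' @param panel matching \code{ld_panel}.
#' @param grid numeric vector of fixed intercepts, each in (0, 1.5].
#' @param n_blocks jackknife block count.
#' @return data frame with one row per grid point (\code{intercept},
#'   \code{h2}, \code{h2_se}).
#' @export
intercept_sweep <- function(sumstats, panel, grid = c(1, 0.9, 0.8, 0.7),
                            n_blocks = 200) {
  if (length(grid) == 0) stop("empty intercept grid")
  if (any(grid <= 0 | grid > 1.5)) stop("grid values must be in (0, 1.5]")
  rows <- lapply(grid, function(g) {
    r <- ldsc_h2(sumstats, panel, intercept = g, n_blocks = n_blocks)
    data.frame(intercept = g, h2 = r$h2, h2_se = r$h2_se)
  })
  do.call(rbind, rows)
}

#' Read / write GWAS summary statistics and LD-score tables
#'
#' Sumstats are whitespace-delimited text with a header containing at least
#' SNP, Z, N; LD scores contain SNP, L2. Column validation only — no
#' allele munging.
#'
#' @param path file path.
#' @return the corresponding data frame.
#' @export
read_sumstats <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  need <- c("SNP", "Z", "N")
  if (!all(need %in% names(d))) {
    stop("sumstats file must have columns SNP, Z, N; found: ",
         paste(names(d), collapse = ", "))
  }
  if (any(!is.finite(d$Z))) stop("non-finite Z statistics in ", path)
  if (any(d$N <= 0)) stop("non-positive N in ", path)
  out <- data.frame(snp = d$SNP, Z = d$Z, N = d$N, stringsAsFactors = FALSE)
  class(out) <- c("sumstats", class(out))
  out
}

#' @rdname read_sumstats
#' @export
read_ld_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  if (!all(c("SNP", "L2") %in% names(d))) {
    stop("LD-score file must have columns SNP, L2")
  }
  out <- data.frame(snp = d$SNP, l2 = d$L2, stringsAsFactors = FALSE)
  .check_panel(out)
  class(out) <- c("ld_panel", class(out))
  out
}

#' @rdname read_sumstats
#' @param sumstats a \code{sumstats} data frame.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(data.frame(SNP = sumstats$snp, Z = sumstats$Z,
                                N = sumstats$N),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sumstats
#' @param panel an \code{ld_panel}.
#' @export
write_ld_scores <- function(panel, path) {
  utils::write.table(data.frame(SNP = panel$snp, L2 = panel$l2),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
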