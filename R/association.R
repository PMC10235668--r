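#' Logistic regression with cluster-robust (sandwich) variance
#'
#' Fits a binomial GLM by iteratively reweighted least squares and returns
#' both the model-based and the clustered information-sandwich covariance
#' (score contributions summed within cluster). With every observation in
#' its own cluster the sandwich reduces to the heteroscedasticity-robust
#' (HC) form. Complete or quasi-complete separation is detected (fitted
#' probabilities pinned at 0/1 together with exploding coefficients) and
#' raised as an error rather than returned silently; rank-deficient designs
#' error with the names of the aliased columns.
#'
#' @param design numeric model matrix including an intercept column.
#' @param outcome binary response vector (0/1).
#' @param clusters cluster ids (any type); defaults to one cluster per row.
#' @return list with \code{coefficients}, \code{vcov_model},
#'   \code{vcov_sandwich}, \code{fit} (the glm object), \code{n},
#'   \code{n_clusters}.
#' @export
fit_logistic <- function(design, outcome, clusters = NULL) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2) {
    stop("degenerate outcome: both classes must be present")
  }
  if (nrow(design) != length(outcome)) stop("design/outcome length mismatch")
  if (is.null(clusters)) clusters <- seq_along(outcome)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  dat <- as.data.frame(design)
  dat$.y <- outcome
  fit <- stats::glm(.y ~ . - 1, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  mu <- stats::fitted(fit)
  eps <- 1e-10
  if (any(mu < eps | mu > 1 - eps) && max(abs(stats::coef(fit))) > 15) {
    stop("separation detected: fitted probabilities pinned at 0/1; ",
         "the logistic MLE does not exist for this dataset")
  }
  if (!fit$converged) stop("IRLS did not converge")
  vc_model <- stats::vcov(fit)
  vc_sand <- sandwich::vcovCL(fit, cluster = clusters, type = "HC0",
                              cadjust = FALSE)
  cf <- stats::coef(fit)
  names(cf) <- colnames(design)
  dimnames(vc_model) <- dimnames(vc_sand) <- list(colnames(design),
                                                  colnames(design))
  list(coefficients = cf, vcov_model = vc_model, vcov_sandwich = vc_sand,
       fit = fit, n = length(outcome), n_clusters = length(unique(clusters)))
}

# drop adjustment covariates that are constant or aliased by the columns
# before them (e.g. the relative's parity when every sibship has size two,
# so parity_i + parity_r is constant); intercept and exposure are pinned
# first and never dropped
.drop_constant_cols <- function(X, keep = c("(Intercept)", "asthma")) {
  ord <- c(which(colnames(X) %in% keep), which(!colnames(X) %in% keep))
  X <- X[, ord, drop = FALSE]
  qrd <- qr(X)
  if (qrd$rank < ncol(X)) {
    X <- X[, sort(qrd$pivot[seq_len(qrd$rank)]), drop = FALSE]
  }
  X
}

.or_from_fit <- function(fitres, term, model_level, pair_kind, n_pairs = NA) {
  b <- fitres$coefficients[term]
  se <- sqrt(fitres$vcov_sandwich[term, term])
  est <- data.frame(
    pair_kind = pair_kind, model_level = model_level,
    OR = exp(b), ci_low = exp(b - 1.959963984540054 * se),
    ci_high = exp(b + 1.959963984540054 * se),
    log_or = b, robust_se = se,
    n = fitres$n, n_clusters = fitres$n_clusters, n_pairs = n_pairs,
    stringsAsFactors = FALSE
  )
  rownames(est) <- NULL
  class(est) <- c("association_estimate", class(est))
  est
}

#' Within-individual odds ratio of one trait given the other
#'
#' Logistic regression of ASD on asthma within person, with family-clustered
#' sandwich standard errors. Individuals flagged as excluded (emulating
#' migration or death before age 6) are removed first. At adjustment level
#' \code{adj_covariates} and above, birth year, sex and parity enter as
#' covariates.
#'
#' @param registry a phenotyped \code{registry}.
#' @param model_level one of \code{"crude"}, \code{"adj_covariates"}.
#' @return an \code{association_estimate} row.
#' @export
within_individual_or <- function(registry, model_level = "crude") {
  model_level <- match.arg(model_level, c("crude", "adj_covariates"))
  d <- registry[registry$role == "child" & !registry$excluded, , drop = FALSE]
  if (nrow(d) == 0) stop("no non-excluded children in registry")
  if (all(d$asd == 0) || all(d$asd == 1)) {
    stop("degenerate outcome: ASD indicator is constant")
  }
  X <- cbind(`(Intercept)` = 1, asthma = d$asthma)
  if (model_level == "adj_covariates") {
    X <- cbind(X, birth_year = d$birth_year - mean(d$birth_year),
               sex_male = as.integer(d$sex == "male"), parity = d$parity)
  }
  fr <- fit_logistic(.drop_constant_cols(X), d$asd, clusters = d$family)
  .or_from_fit(fr, "asthma", model_level, "within_individual")
}

#' Build a double-entered exposure/outcome dataset for one pair kind
#'
#' Each relative pair contributes two rows: member 1 as exposure carrier
#' (asthma) with member 2 as outcome carrier (ASD), and vice versa, so the
#' estimate is symmetric in pair ordering; the induced dependence is
#' absorbed by clustering on the extended family. Covariates of both
#' members are carried (suffix \code{_i} for the index/exposure side,
#' \code{_r} for the relative/outcome side).
#'
#' @param registry phenotyped registry.
#' @param pairs a \code{relative_pairs} table.
#' @param kind pair kind to select.
#' @param exposure,outcome trait column names (defaults asthma -> asd).
#' @return a \code{pair_dataset} data frame.
#' @export
build_pair_dataset <- function(registry, pairs, kind,
                               exposure = "asthma", outcome = "asd") {
  if (!kind %in% pair_kinds()$kind) stop("unknown pair kind '", kind, "'")
  pp <- pairs[pairs$kind == kind, , drop = FALSE]
  idx1 <- match(pp$id_1, registry$id)
  idx2 <- match(pp$id_2, registry$id)
  if (anyNA(idx1) || anyNA(idx2)) {
    missing_ids <- c(pp$id_1[is.na(idx1)], pp$id_2[is.na(idx2)])
    stop("pair table references ids absent from registry: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  pheno_na <- is.na(registry[[exposure]][idx1]) |
    is.na(registry[[outcome]][idx2]) |
    is.na(registry[[exposure]][idx2]) | is.na(registry[[outcome]][idx1])
  if (any(pheno_na)) {
    bad <- unique(c(pp$id_1[pheno_na], pp$id_2[pheno_na]))
    stop("pairs reference individuals without phenotypes; ids: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  excl <- registry$excluded[idx1] | registry$excluded[idx2]
  pp <- pp[!excl, , drop = FALSE]
  idx1 <- idx1[!excl]; idx2 <- idx2[!excl]
  one_dir <- function(i, r) {
    data.frame(
      exposure = registry[[exposure]][i], outcome = registry[[outcome]][r],
      exposure_of_outcome = registry[[exposure]][r],
      birth_year_i = registry$birth_year[i], birth_year_r = registry$birth_year[r],
      sex_i = registry$sex[i], sex_r = registry$sex[r],
      parity_i = registry$parity[i], parity_r = registry$parity[r],
      maternal_age_i = registry$maternal_age[i],
      maternal_age_r = registry$maternal_age[r],
      paternal_age_i = registry$paternal_age[i],
      paternal_age_r = registry$paternal_age[r],
      cluster = pp$cluster, stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_dir(idx1, idx2), one_dir(idx2, idx1))
  attr(out, "kind") <- kind
  attr(out, "n_pairs") <- nrow(pp)
  class(out) <- c("pair_dataset", class(out))
  out
}

#' Cross-relative co-aggregation odds ratio
#'
#' Logistic regression of the relative's ASD on the index person's asthma
#' over a double-entered pair dataset, with cluster-robust standard errors
#' on extended-family clusters. Four nested adjustment levels mirror the
#' standard register-design ladder: (1) crude; (2) + birth year, sex,
#' parity of both members; (3) + asthma of the outcome person; (4) +
#' maternal and paternal age at birth of both members.
#'
#' @param pair_data a \code{pair_dataset}.
#' @param model_level one of \code{"crude"}, \code{"adj_covariates"},
#'   \code{"adj_relative_exposure"}, \code{"adj_parental_age"}.
#' @return an \code{association_estimate} row.
#' @export
coaggregation_or <- function(pair_data, model_level = "adj_covariates") {
  model_level <- match.arg(model_level,
                           c("crude", "adj_covariates",
                             "adj_relative_exposure", "adj_parental_age"))
  d <- pair_data
  if (nrow(d) == 0) stop("empty pair dataset")
  lvl <- match(model_level, c("crude", "adj_covariates",
                              "adj_relative_exposure", "adj_parental_age"))
  X <- cbind(`(Intercept)` = 1, asthma = d$exposure)
  if (lvl >= 2) {
    X <- cbind(X,
               birth_year_i = d$birth_year_i - mean(d$birth_year_i),
               birth_year_r = d$birth_year_r - mean(d$birth_year_r),
               sex_male_i = as.integer(d$sex_i == "male"),
               sex_male_r = as.integer(d$sex_r == "male"),
               parity_i = d$parity_i, parity_r = d$parity_r)
  }
  if (lvl >= 3) X <- cbind(X, asthma_r = d$exposure_of_outcome)
  if (lvl >= 4) {
    X <- cbind(X,
               maternal_age_i = d$maternal_age_i - mean(d$maternal_age_i),
               maternal_age_r = d$maternal_age_r - mean(d$maternal_age_r),
               paternal_age_i = d$paternal_age_i - mean(d$paternal_age_i),
               paternal_age_r = d$paternal_age_r - mean(d$paternal_age_r))
  }
  fr <- fit_logistic(.drop_constant_cols(X), d$outcome, clusters = d$cluster)
  .or_from_fit(fr, "asthma", model_level, attr(d, "kind"),
               n_pairs = attr(d, "n_pairs"))
}

#' Co-aggregation odds ratios across all relative types
#'
#' Runs \code{\link{coaggregation_or}} for every pair kind present and
#' prepends the within-individual estimate, producing the relatedness
#' gradient table (and, optionally, a forest plot).
#'
#' @param registry phenotyped registry.
#' @param pairs relative-pair table.
#' @param model_level adjustment level for the pair models.
#' @param within_level adjustment level for the within-individual model.
#' @param kinds pair kinds to analyse; the default is the register design
#'   (siblings, half-siblings, cousins — twins belong to the
#'   liability-model stage, not the co-aggregation gradient).
#' @return data frame of \code{association_estimate} rows.
#' @export
coaggregation_table <- function(registry, pairs,
                                model_level = "adj_covariates",
                                within_level = "adj_covariates",
                                kinds = c("full_sibling",
                                          "maternal_half_sibling",
                                          "paternal_half_sibling",
                                          "full_cousin")) {
  res <- list(within_individual_or(registry, within_level))
  kinds_present <- intersect(kinds, unique(pairs$kind))
  for (k in kinds_present) {
    pd <- build_pair_dataset(registry, pairs, k)
    res[[length(res) + 1L]] <- coaggregation_or(pd, model_level)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Forest plot of the relatedness gradient
#'
#' @param coagg_table output of \code{\link{coaggregation_table}}.
#' @return a ggplot object (ORs with 95\% CIs on a log scale, one row per
#'   relative type, ordered by genetic relatedness).
#' @export
plot_coaggregation <- function(coagg_table) {
  lev <- c("within_individual", "MZ_twin", "DZ_twin", "full_sibling",
           "maternal_half_sibling", "paternal_half_sibling", "full_cousin")
  d <- coagg_table
  d$pair_kind <- factor(d$pair_kind, levels = rev(intersect(lev, d$pair_kind)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$OR, y = .data$pair_kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL,
                  title = "Familial co-aggregation by degree of relatedness") +
    ggplot2::theme_minimal()
}
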