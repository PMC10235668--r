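# Seed hygiene: every stochastic entry point takes an integer seed and
# restores the caller's RNG state on exit, so pipeline stages never perturb
# each other's randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Configuration of a synthetic family registry
#'
#' Counts of family structures to generate. Each structure contributes a
#' characteristic set of relative pairs: nuclear families give full-sibling
#' pairs; half-sibling families give one maternal or paternal half-sibling
#' pair each; cousin families (two married siblings, one child each, linked
#' through shared grandparents) give one full-cousin pair; twin families give
#' one MZ or DZ twin pair.
#'
#' @param n_nuclear number of nuclear families.
#' @param sibship_size children per nuclear family (>= 2 to yield pairs).
#' @param n_maternal_half,n_paternal_half numbers of half-sibling families
#'   (shared mother with two fathers, or shared father with two mothers).
#' @param n_cousin number of cousin-linked family clusters.
#' @param n_twin number of twin families.
#' @param mz_ratio fraction of twin families that are monozygotic.
#' @param birth_years inclusive range of birth years for the child cohort.
#' @param exclusion_prob probability a child is flagged as excluded
#'   (emulates migration/death before age 6); flagged children are dropped by
#'   the association stage, not here.
#' @param confounding numeric; named entries \code{birth_year} and
#'   \code{parental_age} give path coefficients from standardized covariates
#'   into both liabilities (0 = covariates independent of liabilities).
#' @param cousin_k_A,maternal_half_k_C sharing-coefficient overrides passed
#'   to \code{\link{pair_kinds}}.
#' @return a \code{registry_config} list.
#' @export
registry_config <- function(n_nuclear = 0, sibship_size = 2,
                            n_maternal_half = 0, n_paternal_half = 0,
                            n_cousin = 0, n_twin = 0, mz_ratio = 0.5,
                            birth_years = c(1992L, 2007L),
                            exclusion_prob = 0,
                            confounding = c(birth_year = 0, parental_age = 0),
                            cousin_k_A = 0.125, maternal_half_k_C = 1) {
  counts <- c(n_nuclear, n_maternal_half, n_paternal_half, n_cousin, n_twin)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("family counts must be non-negative integers")
  }
  if (sibship_size < 1) stop("sibship_size must be >= 1")
  if (mz_ratio < 0 || mz_ratio > 1) stop("mz_ratio must be in [0, 1]")
  if (exclusion_prob < 0 || exclusion_prob > 1) stop("exclusion_prob in [0, 1]")
  cf <- c(birth_year = 0, parental_age = 0)
  cf[names(confounding)] <- confounding
  if (sum(cf^2) >= 1) stop("confounding paths too large: sum of squares must be < 1")
  structure(list(
    n_nuclear = as.integer(n_nuclear), sibship_size = as.integer(sibship_size),
    n_maternal_half = as.integer(n_maternal_half),
    n_paternal_half = as.integer(n_paternal_half),
    n_cousin = as.integer(n_cousin), n_twin = as.integer(n_twin),
    mz_ratio = mz_ratio, birth_years = as.integer(birth_years),
    exclusion_prob = exclusion_prob, confounding = cf,
    cousin_k_A = cousin_k_A, maternal_half_k_C = maternal_half_k_C
  ), class = "registry_config")
}

.empty_registry <- function() {
  out <- data.frame(
    id = integer(), family = integer(), mother = integer(), father = integer(),
    role = character(), stratum = character(), zygosity = character(),
    sex = character(), birth_year = integer(), parity = integer(),
    maternal_age = numeric(), paternal_age = numeric(),
    excluded = logical(), asthma = integer(), asd = integer(),
    asd_score = numeric(), liab_asthma = numeric(), liab_asd = numeric(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("registry", class(out))
  out
}

#' Build a synthetic pedigree (no phenotypes yet)
#'
#' Generates founder and child records for the family structures requested in
#' the configuration. Children receive covariates (sex, birth year, parity,
#' parental ages at birth) drawn independently of any liability; phenotype
#' columns are left NA until \code{\link{draw_liabilities}} and
#' \code{\link{apply_thresholds}} run. MZ twin pairs are assigned a common
#' sex. Output is deterministic given the seed.
#'
#' @param config a \code{\link{registry_config}}.
#' @param seed integer seed.
#' @return a \code{registry} data frame; attribute \code{"config"} holds the
#'   resolved configuration.
#' @export
build_pedigrees <- function(config, seed = 1L) {
  stopifnot(inherits(config, "registry_config"))
  with_seed(seed, {
    blocks <- list()
    next_id <- 1L
    next_fam <- 1L
    add_block <- function(n_fam, stratum, n_founders, n_children,
                          mother_of, father_of, zygosity = NULL) {
      # founders first within each family, then children; layout repeated
      # identically across the n_fam families of the block
      if (n_fam == 0) return(invisible(NULL))
      per_fam <- n_founders + n_children
      fam <- rep(seq_len(n_fam) - 1L + next_fam, each = per_fam)
      local_idx <- rep(seq_len(per_fam), n_fam)
      id <- seq_len(n_fam * per_fam) - 1L + next_id
      base <- (fam - next_fam) * per_fam + next_id - 1L  # id offset per family
      is_child <- local_idx > n_founders
      ch_slot <- local_idx - n_founders
      mother <- ifelse(is_child, base + mother_of[pmax(ch_slot, 1L)], NA_integer_)
      father <- ifelse(is_child, base + father_of[pmax(ch_slot, 1L)], NA_integer_)
      n_ch <- sum(is_child)
      sex <- rep(NA_character_, length(id))
      sex[!is_child] <- "female"  # founder sex is irrelevant downstream
      sex[is_child] <- sample(c("female", "male"), n_ch, replace = TRUE)
      zyg <- rep(NA_character_, length(id))
      if (!is.null(zygosity)) {
        zyg[is_child] <- rep(zygosity, each = n_children)
        # MZ pairs share sex: copy first twin's sex to the second
        mz_first <- is_child & ch_slot == 1L & zyg == "MZ"
        sex[which(mz_first) + 1L] <- sex[mz_first]
      }
      by <- config$birth_years
      birth_year <- rep(NA_integer_, length(id))
      birth_year[is_child] <- sample(seq(by[1], by[2]), n_ch, replace = TRUE)
      if (!is.null(zygosity)) {
        # twins share a birth year
        first <- which(is_child & ch_slot == 1L)
        birth_year[first + 1L] <- birth_year[first]
      }
      m_age <- rep(NA_real_, length(id))
      p_age <- rep(NA_real_, length(id))
      m_age[is_child] <- round(pmin(45, pmax(18, stats::rnorm(n_ch, 29, 5))))
      p_age[is_child] <- round(pmin(55, pmax(18, stats::rnorm(n_ch, 31, 5.5))))
      blocks[[length(blocks) + 1L]] <<- data.frame(
        id = id, family = fam, mother = mother, father = father,
        role = ifelse(is_child, "child", "founder"),
        stratum = stratum, zygosity = zyg, sex = sex, birth_year = birth_year,
        parity = NA_integer_, maternal_age = m_age, paternal_age = p_age,
        excluded = NA, asthma = NA_integer_, asd = NA_integer_,
        asd_score = NA_real_, liab_asthma = NA_real_, liab_asd = NA_real_,
        stringsAsFactors = FALSE
      )
      next_id <<- next_id + n_fam * per_fam
      next_fam <<- next_fam + n_fam
      invisible(NULL)
    }

    s <- config$sibship_size
    # nuclear: founders (1 mother, 2 father), children all share both
    add_block(config$n_nuclear, "nuclear", 2L, s,
              mother_of = rep(1L, s), father_of = rep(2L, s))
    # maternal half-sibs: 1 mother, 2 fathers, 2 children
    add_block(config$n_maternal_half, "maternal_half", 3L, 2L,
              mother_of = c(1L, 1L), father_of = c(2L, 3L))
    # paternal half-sibs: 2 mothers, 1 father, 2 children
    add_block(config$n_paternal_half, "paternal_half", 3L, 2L,
              mother_of = c(1L, 2L), father_of = c(3L, 3L))
    # cousins: grandmother(1), grandfather(2); two sibling parents (3, 4,
    # children of 1+2); two spouses (5, 6); one child per couple
    if (config$n_cousin > 0) {
      n_fam <- config$n_cousin
      per_fam <- 8L
      fam <- rep(seq_len(n_fam) - 1L + next_fam, each = per_fam)
      id <- seq_len(n_fam * per_fam) - 1L + next_id
      base <- (fam - next_fam) * per_fam + next_id - 1L
      local_idx <- rep(seq_len(per_fam), n_fam)
      mother <- rep(NA_integer_, length(id))
      father <- rep(NA_integer_, length(id))
      mother[local_idx %in% c(3L, 4L)] <- base[local_idx %in% c(3L, 4L)] + 1L
      father[local_idx %in% c(3L, 4L)] <- base[local_idx %in% c(3L, 4L)] + 2L
      # children: 7 from couple (3,5), 8 from couple (4,6)
      mother[local_idx == 7L] <- base[local_idx == 7L] + 3L
      father[local_idx == 7L] <- base[local_idx == 7L] + 5L
      mother[local_idx == 8L] <- base[local_idx == 8L] + 6L
      father[local_idx == 8L] <- base[local_idx == 8L] + 4L
      is_child <- local_idx %in% c(7L, 8L)
      n_ch <- sum(is_child)
      sex <- ifelse(is_child, NA_character_, "female")
      sex[is_child] <- sample(c("female", "male"), n_ch, replace = TRUE)
      by <- config$birth_years
      birth_year <- rep(NA_integer_, length(id))
      birth_year[is_child] <- sample(seq(by[1], by[2]), n_ch, replace = TRUE)
      m_age <- rep(NA_real_, length(id)); p_age <- rep(NA_real_, length(id))
      m_age[is_child] <- round(pmin(45, pmax(18, stats::rnorm(n_ch, 29, 5))))
      p_age[is_child] <- round(pmin(55, pmax(18, stats::rnorm(n_ch, 31, 5.5))))
      blocks[[length(blocks) + 1L]] <- data.frame(
        id = id, family = fam, mother = mother, father = father,
        role = ifelse(is_child, "child", "founder"),
        stratum = "cousin", zygosity = NA_character_, sex = sex,
        birth_year = birth_year, parity = NA_integer_,
        maternal_age = m_age, paternal_age = p_age,
        excluded = NA, asthma = NA_integer_, asd = NA_integer_,
        asd_score = NA_real_, liab_asthma = NA_real_, liab_asd = NA_real_,
        stringsAsFactors = FALSE
      )
      next_id <- next_id + n_fam * per_fam
      next_fam <- next_fam + n_fam
    }
    # twins: zygosity assigned deterministically by count, shuffled
    if (config$n_twin > 0) {
      n_mz <- round(config$n_twin * config$mz_ratio)
      zyg <- sample(c(rep("MZ", n_mz), rep("DZ", config$n_twin - n_mz)))
      add_block(config$n_twin, "twin", 2L, 2L,
                mother_of = c(1L, 1L), father_of = c(2L, 2L), zygosity = zyg)
    }

    if (length(blocks) == 0) return(.empty_registry())
    reg <- do.call(rbind, blocks)
    fnd <- reg$role == "founder"
    reg$sex[fnd] <- ifelse(reg$id[fnd] %in% reg$mother, "female",
                           ifelse(reg$id[fnd] %in% reg$father, "male",
                                  NA_character_))
    child <- reg$role == "child"
    reg$excluded[child] <- if (config$exclusion_prob > 0) {
      stats::runif(sum(child)) < config$exclusion_prob
    } else FALSE
    # parity: birth order within the same mother, ties by record order
    ord <- order(reg$mother[child], reg$birth_year[child])
    par <- integer(sum(child))
    par[ord] <- stats::ave(seq_along(ord), reg$mother[child][ord],
                           FUN = seq_along)
    reg$parity[child] <- par
    class(reg) <- c("registry", class(reg))
    attr(reg, "config") <- config
    reg
  })
}

# kinship sharing coefficients (k_A, k_D, k_C) for every within-family child
# pair, classified from parent pointers; cousins detected through shared
# grandparents. Returns a data.frame of pairs with coefficients.
classify_pairs <- function(registry, kinds = NULL) {
  cfg <- attr(registry, "config")
  if (is.null(kinds)) {
    kinds <- if (!is.null(cfg)) {
      pair_kinds(cousin_k_A = cfg$cousin_k_A,
                 maternal_half_k_C = cfg$maternal_half_k_C)
    } else pair_kinds()
  }
  ch <- registry[registry$role == "child", , drop = FALSE]
  if (nrow(ch) == 0) {
    return(data.frame(id_1 = integer(), id_2 = integer(),
                      kind = character(), cluster = integer(),
                      stringsAsFactors = FALSE))
  }
  # enumerate all unordered child pairs within a family, vectorized over
  # families of equal sibship size (one combination template per size)
  ch <- ch[order(ch$family, ch$id), , drop = FALSE]
  runs <- rle(ch$family)
  sizes <- runs$lengths
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  i <- j <- integer(0)
  for (s in unique(sizes[sizes >= 2])) {
    tmpl <- utils::combn(s, 2)
    off <- starts[sizes == s] - 1L
    i <- c(i, rep(tmpl[1, ], times = length(off)) +
             rep(off, each = ncol(tmpl)))
    j <- c(j, rep(tmpl[2, ], times = length(off)) +
             rep(off, each = ncol(tmpl)))
  }
  if (length(i) == 0) {
    return(data.frame(id_1 = integer(), id_2 = integer(),
                      kind = character(), cluster = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(ch$family[i])
  i <- i[ord]; j <- j[ord]
  gm <- registry$mother[match(ch$mother, registry$id)]  # maternal grandmother
  gf <- registry$mother[match(ch$father, registry$id)]  # paternal grandmother
  same_m <- ch$mother[i] == ch$mother[j]
  same_f <- ch$father[i] == ch$father[j]
  kind <- rep(NA_character_, length(i))
  full <- same_m & same_f
  zyg_i <- ch$zygosity[i]
  kind[full] <- ifelse(!is.na(zyg_i[full]) & zyg_i[full] == "MZ", "MZ_twin",
                ifelse(!is.na(zyg_i[full]) & zyg_i[full] == "DZ", "DZ_twin",
                       "full_sibling"))
  kind[same_m & !same_f] <- "maternal_half_sibling"
  kind[!same_m & same_f] <- "paternal_half_sibling"
  # cousins: a parent of i and a parent of j are full siblings (children of
  # the same founder couple); detected via shared maternal-line grandmother
  # on either side of each child
  neither <- !same_m & !same_f
  if (any(neither)) {
    gmi <- cbind(gm[i], gf[i])
    gmj <- cbind(gm[j], gf[j])
    is_cousin <- neither & (
      (!is.na(gmi[, 1]) & !is.na(gmj[, 1]) & gmi[, 1] == gmj[, 1]) |
      (!is.na(gmi[, 1]) & !is.na(gmj[, 2]) & gmi[, 1] == gmj[, 2]) |
      (!is.na(gmi[, 2]) & !is.na(gmj[, 1]) & gmi[, 2] == gmj[, 1]) |
      (!is.na(gmi[, 2]) & !is.na(gmj[, 2]) & gmi[, 2] == gmj[, 2]))
    kind[is_cousin] <- "full_cousin"
  }
  keep <- !is.na(kind)
  out <- data.frame(id_1 = ch$id[i[keep]], id_2 = ch$id[j[keep]],
                    kind = kind[keep], cluster = ch$family[i[keep]],
                    stringsAsFactors = FALSE)
  m <- match(out$kind, kinds$kind)
  out$k_A <- kinds$k_A[m]; out$k_D <- kinds$k_D[m]; out$k_C <- kinds$k_C[m]
  out
}

#' Enumerate all relative pairs in a registry
#'
#' All within-family child pairs are classified from parent pointers
#' (shared mother and father = full sibling or twin by zygosity; shared
#' mother only = maternal half-sibling; shared father only = paternal
#' half-sibling; parents full siblings = full cousin). Every unordered pair
#' appears once; \code{cluster} is the extended-family id used for
#' cluster-robust variance downstream.
#'
#' @param registry a \code{registry}.
#' @return a \code{relative_pairs} data frame with columns \code{id_1},
#'   \code{id_2}, \code{kind}, \code{cluster}.
#' @export
enumerate_pairs <- function(registry) {
  out <- classify_pairs(registry)
  out <- out[, c("id_1", "id_2", "kind", "cluster")]
  class(out) <- c("relative_pairs", class(out))
  out
}

# per-pair-kind implied liability covariance entries between two individuals
# for traits t, u (t, u in {1, 2}); params is acde_params
.cross_cov <- function(params, k_A, k_D, k_C, t, u, same_person = FALSE) {
  r_A <- if (t == u) 1 else params$r_A
  r_C <- if (t == u) 1 else params$r_C
  r_D <- if (t == u) 1 else params$r_D
  r_E <- if (t == u) 1 else params$r_E
  v <- k_A * r_A * sqrt(params$A[t] * params$A[u]) +
    k_D * r_D * sqrt(params$D[t] * params$D[u]) +
    k_C * r_C * sqrt(params$C[t] * params$C[u])
  if (same_person) v <- v + r_E * sqrt(params$E[t] * params$E[u])
  v
}

# build the 2n x 2n liability covariance for one family's children, given
# the pairwise sharing coefficients; ordering is individual-major:
# (ind1 trait1, ind1 trait2, ind2 trait1, ...)
family_liability_cov <- function(params, kmat_A, kmat_D, kmat_C) {
  n <- nrow(kmat_A)
  S <- matrix(0, 2 * n, 2 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same <- i == j
    kA <- if (same) 1 else kmat_A[i, j]
    kD <- if (same) 1 else kmat_D[i, j]
    kC <- if (same) 1 else kmat_C[i, j]
    for (t in 1:2) for (u in 1:2) {
      S[2 * (i - 1) + t, 2 * (j - 1) + u] <-
        .cross_cov(params, kA, kD, kC, t, u, same_person = same)
    }
  }
  S
}

#' Draw bivariate liabilities for every child in the registry
#'
#' Within each family the children's joint liability vector (two traits per
#' child) is multivariate normal with mean zero, unit variances, and
#' cross-covariances assembled from the pair sharing coefficients and the
#' variance-component architecture:
#' \deqn{Cov(L_t(i), L_u(j)) = k_A r_A \sqrt{A_t A_u} + k_D r_D \sqrt{D_t D_u}
#'   + k_C r_C \sqrt{C_t C_u} + 1\{i=j\} r_E \sqrt{E_t E_u}}
#' with within-trait component correlations equal to 1. Families sharing a
#' covariance template are simulated in one vectorized block (one Cholesky
#' per template). If the configuration requests confounding, standardized
#' birth-year and mid-parental-age scores enter both liabilities with the
#' configured path coefficients and the architecture part is rescaled so
#' total variance stays one.
#'
#' @param registry a \code{registry} from \code{\link{build_pedigrees}}.
#' @param params an \code{\link{acde_params}}.
#' @param seed integer seed.
#' @return the registry with \code{liab_asthma}, \code{liab_asd} filled in.
#' @export
draw_liabilities <- function(registry, params, seed = 1L) {
  stopifnot(inherits(params, "acde_params"))
  cfg <- attr(registry, "config")
  pairs <- classify_pairs(registry)
  ch_rows <- which(registry$role == "child")
  if (length(ch_rows) == 0) return(registry)
  ch_ids <- registry$id[ch_rows]
  fam_of <- registry$family[ch_rows]
  with_seed(seed, {
    # group families by covariance signature: sibship size + the multiset of
    # pair kinds, encoded numerically (rowsum over 8^kind is collision-free
    # for the small per-family pair counts) so no per-family list splitting
    # is needed; families sharing a signature share one Cholesky factor
    ord <- order(fam_of)
    fam_sorted <- fam_of[ord]
    runs <- rle(fam_sorted)
    fam_levels <- runs$values
    n_ch_fam <- runs$lengths
    fam_pos <- match(fam_of, fam_levels)
    kind_id <- match(pairs$kind, pair_kinds()$kind)
    pair_sig <- rep(0, length(fam_levels))
    if (nrow(pairs) > 0) {
      agg <- rowsum(8^kind_id, group = pairs$cluster)
      pair_sig[match(as.numeric(rownames(agg)), fam_levels)] <- agg[, 1]
    }
    sig <- paste0("n", n_ch_fam, ":", pair_sig)
    child_order <- order(fam_pos, ch_ids)   # positions grouped by family
    fam_start <- cumsum(c(1L, n_ch_fam[-length(n_ch_fam)]))
    liab <- matrix(NA_real_, nrow = length(ch_rows), ncol = 2)
    for (s in unique(sig)) {
      fam_idx <- which(sig == s)
      n <- n_ch_fam[fam_idx[1]]
      ii <- child_order[fam_start[fam_idx[1]] + seq_len(n) - 1L]
      kA <- kD <- kC <- matrix(0, n, n)
      pr <- which(pairs$cluster == fam_levels[fam_idx[1]])
      if (length(pr) > 0) {
        ids1 <- match(pairs$id_1[pr], ch_ids[ii])
        ids2 <- match(pairs$id_2[pr], ch_ids[ii])
        for (r in seq_along(pr)) {
          a <- ids1[r]; b <- ids2[r]
          kA[a, b] <- kA[b, a] <- pairs$k_A[pr[r]]
          kD[a, b] <- kD[b, a] <- pairs$k_D[pr[r]]
          kC[a, b] <- kC[b, a] <- pairs$k_C[pr[r]]
        }
      }
      S <- family_liability_cov(params, kA, kD, kC)
      L <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(L)) {
        stop("implied liability covariance is not positive definite for ",
             "family structure '", s, "' (check cross-trait correlations)")
      }
      nf <- length(fam_idx)
      Z <- matrix(stats::rnorm(nf * 2 * n), nrow = nf) %*% L
      pos <- rep(fam_start[fam_idx], each = n) + seq_len(n) - 1L
      rows <- child_order[pos]
      # Z rows: one family each, columns individual-major (ind, trait)
      liab[rows, 1] <- as.vector(t(Z[, seq(1, 2 * n, by = 2), drop = FALSE]))
      liab[rows, 2] <- as.vector(t(Z[, seq(2, 2 * n, by = 2), drop = FALSE]))
    }
    cf <- if (!is.null(cfg)) cfg$confounding else c(birth_year = 0, parental_age = 0)
    if (any(cf != 0)) {
      z_by <- as.vector(scale(registry$birth_year[ch_rows]))
      z_pa <- as.vector(scale(registry$maternal_age[ch_rows] +
                                registry$paternal_age[ch_rows]))
      conf <- cf[["birth_year"]] * z_by + cf[["parental_age"]] * z_pa
      lam <- sqrt(1 - sum(cf^2))
      liab <- lam * liab + conf  # same confounder score enters both traits
    }
    registry$liab_asthma[ch_rows] <- liab[, 1]
    registry$liab_asd[ch_rows] <- liab[, 2]
    registry
  })
}

#' Dichotomize liabilities at sex-specific thresholds
#'
#' @param registry registry with liabilities drawn.
#' @param thresholds a \code{\link{threshold_spec}}.
#' @return registry with binary \code{asthma}, \code{asd} columns filled.
#' @export
apply_thresholds <- function(registry, thresholds) {
  stopifnot(inherits(thresholds, "threshold_spec"))
  ch <- registry$role == "child"
  if (any(ch & is.na(registry$liab_asthma))) {
    stop("liabilities must be drawn before thresholds are applied")
  }
  sx <- ifelse(registry$sex[ch] == "male", "male", "female")
  registry$asthma[ch] <-
    as.integer(registry$liab_asthma[ch] > thresholds[1, ][sx])
  registry$asd[ch] <-
    as.integer(registry$liab_asd[ch] > thresholds[2, ][sx])
  registry
}

#' Attach a continuous trait score to twins
#'
#' Produces a parent-report-style continuous score for the second trait
#' (ASD) as an affine transform of its liability, mimicking a summed
#' 17-item symptom inventory. Optionally clamps and rounds to the 0-17
#' grid. The untransformed liability is retained in \code{liab_asd} so
#' fitted models can be checked on the exact generative scale.
#'
#' @param registry registry with liabilities drawn.
#' @param mean,sd target mean and SD of the score.
#' @param grid if TRUE, round to integers and clamp to [0, 17].
#' @return registry with \code{asd_score} filled for twins.
#' @export
make_trait_score <- function(registry, mean = 0, sd = 1, grid = FALSE) {
  if (sd < 0) stop("sd must be non-negative")
  tw <- registry$role == "child" & !is.na(registry$zygosity)
  if (any(tw & is.na(registry$liab_asd))) {
    stop("liabilities must be drawn before scores are computed")
  }
  sc <- mean + sd * registry$liab_asd[tw]
  if (grid) sc <- pmin(17, pmax(0, round(sc)))
  registry$asd_score[tw] <- sc
  registry
}

#' Simulate a complete registry in one call
#'
#' Convenience wrapper: build pedigrees, draw liabilities, apply thresholds,
#' attach the twin trait score, and enumerate relative pairs.
#'
#' @param config a \code{\link{registry_config}}.
#' @param params an \code{\link{acde_params}}.
#' @param thresholds a \code{\link{threshold_spec}}.
#' @param seed integer seed (sub-seeds for each stage are derived from it).
#' @param score_mean,score_sd,score_grid passed to
#'   \code{\link{make_trait_score}}.
#' @return list with elements \code{registry} and \code{pairs}.
#' @export
simulate_registry <- function(config, params, thresholds, seed = 1L,
                              score_mean = 0, score_sd = 1,
                              score_grid = FALSE) {
  reg <- build_pedigrees(config, seed = seed)
  if (nrow(reg) == 0) return(list(registry = reg, pairs = enumerate_pairs(reg)))
  reg <- draw_liabilities(reg, params, seed = seed + 1000003L)
  reg <- apply_thresholds(reg, thresholds)
  reg <- make_trait_score(reg, mean = score_mean, sd = score_sd,
                          grid = score_grid)
  list(registry = reg, pairs = enumerate_pairs(reg))
}

REGISTRY_FORMAT_VERSION <- "famliab-registry-v1"
PAIRS_FORMAT_VERSION <- "famliab-pairs-v1"

#' Write / read a registry as tab-separated text
#'
#' Files carry a one-line format-version comment followed by a header row;
#' missing values are empty fields.
#'
#' @param registry a \code{registry}.
#' @param path output path.
#' @export
write_registry <- function(registry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", REGISTRY_FORMAT_VERSION), con)
  utils::write.table(registry, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @param path input path.
#' @export
read_registry <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(REGISTRY_FORMAT_VERSION, first, fixed = TRUE)) {
    stop("not a famliab registry file (missing version line): ", path)
  }
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           na.strings = "", stringsAsFactors = FALSE)
  out$excluded <- as.logical(out$excluded)
  class(out) <- c("registry", class(out))
  out
}

#' @rdname write_registry
#' @param pairs a \code{relative_pairs} table.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", PAIRS_FORMAT_VERSION), con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(PAIRS_FORMAT_VERSION, first, fixed = TRUE)) {
    stop("not a famliab pairs file (missing version line): ", path)
  }
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           na.strings = "", stringsAsFactors = FALSE)
  class(out) <- c("relative_pairs", class(out))
  out
}
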