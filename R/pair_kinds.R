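#' Relative-pair kinds and their sharing coefficients
#'
#' Each pair kind carries three sharing coefficients used throughout the
#' package: \code{k_A}, the expected proportion of additive-genetic variance
#' shared by the pair; \code{k_D}, the proportion of dominant-genetic variance
#' shared; and \code{k_C}, the proportion of shared-environment variance
#' shared. The defaults encode the classical quantitative-genetic assumptions
#' for register designs: monozygotic (MZ) twins share all additive and
#' dominant variance, dizygotic (DZ) twins and full siblings share 1/2 of the
#' additive and 1/4 of the dominant variance, half-siblings share 1/4 of the
#' additive and none of the dominant variance, and full cousins share 1/8 of
#' the additive variance. Shared environment is fully shared by twins, full
#' siblings and maternal half-siblings, and not shared by paternal
#' half-siblings or cousins (cousins are reared in different households).
#'
#' @param cousin_k_A additive sharing for full cousins (standard kinship
#'   theory gives 0.125); override for sensitivity analyses.
#' @param maternal_half_k_C shared-environment sharing for maternal
#'   half-siblings; default 1 (reared together with the shared mother).
#' @return a data frame with one row per kind and columns
#'   \code{kind}, \code{k_A}, \code{k_D}, \code{k_C}.
#' @export
#' @examples
#' pair_kinds()
pair_kinds <- function(cousin_k_A = 0.125, maternal_half_k_C = 1) {
  stopifnot(cousin_k_A >= 0, cousin_k_A <= 1,
            maternal_half_k_C >= 0, maternal_half_k_C <= 1)
  kinds <- data.frame(
    kind = c("MZ_twin", "DZ_twin", "full_sibling",
             "maternal_half_sibling", "paternal_half_sibling", "full_cousin"),
    k_A = c(1, 0.5, 0.5, 0.25, 0.25, cousin_k_A),
    k_D = c(1, 0.25, 0.25, 0, 0, 0),
    k_C = c(1, 1, 1, maternal_half_k_C, 0, 0),
    stringsAsFactors = FALSE
  )
  stopifnot(all(kinds$k_A >= kinds$k_D))
  class(kinds) <- c("pair_kinds", class(kinds))
  kinds
}

#' Look up the sharing coefficients of one pair kind
#'
#' @param kind one of \code{"MZ_twin"}, \code{"DZ_twin"},
#'   \code{"full_sibling"}, \code{"maternal_half_sibling"},
#'   \code{"paternal_half_sibling"}, \code{"full_cousin"}.
#' @param kinds a \code{\link{pair_kinds}} table (defaults allow overrides).
#' @return a list with elements \code{kind}, \code{k_A}, \code{k_D},
#'   \code{k_C}.
#' @export
pair_kind <- function(kind, kinds = pair_kinds()) {
  i <- match(kind, kinds$kind)
  if (is.na(i)) {
    stop("unknown pair kind '", kind, "'; expected one of: ",
         paste(kinds$kind, collapse = ", "))
  }
  as.list(kinds[i, , drop = FALSE])
}
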