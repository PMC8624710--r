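#' Compound registry for ion-pair prodrug dose equivalence
#'
#' A compound registry holds the active moiety (free ibuprofen acid) and its
#' ion-pair derivatives (here, L-valine alkyl ester ibuprofenates) together
#' with the molar masses needed to convert between salt mass and
#' active-moiety-equivalent mass. Two molar masses are carried per compound:
#' \code{M_pair} drives all dose arithmetic, while \code{M_pair_display} is
#' the value quoted for display where the literature prints a (slightly)
#' different figure for the same salt.
#'
#' @param path Path to a registry CSV with header
#'   \code{acronym,name,M_pair,M_active,chain_length,branched} (an optional
#'   \code{M_pair_display} column defaults to \code{M_pair}).
#' @return A data.frame of class \code{compound_registry}, one row per
#'   compound.
#' @examples
#' reg <- default_compound_registry()
#' active_fraction(get_compound(reg, "[ValOEt][IBU]"))
#' @export
read_compound_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("acronym", "name", "M_pair", "M_active", "chain_length", "branched")
  missing <- setdiff(needed, names(reg))
  if (length(missing) > 0L)
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  if (is.null(reg$M_pair_display)) reg$M_pair_display <- reg$M_pair
  reg$branched <- as.logical(reg$branched)
  validate_registry(reg)
  class(reg) <- c("compound_registry", "data.frame")
  reg
}

#' @rdname read_compound_registry
#' @export
default_compound_registry <- function() {
  read_compound_registry(
    system.file("extdata", "compound_registry.csv", package = "franzperm",
      mustWork = TRUE))
}

validate_registry <- function(reg) {
  if (nrow(reg) == 0L) stop("registry is empty")
  if (anyDuplicated(reg$acronym))
    stop("duplicate acronyms in registry: ",
         paste(unique(reg$acronym[duplicated(reg$acronym)]), collapse = ", "))
  bad <- !is.finite(reg$M_pair) | !is.finite(reg$M_active) |
    reg$M_active <= 0 | reg$M_pair < reg$M_active
  if (any(bad))
    stop("invalid molar masses (need M_pair >= M_active > 0) for: ",
         paste(reg$acronym[bad], collapse = ", "))
  invisible(reg)
}

#' Look up one compound in a registry
#'
#' @param registry A \code{compound_registry}.
#' @param acronym Compound acronym, e.g. \code{"[ValOPr][IBU]"}.
#' @return A one-row list of class \code{compound}.
#' @export
get_compound <- function(registry, acronym) {
  i <- match(acronym, registry$acronym)
  if (is.na(i)) stop("unknown compound acronym: ", acronym)
  cmp <- as.list(registry[i, , drop = FALSE])
  class(cmp) <- "compound"
  cmp
}

check_compound <- function(compound) {
  if (inherits(compound, "compound_registry"))
    stop("pass a single compound (see get_compound()), not a registry")
  if (is.null(compound$M_pair) || is.null(compound$M_active))
    stop("invalid compound: needs M_pair and M_active")
  if (!is.finite(compound$M_pair) || !is.finite(compound$M_active) ||
      compound$M_active <= 0 || compound$M_pair < compound$M_active)
    stop("invalid compound: need M_pair >= M_active > 0")
  invisible(compound)
}

#' Mass fraction of active moiety in an ion-pair salt
#'
#' The fraction of the salt's mass contributed by the active moiety,
#' \code{M_active / M_pair}. Equals 1 for the free acid.
#'
#' @param compound A \code{compound} (see \code{\link{get_compound}}).
#' @return Dimensionless fraction in (0, 1].
#' @export
active_fraction <- function(compound) {
  check_compound(compound)
  compound$M_active / compound$M_pair
}

#' Convert salt mass to active-moiety-equivalent mass
#'
#' @param salt_mass Mass of the salt, g (vectorized, must be >= 0).
#' @param compound A \code{compound}.
#' @return Mass of active moiety delivered, g.
#' @export
equivalent_active_mass <- function(salt_mass, compound) {
  check_compound(compound)
  if (any(salt_mass < 0)) stop("salt_mass must be >= 0")
  salt_mass * compound$M_active / compound$M_pair
}

#' Salt mass needed for a target active dose
#'
#' Exact inverse of \code{\link{equivalent_active_mass}}.
#'
#' @param active_dose Target mass of active moiety, g (vectorized, >= 0).
#' @param compound A \code{compound}.
#' @return Mass of salt to weigh, g.
#' @export
salt_mass_for_dose <- function(active_dose, compound) {
  check_compound(compound)
  if (any(active_dose < 0)) stop("active_dose must be >= 0")
  active_dose * compound$M_pair / compound$M_active
}

#' Formulation (cream) compositions
#'
#' Reads a formulation table: per compound, the vehicle, salt and cosolvent
#' masses making up one cream batch. Checks mass closure and attaches the
#' active mass fraction of the whole formulation.
#'
#' @param path CSV with header
#'   \code{acronym,vehicle_mass_g,compound_mass_g,cosolvent_mass_g,total_mass_g}.
#' @param registry A \code{compound_registry} used to resolve acronyms.
#' @param tol Mass-closure tolerance, g.
#' @return data.frame with an added \code{active_mass_fraction} column.
#' @export
read_formulations <- function(path, registry = default_compound_registry(),
                              tol = 1e-6) {
  fm <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("acronym", "vehicle_mass_g", "compound_mass_g",
              "cosolvent_mass_g", "total_mass_g")
  missing <- setdiff(needed, names(fm))
  if (length(missing) > 0L)
    stop("formulation table is missing columns: ",
         paste(missing, collapse = ", "))
  closure <- fm$vehicle_mass_g + fm$compound_mass_g + fm$cosolvent_mass_g
  if (any(abs(closure - fm$total_mass_g) > tol))
    stop("formulation masses do not close to total within ", tol, " g")
  fm$active_mass_fraction <- vapply(seq_len(nrow(fm)), function(i) {
    cmp <- get_compound(registry, fm$acronym[i])
    equivalent_active_mass(fm$compound_mass_g[i], cmp) / fm$total_mass_g[i]
  }, numeric(1))
  if (any(fm$active_mass_fraction <= 0 | fm$active_mass_fraction >= 1))
    stop("active_mass_fraction must be in (0, 1)")
  fm
}

#' @rdname read_formulations
#' @export
default_formulations <- function(registry = default_compound_registry()) {
  read_formulations(
    system.file("extdata", "formulations.csv", package = "franzperm",
      mustWork = TRUE),
    registry = registry)
}
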