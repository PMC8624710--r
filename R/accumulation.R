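#' Drug accumulation in the membrane
#'
#' Deposited drug per gram of membrane from the end-of-study extraction
#' assay: the membrane is extracted in \code{V_extract} mL of solvent and
#' the supernatant assayed, so
#' \code{accumulation = C_supernatant * V_extract / m_membrane}.
#'
#' @param C_supernatant Supernatant drug concentration, ug/mL (vectorized).
#' @param V_extract Extraction solvent volume, mL.
#' @param m_membrane Membrane (tissue) mass, g; must be > 0.
#' @return Accumulation, ug drug per g membrane.
#' @export
membrane_accumulation <- function(C_supernatant, V_extract, m_membrane) {
  if (any(!is.finite(m_membrane)) || any(m_membrane <= 0))
    stop("m_membrane must be > 0")
  if (any(C_supernatant < 0) || any(V_extract < 0))
    stop("concentration and volume must be >= 0")
  C_supernatant * V_extract / m_membrane
}

#' Re-express salt-basis accumulation as active moiety
#'
#' When the assay quantifies the intact salt, multiply by the active mass
#' fraction to report ug of active (ibuprofen) per g of membrane; the free
#' acid is unchanged.
#'
#' @param accumulation_salt_basis Accumulation on the salt basis, ug/g.
#' @param compound A \code{compound} (see \code{\link{get_compound}}).
#' @return Accumulation on the active-moiety basis, ug active per g.
#' @export
express_as_active <- function(accumulation_salt_basis, compound) {
  if (any(accumulation_salt_basis < 0)) stop("accumulation must be >= 0")
  accumulation_salt_basis * active_fraction(compound)
}

#' Process an accumulation assay table
#'
#' @param data data.frame with columns \code{cell_id, compound, membrane,
#'   conc_supernatant_ug_per_ml, V_extract_ml, membrane_mass_g}.
#' @param registry A \code{compound_registry} (used when
#'   \code{basis = "salt"}).
#' @param basis Either \code{"active"} (default: the assay already reports
#'   active-moiety equivalents) or \code{"salt"} (convert via
#'   \code{\link{express_as_active}}).
#' @return The input with an added \code{accumulation_ug_per_g} column
#'   (active-moiety basis).
#' @export
accumulation_table <- function(data, registry = default_compound_registry(),
                               basis = c("active", "salt")) {
  basis <- match.arg(basis)
  needed <- c("cell_id", "compound", "membrane",
              "conc_supernatant_ug_per_ml", "V_extract_ml", "membrane_mass_g")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L)
    stop("accumulation table is missing columns: ",
         paste(missing, collapse = ", "))
  acc <- membrane_accumulation(data$conc_supernatant_ug_per_ml,
                               data$V_extract_ml, data$membrane_mass_g)
  if (basis == "salt") {
    acc <- vapply(seq_along(acc), function(i)
      express_as_active(acc[i], get_compound(registry, data$compound[i])),
      numeric(1))
  }
  data$accumulation_ug_per_g <- acc
  data
}
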