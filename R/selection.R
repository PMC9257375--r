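#' Available prey biomass from density surveys
#'
#' Converts prey population densities to available biomass per km^2 by
#' multiplying each density by a representative (adult female) body mass,
#' then expresses each taxon's share of the total. Because electivity
#' values for rare species are unstable, taxa whose share of available
#' biomass does not exceed `include_threshold` are excluded and the
#' shares renormalized over the included set; taxa without a body mass
#' are excluded up front.
#'
#' @param densities data.frame with columns `taxon`, `density`
#'   (individuals/km^2), optional `se`, and `female_mass_kg` (kg, `NA`
#'   when unknown).
#' @param include_threshold minimum proportion of available biomass for
#'   inclusion (default 0.05, i.e. the ">5% of biomass available" rule);
#'   comparison is strict.
#' @return an `availability_table`: list with `entries` (data.frame
#'   `taxon`, `density`, `se`, `female_mass_kg`, `biomass_kg_per_km2`,
#'   `p` over included taxa, `p` summing to 1) and `excluded` (data.frame
#'   `taxon`, `reason`).
#' @examples
#' available_biomass(data.frame(
#'   taxon = c("muntjac", "wild_pig", "sambar", "serow", "gaur"),
#'   density = c(1.50, 3.19, 0.36, 0.22, 0.02),
#'   female_mass_kg = c(20, 75, 185, 85, NA)))
#' @export
available_biomass <- function(densities, include_threshold = 0.05) {
  stopifnot(is.data.frame(densities),
            all(c("taxon", "density", "female_mass_kg") %in%
                  names(densities)))
  if (nrow(densities) == 0) stop("empty density table", call. = FALSE)
  if (any(densities$density < 0, na.rm = TRUE))
    stop("densities must be non-negative", call. = FALSE)
  if (any(densities$female_mass_kg <= 0, na.rm = TRUE))
    stop("female masses must be positive", call. = FALSE)
  if (!"se" %in% names(densities)) densities$se <- NA_real_

  excluded <- data.frame(taxon = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  no_mass <- is.na(densities$female_mass_kg)
  if (any(no_mass))
    excluded <- rbind(excluded,
                      data.frame(taxon = densities$taxon[no_mass],
                                 reason = "no mass"))
  ent <- densities[!no_mass, , drop = FALSE]
  ent$biomass_kg_per_km2 <- ent$density * ent$female_mass_kg
  p_all <- ent$biomass_kg_per_km2 / sum(ent$biomass_kg_per_km2)
  below <- p_all <= include_threshold
  if (any(below))
    excluded <- rbind(excluded,
                      data.frame(taxon = ent$taxon[below],
                                 reason = "below availability threshold"))
  ent <- ent[!below, , drop = FALSE]
  if (nrow(ent) == 0) stop("all taxa excluded from availability",
                           call. = FALSE)
  ent$p <- ent$biomass_kg_per_km2 / sum(ent$biomass_kg_per_km2)
  rownames(ent) <- NULL
  out <- list(entries = ent[, c("taxon", "density", "se",
                                "female_mass_kg", "biomass_kg_per_km2",
                                "p")],
              excluded = excluded,
              include_threshold = include_threshold)
  class(out) <- "availability_table"
  out
}

#' @export
print.availability_table <- function(x, ...) {
  cat("Available prey biomass (included taxa)\n")
  print.data.frame(x$entries, row.names = FALSE)
  if (nrow(x$excluded) > 0) {
    cat("Excluded: ",
        paste(sprintf("%s (%s)", x$excluded$taxon, x$excluded$reason),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Jacobs' electivity index
#'
#' `D = (r - p) / (r + p - 2 r p)` comparing a used proportion `r` to an
#' available proportion `p`. `D` ranges from -1 (complete avoidance,
#' attained exactly when the prey is never used) through 0 (use
#' proportional to availability) to +1 (complete preference).
#'
#' @param r used proportion(s), in `[0, 1]`.
#' @param p available proportion(s), in `(0, 1)`.
#' @return electivity value(s) in `[-1, 1]`.
#' @examples
#' jacobs_D(0, 0.2)        # -1: never used
#' jacobs_D(0.3, 0.3)      #  0: used as available
#' @references Jacobs (1974) Oecologia 14:413-417.
#' @export
jacobs_D <- function(r, p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("available proportion p must lie strictly within (0, 1)",
         call. = FALSE)
  if (any(!is.finite(r) | r < 0 | r > 1))
    stop("used proportion r must lie within [0, 1]", call. = FALSE)
  (r - p) / (r + p - 2 * r * p)
}

#' Classify an electivity value as preference, neutrality or avoidance
#'
#' Strict thresholds: preferred if `D > threshold`, avoided if
#' `D < -threshold`, neutral otherwise.
#'
#' @param D Jacobs' electivity value(s) in `[-1, 1]`.
#' @param threshold classification threshold (default 0.30).
#' @return character vector of `"preferred"`, `"neutral"`, `"avoided"`.
#' @export
classify_preference <- function(D, threshold = 0.30) {
  if (any(!is.finite(D) | D < -1 | D > 1))
    stop("D must lie within [-1, 1]", call. = FALSE)
  ifelse(D > threshold, "preferred",
         ifelse(D < -threshold, "avoided", "neutral"))
}

#' Prey-selection analysis: used versus available biomass
#'
#' Computes Jacobs' electivity for every taxon in the availability set.
#' Used proportions come from the diet's percent-biomass column; a taxon
#' absent from the diet gets a used proportion of 0. Two conventions are
#' offered: `"renormalized"` (default) rescales the biomass percentages
#' of the availability-included taxa to sum to 1, so that used and
#' available proportions are measured over the same prey base; `"raw"`
#' uses `bio_pct / 100` over the whole diet. The two generally agree in
#' sign but not in magnitude.
#'
#' @param diet a [diet_composition()] object, or a named numeric vector
#'   of biomass percentages.
#' @param avail an [available_biomass()] table.
#' @param use_convention `"renormalized"` or `"raw"`.
#' @param threshold preference-classification threshold, passed to
#'   [classify_preference()].
#' @return data.frame with one row per included taxon: `taxon`, `r`,
#'   `p`, `D`, `preference_class`, `convention`.
#' @export
selection_analysis <- function(diet, avail,
                               use_convention = c("renormalized", "raw"),
                               threshold = 0.30) {
  use_convention <- match.arg(use_convention)
  stopifnot(inherits(avail, "availability_table"))
  bio <- if (inherits(diet, "diet_composition"))
    stats::setNames(diet$per_taxon$bio_pct, diet$per_taxon$taxon)
  else diet
  taxa <- avail$entries$taxon
  if (!any(taxa %in% names(bio)[bio > 0]))
    stop("diet and availability share no taxon", call. = FALSE)
  used <- stats::setNames(rep(0, length(taxa)), taxa)
  common <- intersect(taxa, names(bio))
  used[common] <- bio[common]
  r <- if (use_convention == "renormalized") used / sum(used)
       else used / 100
  D <- jacobs_D(r, avail$entries$p)
  data.frame(taxon = taxa,
             r = as.numeric(r),
             p = avail$entries$p,
             D = as.numeric(D),
             preference_class = classify_preference(D, threshold),
             convention = use_convention,
             stringsAsFactors = FALSE)
}
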