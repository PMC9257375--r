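#' Frequency of occurrence of prey taxa
#'
#' Percentage of scats containing each prey taxon. A taxon is counted at
#' most once per scat regardless of its volume, so values can sum to more
#' than 100% when scats hold several items.
#'
#' @param x a [scat_table()] for a single predator.
#' @return named numeric vector, taxon -> percent of scats.
#' @export
frequency_of_occurrence <- function(x) {
  check_single_predator(x)
  n <- n_scats(x)
  counts <- tapply_v(x$scat_id, x$prey_taxon, function(id) length(unique(id)))
  100 * counts[order(names(counts))] / n
}

#' Percent volume of prey taxa
#'
#' Mean per-scat volume fraction of each taxon, expressed over all scats:
#' `100 * sum(volume fractions of taxon) / n_scats`. Sums to 100 over
#' taxa because each scat's fractions sum to 1.
#'
#' @inheritParams frequency_of_occurrence
#' @return named numeric vector, taxon -> percent volume.
#' @export
percent_volume <- function(x) {
  check_single_predator(x)
  n <- n_scats(x)
  v <- tapply_v(x$volume_fraction, x$prey_taxon, sum)
  100 * v[order(names(v))] / n
}

#' Percent of ingested biomass of prey taxa
#'
#' Diet composition corrected for differential digestibility. Each
#' taxon's scat content is weighted by its biomass-per-scat correction
#' factor: with the default volume weighting,
#' `bio_i = 100 * V_i * cf_i / sum_j V_j * cf_j`, where `V_i` is the
#' taxon's summed volume fraction across scats. With occurrence
#' weighting, `V_i` is replaced by the count of scats containing the
#' taxon (a coarser convention that does not reproduce volume-resolved
#' published tables; retained for comparability with occurrence-only
#' studies).
#'
#' @inheritParams frequency_of_occurrence
#' @param cf a [build_correction_table()] covering every observed taxon.
#' @param weighting `"volume"` (default) or `"occurrence"`.
#' @return named numeric vector, taxon -> percent of ingested biomass;
#'   sums to 100.
#' @export
percent_biomass <- function(x, cf, weighting = c("volume", "occurrence")) {
  weighting <- match.arg(weighting)
  check_single_predator(x)
  w <- if (weighting == "volume") {
    tapply_v(x$volume_fraction, x$prey_taxon, sum)
  } else {
    tapply_v(x$scat_id, x$prey_taxon, function(id) length(unique(id)))
  }
  w <- w[order(names(w))]
  cfv <- cf_lookup(cf, names(w))
  100 * w * cfv / sum(w * cfv)
}

#' Aggregate a per-taxon composition into prey categories
#'
#' Volume and biomass percentages are summed within category; category
#' occurrence is the percentage of scats containing at least one member
#' taxon (which is why the raw records are required, not just the
#' per-taxon map).
#'
#' @inheritParams frequency_of_occurrence
#' @param per_taxon data.frame with columns `taxon`, `occ_pct`,
#'   `vol_pct`, `bio_pct` (as built by [diet_composition()]).
#' @param categories named character vector, taxon -> category label
#'   (e.g. ungulate, carnivore, rodent, bird, other).
#' @return data.frame with columns `category`, `occ_pct`, `vol_pct`,
#'   `bio_pct`.
#' @export
aggregate_categories <- function(x, per_taxon, categories) {
  uncat <- setdiff(per_taxon$taxon, names(categories))
  if (length(uncat) > 0)
    stop("uncategorized taxa: ", paste(uncat, collapse = ", "),
         call. = FALSE)
  cat_of <- categories[per_taxon$taxon]
  vol <- tapply(per_taxon$vol_pct, cat_of, sum)
  bio <- tapply(per_taxon$bio_pct, cat_of, sum)
  n <- n_scats(x)
  scat_cat <- unique(data.frame(scat_id = x$scat_id,
                                category = categories[x$prey_taxon]))
  occ_counts <- table(scat_cat$category)
  cats <- names(vol)
  data.frame(category = cats,
             occ_pct = 100 * as.numeric(occ_counts[cats]) / n,
             vol_pct = as.numeric(vol),
             bio_pct = as.numeric(bio),
             stringsAsFactors = FALSE)
}

#' Levins' measure of dietary niche breadth
#'
#' `B = 1 / sum(p_i^2)` over diet proportions `p_i = bio_pct_i / 100`.
#' `B` equals 1 for a single-prey specialist and the number of prey items
#' for perfectly even use. Computed over species-level prey items, never
#' category aggregates.
#'
#' @param bio_pct named numeric vector of percentages summing to 100
#'   (within 0.5); zero entries are dropped.
#' @return the niche breadth `B`.
#' @examples
#' levins_niche_breadth(c(a = 25, b = 25, c = 25, d = 25))  # 4
#' @export
levins_niche_breadth <- function(bio_pct) {
  bio_pct <- bio_pct[bio_pct > 0]
  if (length(bio_pct) == 0)
    stop("all diet proportions are zero", call. = FALSE)
  if (abs(sum(bio_pct) - 100) > 0.5)
    stop("percentages must sum to 100 (got ",
         format(sum(bio_pct)), ")", call. = FALSE)
  p <- bio_pct / 100
  1 / sum(p^2)
}

#' Full diet composition of one predator
#'
#' Computes the per-taxon occurrence, volume and biomass percentages, the
#' per-category aggregation, and Levins' niche breadth in one pass: the
#' engine behind a classic scat-analysis diet table.
#'
#' @inheritParams percent_biomass
#' @param categories optional named character vector taxon -> category;
#'   if supplied, a per-category table is included.
#' @return an object of class `diet_composition`: a list with elements
#'   `predator`, `n_scats`, `weighting`, `per_taxon` (data.frame `taxon`,
#'   `category`, `occ_pct`, `vol_pct`, `bio_pct`), `per_category` (or
#'   `NULL`) and `niche_breadth_B`.
#' @examples
#' scats <- nepl_fixture("tiger")
#' ref <- nepl_reference()
#' cf <- build_correction_table("tiger", ref$predators$tiger$mass_kg,
#'                              unlist(ref$predators$tiger$killed_mass_kg))
#' diet_composition(scats, cf, unlist(ref$categories))
#' @export
diet_composition <- function(x, cf, categories = NULL,
                             weighting = c("volume", "occurrence")) {
  weighting <- match.arg(weighting)
  check_single_predator(x)
  occ <- frequency_of_occurrence(x)
  vol <- percent_volume(x)
  bio <- percent_biomass(x, cf, weighting)
  taxa <- names(occ)
  per_taxon <- data.frame(
    taxon = taxa,
    category = if (is.null(categories)) NA_character_ else
      as.character(categories[taxa]),
    occ_pct = as.numeric(occ),
    vol_pct = as.numeric(vol),
    bio_pct = as.numeric(bio),
    stringsAsFactors = FALSE)
  per_category <- if (is.null(categories)) NULL else
    aggregate_categories(x, per_taxon, categories)
  out <- list(predator = unique(x$predator),
              n_scats = n_scats(x),
              weighting = weighting,
              per_taxon = per_taxon,
              per_category = per_category,
              niche_breadth_B = levins_niche_breadth(bio))
  class(out) <- "diet_composition"
  out
}

#' @export
print.diet_composition <- function(x, digits = 1, ...) {
  cat(sprintf("Diet composition of %s (n = %d scats, %s weighting)\n",
              x$predator, x$n_scats, x$weighting))
  tab <- x$per_taxon
  ord <- order(tab$category, -tab$bio_pct)
  tab <- tab[ord, ]
  tab[c("occ_pct", "vol_pct", "bio_pct")] <-
    round(tab[c("occ_pct", "vol_pct", "bio_pct")], digits)
  print.data.frame(tab, row.names = FALSE)
  if (!is.null(x$per_category)) {
    cat("By category:\n")
    pc <- x$per_category
    pc[c("occ_pct", "vol_pct", "bio_pct")] <-
      round(pc[c("occ_pct", "vol_pct", "bio_pct")], digits)
    print.data.frame(pc, row.names = FALSE)
  }
  cat(sprintf("Niche breadth B = %.2f\n", x$niche_breadth_B))
  invisible(x)
}

check_single_predator <- function(x) {
  if (!inherits(x, "scat_table")) x <- scat_table(x)
  if (nrow(x) == 0) stop("empty scat table", call. = FALSE)
  if (length(unique(x$predator)) > 1)
    stop("scat table contains more than one predator; filter first",
         call. = FALSE)
  invisible(x)
}
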