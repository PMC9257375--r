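# shared builders for tests: everything constructed in code, no files

# scat table from a list of per-scat item lists; items may be a character
# vector (even split) or a named numeric vector of fractions
mk_scats <- function(items, predator = "toy", prefix = "S") {
  rows <- do.call(rbind, lapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (is.character(it)) it <- stats::setNames(rep(1 / length(it),
                                                    length(it)), it)
    data.frame(scat_id = sprintf("%s%02d", prefix, i), predator = predator,
               prey_taxon = names(it), volume_fraction = as.numeric(it),
               stringsAsFactors = FALSE)
  }))
  scat_table(rows)
}

nepl_cf <- function(predator) {
  ref <- nepl_reference()
  pr <- ref$predators[[predator]]
  build_correction_table(predator, pr$mass_kg, unlist(pr$killed_mass_kg))
}

nepl_categories <- function() unlist(nepl_reference()$categories)

nepl_avail <- function() available_biomass(density_table(nepl_reference()))

# published diet-table columns used as oracle values
tbl1 <- list(
  clouded_leopard = list(
    bio = c(wild_pig = 33.3, serow = 13.3, hog_badger = 28.4, civet = 4.2,
            brush_tailed_porcupine = 3.1, small_rodent = 14.7, bird = 3.0),
    vol = c(wild_pig = 23.8, serow = 9.5, hog_badger = 21.4, civet = 3.6,
            brush_tailed_porcupine = 3.6, small_rodent = 31.6, bird = 6.4),
    occ = c(wild_pig = 28.6, serow = 14.3, hog_badger = 28.6, civet = 7.1,
            brush_tailed_porcupine = 7.1, small_rodent = 50.0, bird = 14.3),
    B = 4.27),
  tiger = list(
    bio = c(wild_pig = 43.8, serow = 18.0, sambar = 12.2, muntjac = 7.2,
            hog_badger = 5.6, civet = 2.4, black_bear = 9.6, macaque = 1.4),
    vol = c(wild_pig = 44.0, serow = 13.1, sambar = 8.7, muntjac = 8.7,
            hog_badger = 9.5, civet = 4.8, black_bear = 8.7, macaque = 2.4),
    occ = c(wild_pig = 52.4, serow = 19.0, sambar = 14.3, muntjac = 14.3,
            hog_badger = 14.3, civet = 4.8, black_bear = 14.3,
            macaque = 4.8),
    B = 3.89))

# a random feasible co-occurrence plan with the same multi-occurrence
# multiset as the packaged plan: reshuffles taxa across multi-item scats
# (rejection sampling against within-scat distinctness and volume
# feasibility, checked by reconstruct_fixture itself)
random_plan_fixture <- function(predator, max_tries = 200) {
  m <- nepl_marginals(predator)
  base <- nepl_cooccurrence_plan(predator)
  sizes <- lengths(base)
  pool <- unlist(base)
  for (i in seq_len(max_tries)) {
    shuffled <- sample(pool)
    plan <- split(shuffled, rep(seq_along(sizes), sizes))
    if (any(vapply(plan, anyDuplicated, 0) > 0)) next
    out <- try(reconstruct_fixture(m$occurrence_counts, m$n_scats,
                                   unname(plan), m$vol_pct,
                                   predator = predator),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("no feasible random plan found in ", max_tries, " tries")
}
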