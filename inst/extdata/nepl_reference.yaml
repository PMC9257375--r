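# Reference values for the NEPL (northern Laos) example analysis.
# Predator masses are range medians; killed-prey masses are the assumed
# masses of individuals actually killed (half adult-female mass where the
# predator is assumed to take young up to adult females; civet mass is the
# mean of the three common civet species: 8.5, 2.5 and 4 kg).
predators:
  clouded_leopard:
    mass_kg: 17.0
    killed_mass_kg:
      wild_pig: 37.5
      serow: 55.0
      hog_badger: 10.5
      civet: 5.0
      brush_tailed_porcupine: 2.75
      small_rodent: 0.5
      bird: 0.5
  tiger:
    mass_kg: 172.5
    killed_mass_kg:
      wild_pig: 38.0
      serow: 135.0
      sambar: 212.0
      muntjac: 24.0
      black_bear: 50.0
      hog_badger: 10.5
      civet: 5.0
      macaque: 10.0
categories:
  wild_pig: ungulate
  serow: ungulate
  sambar: ungulate
  muntjac: ungulate
  hog_badger: carnivore
  civet: carnivore
  black_bear: carnivore
  macaque: other
  brush_tailed_porcupine: rodent
  small_rodent: rodent
  bird: bird
# Ungulate densities (individuals/km^2, grid-based occupancy survey) and
# adult-female masses (kg) used for available-biomass; gaur has no mass
# on record and is excluded from electivity.
availability:
  muntjac:
    density: 1.50
    se: 0.11
    female_mass_kg: 20.0
  wild_pig:
    density: 3.19
    se: 0.15
    female_mass_kg: 75.0
  sambar:
    density: 0.36
    se: 0.01
    female_mass_kg: 185.0
  serow:
    density: 0.22
    se: 0.02
    female_mass_kg: 85.0
  gaur:
    density: 0.02
    se: 0.003
    female_mass_kg: null
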