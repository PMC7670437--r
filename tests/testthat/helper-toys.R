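# Tiny hand-built molecules and components shared across tests.

# two unit-area segments 1 A apart with opposite charge densities
toy_two_segments <- function(sigma = 0.01) {
  cosmo_molecule(
    name = "two-seg",
    atoms = data.frame(element = "C", x = 0.5, y = 0, z = 0),
    segments = data.frame(
      atom_index = c(1L, 1L),
      x = c(0, 1), y = 0, z = 0,
      charge = c(sigma, -sigma), area = 1,
      charge_density = c(sigma, -sigma), potential = 0
    ),
    cavity_volume = 5
  )
}

# a molecule and its charge-mirrored twin (all sigma negated)
mirror_molecule <- function(mol) {
  seg <- mol$segments
  seg$charge <- -seg$charge
  seg$charge_density <- -seg$charge_density
  cosmo_molecule(paste0(mol$name, "-mirrored"), mol$atoms, seg,
                 total_area = mol$total_area,
                 cavity_volume = mol$cavity_volume)
}

toy_binary_components <- function(seed_a = 1L, seed_b = 2L) {
  list(
    cosmo_component(make_toy_molecule(seed = seed_a)),
    cosmo_component(make_toy_molecule(seed = seed_b, total_area = 150,
                                      cavity_volume = 140))
  )
}

toy_hb_binary_components <- function() {
  list(
    cosmo_component(make_toy_molecule(pattern = "donor-acceptor-pair",
                                      hb_fraction = 0.4, seed = 3L)),
    cosmo_component(make_toy_molecule(seed = 4L, total_area = 150,
                                      cavity_volume = 140))
  )
}

toy_fh_records <- function() {
  rbind(
    hansen_record("solute", 19, 8, 6, V = 120),
    hansen_record("solvent", 16, 9, 10, V = 60)
  )
}
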