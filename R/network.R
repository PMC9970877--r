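# Thermodynamically annotated reduced metabolic network.
#
# The container holds a species table (carbon content, molar mass,
# transformed formation energy, exchanged flag), a reaction table
# (stoichiometry, bounds), a biomass-assembly template whose
# per-component molar coefficients are rescaled phase by phase, the
# model's reference biomass composition c_model, the biomass molar mass
# and the Gibbs-dissipation cap. The shipped fixture
# (inst/extdata/network_synthetic.json) is a synthetic ~18-reaction
# glucose/ethanol/respiration network with lumped component-synthesis
# reactions -- illustrative stoichiometry, not a published model.

#' Read a thermodynamically annotated reduced network
#'
#' @param path JSON file with `species` (id, carbon, mass_g_mmol, dfG,
#'   exchanged), `reactions` (id, stoich as named coefficient map, lb,
#'   ub), `biomass` (component ids and reference mass fractions
#'   `c_model`), `M_biomass` (g/mmol) and `g_lim` (J/gDW/h).
#' @return object of class `cycleflux_network`.
#' @export
read_thermo_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- do.call(rbind, lapply(j$species, function(s)
    data.frame(id = s$id, carbon = s$carbon,
               mass_g_mmol = s$mass_g_mmol,
               dfG = if (is.null(s$dfG)) NA_real_ else s$dfG,
               exchanged = isTRUE(s$exchanged))))
  reactions <- lapply(j$reactions, function(r)
    list(id = r$id, stoich = unlist(r$stoich), lb = r$lb, ub = r$ub))
  network(species, reactions, c_model = unlist(j$biomass$c_model),
          M_biomass = j$M_biomass, g_lim = j$g_lim)
}

#' Construct a network object
#'
#' @param species data.frame: `id`, `carbon`, `mass_g_mmol`, `dfG`
#'   (kJ/mol; `NA` allowed for species never crossing the boundary),
#'   `exchanged` (logical).
#' @param reactions list of lists: `id`, `stoich` (named numeric,
#'   negative = consumed), `lb`, `ub`.
#' @param c_model named reference mass fractions of the biomass
#'   components (protein, lipid, polysacch, DNA, RNA, storage).
#' @param M_biomass biomass molar mass (g/mmol).
#' @param g_lim Gibbs-dissipation cap (J/gDW/h).
#' @return object of class `cycleflux_network` with the stoichiometric
#'   matrix `S` (species x reactions), bounds, and component bookkeeping.
#' @export
network <- function(species, reactions, c_model, M_biomass = 0.966,
                    g_lim = 12.3) {
  if (g_lim <= 0) cf_stop("g_lim must be positive")
  rids <- vapply(reactions, `[[`, character(1), "id")
  S <- matrix(0, nrow(species), length(reactions),
              dimnames = list(species$id, rids))
  for (i in seq_along(reactions)) {
    st <- reactions[[i]]$stoich
    if (!all(names(st) %in% species$id))
      cf_stop(paste("unknown species in reaction", rids[i]))
    S[names(st), i] <- st
  }
  lb <- vapply(reactions, `[[`, numeric(1), "lb")
  ub <- vapply(reactions, `[[`, numeric(1), "ub")
  names(lb) <- names(ub) <- rids
  comp <- intersect(names(c_model), species$id)
  if (length(comp) != length(c_model))
    cf_stop("every biomass component needs a species entry")
  # carbon balance audit of non-boundary reactions
  carbon <- stats::setNames(species$carbon, species$id)
  boundary <- grepl("^EX_", rids)
  imb <- as.numeric(carbon %*% S)
  bad <- which(!boundary & abs(imb) > 1e-6 &
                 colnames(S) != "BIOMASS")
  if (length(bad))
    cf_stop(paste("carbon-unbalanced internal reaction(s):",
                  paste(rids[bad], collapse = ", ")))
  structure(list(species = species, S = S, lb = lb, ub = ub,
                 c_model = c_model, M_biomass = M_biomass,
                 g_lim = g_lim, boundary = boundary),
            class = "cycleflux_network")
}

#' @export
print.cycleflux_network <- function(x, ...) {
  cat("<thermo network>", nrow(x$S), "species,", ncol(x$S),
      "reactions; g_lim =", x$g_lim, "J/gDW/h\n")
  invisible(x)
}

#' Built-in synthetic reduced network
#'
#' A small glucose-fed network with lumped glycolysis, fermentation to
#' ethanol + CO2, respiration, ATP maintenance, six component-synthesis
#' lumps with distinct ATP/NADH/precursor costs, and a biomass assembly
#' reaction. Stoichiometries are carbon-balanced but synthetic;
#' formation energies are chosen so the default dissipation cap is the
#' binding constraint under fermentative operation.
#'
#' @return a `cycleflux_network`.
#' @export
example_network <- function() {
  read_thermo_network(system.file("extdata", "network_synthetic.json",
                                  package = "cycleflux"))
}
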