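#' Physical constants used throughout the package
#'
#' Ideal gas constant `R` (J K^-1 mol^-1) and Faraday's constant `F`
#' (C mol^-1), fixed at the printed precision used by the model.
#'
#' @format A named list with elements `R` and `F`.
#' @export
physical_constants <- list(R = 8.314472, F = 9.648533e4)

# Valences of the free ions the stoichiometry table can produce.
.ion_registry <- c(Na = 1L, K = 1L, Mg = 2L, Ca = 2L, Cl = -1L, F = -1L)

# Formula-unit ion counts for the supported salts.  Solutes that do not
# dissociate into free ions at these concentrations (sugars, buffers,
# chelators) are listed separately and ignored with a note.
.salt_table <- list(
  NaCl  = c(Na = 1, Cl = 1),
  KCl   = c(K = 1, Cl = 1),
  KF    = c(K = 1, F = 1),
  MgCl2 = c(Mg = 1, Cl = 2),
  CaCl2 = c(Ca = 1, Cl = 2),
  NaF   = c(Na = 1, F = 1)
)
.nondissociating <- c("glucose", "HEPES", "EGTA", "sucrose")

#' Define an ion species
#'
#' @param name Ion label, e.g. `"K"` or `"Mg"`.
#' @param valence Signed integer charge per ion; must be nonzero. When
#'   omitted, looked up from the built-in registry (Na, K, Mg, Ca, Cl, F).
#' @return An object of class `ion_species` with fields `name` and `valence`.
#' @examples
#' ion_species("K")
#' ion_species("Gluconate", valence = -1)
#' @export
ion_species <- function(name, valence = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(valence)) {
    if (!name %in% names(.ion_registry))
      stop("unknown ion '", name, "': supply a valence explicitly",
           call. = FALSE)
    valence <- .ion_registry[[name]]
  }
  valence <- as.integer(valence)
  if (is.na(valence) || valence == 0L)
    stop("ion valence must be a nonzero integer", call. = FALSE)
  structure(list(name = name, valence = valence), class = "ion_species")
}

.as_ion_list <- function(ions) {
  if (inherits(ions, "ion_species")) ions <- list(ions)
  ions <- lapply(ions, function(x) {
    if (inherits(x, "ion_species")) x else ion_species(x)
  })
  nm <- vapply(ions, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated ion in ion list", call. = FALSE)
  ions
}

#' Free-ion composition of a solution
#'
#' @param concentrations_mM Named numeric vector, mM per ion; all >= 0.
#' @param temperature_K Absolute temperature, default 298.15 K.
#' @param label Optional label.
#' @return An object of class `ionic_composition`.
#' @export
ionic_composition <- function(concentrations_mM, temperature_K = 298.15,
                              label = NULL) {
  conc <- unlist(concentrations_mM)
  if (length(conc) && is.null(names(conc)))
    stop("concentrations must be named by ion", call. = FALSE)
  if (anyDuplicated(names(conc)))
    stop("duplicated ion name in composition", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  structure(list(concentrations_mM = conc,
                 temperature_K = temperature_K, label = label),
            class = "ionic_composition")
}

#' @export
print.ionic_composition <- function(x, ...) {
  cat("Ionic composition", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "at", x$temperature_K, "K\n")
  if (!length(x$concentrations_mM)) {
    cat("  (empty)\n")
  } else {
    for (nm in names(x$concentrations_mM))
      cat(sprintf("  %-4s %8.3f mM\n", nm, x$concentrations_mM[[nm]]))
  }
  invisible(x)
}

.conc_of <- function(comp, ion) {
  c <- comp$concentrations_mM
  if (ion %in% names(c)) unname(c[[ion]]) else 0
}

#' Salt recipe of a physiological solution
#'
#' @param salts Named numeric vector: salt formula -> concentration (mM).
#'   Supported formulas: `r paste(names(.salt_table), collapse = ", ")`.
#' @param nondissociating Named numeric vector of solutes that contribute no
#'   free ions (glucose, HEPES, EGTA, ...); recorded but ignored by
#'   [dissociate()].
#' @param temperature_K Absolute temperature (K).
#' @param label Optional label.
#' @return An object of class `salt_recipe`.
#' @examples
#' extracellular <- salt_recipe(
#'   c(NaCl = 160, KCl = 4.5, MgCl2 = 1, CaCl2 = 2),
#'   nondissociating = c(glucose = 5, HEPES = 10),
#'   label = "extracellular")
#' dissociate(extracellular)
#' @export
salt_recipe <- function(salts, nondissociating = NULL,
                        temperature_K = 298.15, label = NULL) {
  salts <- unlist(salts)
  if (length(salts) && is.null(names(salts)))
    stop("salts must be a named vector (formula -> mM)", call. = FALSE)
  if (any(!is.finite(salts)) || any(salts < 0))
    stop("salt concentrations must be finite and >= 0", call. = FALSE)
  unknown <- setdiff(names(salts), names(.salt_table))
  if (length(unknown))
    stop("unknown salt formula(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(salts = salts, nondissociating = unlist(nondissociating),
                 temperature_K = temperature_K, label = label),
            class = "salt_recipe")
}

#' Expand a salt recipe into its free-ion composition
#'
#' Each salt contributes its formula-unit ion counts times its concentration;
#' listed non-dissociating solutes are skipped with an informational note.
#' Full dissociation is assumed (free-ion concentrations, no activity
#' corrections).
#'
#' @param recipe A [salt_recipe()].
#' @param quiet Suppress the note about ignored solutes.
#' @return An [ionic_composition()] at the recipe's temperature.
#' @export
dissociate <- function(recipe, quiet = FALSE) {
  stopifnot(inherits(recipe, "salt_recipe"))
  conc <- numeric(0)
  for (salt in names(recipe$salts)) {
    mM <- recipe$salts[[salt]]
    for (ion in names(.salt_table[[salt]])) {
      add <- mM * .salt_table[[salt]][[ion]]
      conc[ion] <- if (ion %in% names(conc)) conc[[ion]] + add else add
    }
  }
  extra <- recipe$nondissociating
  if (!quiet && length(extra))
    message("dissociate: ignoring non-dissociating solute(s): ",
            paste(names(extra), collapse = ", "))
  ionic_composition(conc, recipe$temperature_K, recipe$label)
}

#' Read a solution recipe from a config file
#'
#' The file is YAML with keys `label`, `temperature_K`, `salts`
#' (formula -> mM) and optionally `nondissociating`.  Two recipes matching
#' the standard extracellular and intracellular patch solutions ship with
#' the package; see the example.
#'
#' @param path Path to the recipe file.
#' @return A [salt_recipe()].
#' @examples
#' path <- system.file("extdata", "intracellular.cfg", package = "cytoclamp")
#' dissociate(read_recipe(path))
#' @export
read_recipe <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$salts))
    stop("recipe file has no 'salts' section: ", path, call. = FALSE)
  salt_recipe(unlist(cfg$salts),
              nondissociating = cfg$nondissociating,
              temperature_K = if (is.null(cfg$temperature_K)) 298.15
                              else cfg$temperature_K,
              label = cfg$label)
}

#' Nernst equilibrium potential of a single ion
#'
#' E = (RT / ZF) ln(c_out / c_in), returned in mV.  Concentration ratios are
#' unit-free, so mM in and mM out is fine.
#'
#' @param ion An [ion_species()] or an ion name known to the registry.
#' @param c_out,c_in Outside / inside concentrations (mM), both > 0.
#' @param temperature_K Absolute temperature (K), > 0.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential("K", 4.5, 149.6)    # about -90 mV
#' nernst_potential("Na", 160, 15.48)   # about +60 mV
#' @export
nernst_potential <- function(ion, c_out, c_in, temperature_K = 298.15) {
  if (!inherits(ion, "ion_species")) ion <- ion_species(ion)
  if (!is.finite(c_out) || !is.finite(c_in) || c_out <= 0 || c_in <= 0)
    stop("Nernst potential needs strictly positive concentrations ",
         "(logarithm undefined at zero)", call. = FALSE)
  stopifnot(temperature_K > 0)
  with(physical_constants,
       1000 * R * temperature_K / (ion$valence * F) * log(c_out / c_in))
}

#' Multi-ion membrane battery
#'
#' Sum of per-ion Nernst terms over a caller-supplied ion list: the additive
#' form used by the equivalent model (not a conductance-weighted GHK
#' potential).  Ions whose contribution is considered negligible are simply
#' left off the list by the caller.
#'
#' @param outside,inside [ionic_composition()] objects; every listed ion must
#'   be present with positive concentration on both sides.
#' @param ions Character vector of ion names or list of [ion_species()].
#' @return Membrane battery potential in mV.
#' @examples
#' out <- ionic_composition(c(Na = 160, K = 4.5))
#' inn <- ionic_composition(c(Na = 15.48, K = 149.6))
#' membrane_battery(out, inn, c("Na", "K"))   # about -30 mV
#' @export
membrane_battery <- function(outside, inside, ions) {
  stopifnot(inherits(outside, "ionic_composition"),
            inherits(inside, "ionic_composition"))
  ions <- .as_ion_list(ions)
  sum(vapply(ions, function(ion) {
    co <- .conc_of(outside, ion$name)
    ci <- .conc_of(inside, ion$name)
    if (co <= 0 || ci <= 0)
      stop("ion '", ion$name,
           "' missing (or nonpositive) on one side of the membrane",
           call. = FALSE)
    nernst_potential(ion, co, ci, inside$temperature_K)
  }, numeric(1)))
}

#' Instantaneous conservative mixing of injectate into cytoplasm
#'
#' Mass balance per ion: c_new = (c_cyto V_cell + c_inj V_inj) /
#' (V_cell + V_inj).  The extracellular side is untouched; no osmotic volume
#' change is modelled.
#'
#' @param cytoplasm [ionic_composition()] of the cytoplasm before injection.
#' @param cell_volume_pL Cell volume (pL), > 0.
#' @param injectate [ionic_composition()] of the injected solution.
#' @param injected_volume_pL Injected volume (pL), >= 0.
#' @return The post-injection cytoplasmic [ionic_composition()].
#' @examples
#' cyto <- ionic_composition(c(K = 155))
#' inj  <- ionic_composition(c(K = 145))
#' mix_injection(cyto, 23.2, inj, 19)   # K about 150.5 mM
#' @export
mix_injection <- function(cytoplasm, cell_volume_pL, injectate,
                          injected_volume_pL) {
  stopifnot(inherits(cytoplasm, "ionic_composition"),
            inherits(injectate, "ionic_composition"))
  if (!is.finite(cell_volume_pL) || cell_volume_pL <= 0)
    stop("cell volume must be > 0 pL", call. = FALSE)
  if (!is.finite(injected_volume_pL) || injected_volume_pL < 0)
    stop("injected volume must be >= 0 pL", call. = FALSE)
  ions <- union(names(cytoplasm$concentrations_mM),
                names(injectate$concentrations_mM))
  vt <- cell_volume_pL + injected_volume_pL
  conc <- vapply(ions, function(ion) {
    (.conc_of(cytoplasm, ion) * cell_volume_pL +
       .conc_of(injectate, ion) * injected_volume_pL) / vt
  }, numeric(1))
  ionic_composition(conc, cytoplasm$temperature_K, cytoplasm$label)
}

#' Injection potential from pre/post cytoplasmic compositions
#'
#' The battery hypothesised to appear when injected solution mixes with the
#' cytoplasm: the new membrane battery minus the old one, both taken against
#' the same (unchanged) extracellular composition.
#'
#' @param outside Extracellular [ionic_composition()].
#' @param inside_old,inside_new Cytoplasmic compositions before/after mixing.
#' @param ions Ion list as in [membrane_battery()].
#' @return E_Injection in mV.
#' @export
injection_potential <- function(outside, inside_old, inside_new, ions) {
  membrane_battery(outside, inside_new, ions) -
    membrane_battery(outside, inside_old, ions)
}

#' Default cell volume (pL) of a small adherent cell
#'
#' Ellipsoid estimate for a cell under 30 um across and under 10 um thick;
#' used only as a default for mixing calculations, never inside operations.
#' @export
default_cell_volume_pL <- 2.5
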