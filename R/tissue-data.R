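#' Elemental constants table
#'
#' Atomic number, atomic mass and mean excitation energy (I-value) for the
#' elements occurring in the packaged tissue compositions. The I-values are the
#' ICRU-recommended condensed-phase elemental values (H 19.2, C 81, N 82,
#' O 106, Na 149, P 173, S 180, Ca 191 eV). Because compound I-values are
#' convention-sensitive, the table is an ordinary tibble that callers may
#' modify and pass back into any of the physics functions.
#'
#' @return A tibble with columns `symbol`, `atomic_number`, `atomic_mass`
#'   (g/mol) and `i_ev` (eV).
#' @export
#' @examples
#' element_table()
element_table <- function() {
  path <- system.file("extdata", "elements.csv", package = "mrirsp", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Tissue-substitute phantom ground truth
#'
#' Measured mass density (g/cm^3), proton relative stopping power at 150 MeV,
#' mean excitation energy (eV) and elemental mass fractions for the five
#' tissue-substitute phantoms (skin, muscle, adipose, spongiosa, 45%
#' hydroxyapatite bone) and the two animal-tissue phantoms (pig brain, pig
#' liver). Mass percents are converted to fractions in \[0, 1\] at load time.
#'
#' @param validate Check row invariants (fractions in \[0,1\], compositions
#'   summing to 1 within 0.005, positive density/RSP/I). Default `TRUE`.
#' @return A tibble with one row per phantom: `tissue`, `density`, `rsp`,
#'   `i_ev`, and one mass-fraction column per element symbol.
#' @export
#' @examples
#' tissue_table()
tissue_table <- function(validate = TRUE) {
  path <- system.file("extdata", "tissues.csv", package = "mrirsp", mustWork = TRUE)
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  el <- setdiff(names(tab), c("tissue", "density", "rsp", "i_ev"))
  tab[el] <- tab[el] / 100
  if (validate) validate_tissues(tab)
  tab
}

#' Phantom mixing recipes
#'
#' Ingredient mass fractions (water, porcine gelatin, porcine lard,
#' hydroxyapatite, SDS surfactant) used to mix each tissue-substitute phantom.
#'
#' @return A tibble with one row per tissue-substitute phantom; ingredient
#'   columns are mass fractions in \[0, 1\].
#' @export
recipe_table <- function() {
  path <- system.file("extdata", "recipes.csv", package = "mrirsp", mustWork = TRUE)
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  ing <- setdiff(names(tab), "tissue")
  tab[ing] <- tab[ing] / 100
  tab
}

# Column names that are never interpreted as element symbols.
.reserved_cols <- c(
  "tissue", "density", "rsp", "i_ev", "z_over_a", "rho_e", "i_bragg",
  "rsp_theoretical", "z_eff"
)

#' Construct a single tissue specification
#'
#' Convenience constructor for ad-hoc materials: element mass fractions are
#' given as named arguments and become one wide tibble row compatible with
#' [tissue_table()].
#'
#' @param tissue Material name.
#' @param ... Named element mass fractions in \[0, 1\], e.g. `H = 0.1119`.
#' @param density Mass density in g/cm^3 (optional).
#' @param rsp Measured relative stopping power (optional).
#' @param i_ev Mean excitation energy in eV (optional).
#' @return A one-row tibble.
#' @export
#' @examples
#' tissue_spec("water", H = 0.1119, O = 0.8881, density = 1.0)
tissue_spec <- function(tissue, ..., density = NA_real_, rsp = NA_real_,
                        i_ev = NA_real_) {
  fr <- list(...)
  if (length(fr) == 0L) abort("a tissue specification needs at least one element")
  if (is.null(names(fr)) || any(names(fr) == "")) {
    abort("element mass fractions must be named by element symbol")
  }
  vals <- vapply(fr, as.numeric, numeric(1))
  if (any(vals < 0 | vals > 1)) abort("mass fractions must lie in [0, 1]")
  tibble(tissue = tissue, density = density, rsp = rsp, i_ev = i_ev, !!!fr)
}

#' Reference water composition
#'
#' @return One-row tissue tibble for liquid water (H 11.19%, O 88.81%) at
#'   1.000 g/cm^3.
#' @export
water_spec <- function() {
  tissue_spec("water", H = 0.1119, O = 0.8881, density = 1.0, rsp = 1.0, i_ev = 75)
}

validate_tissues <- function(tissues) {
  el <- setdiff(names(tissues), .reserved_cols)
  fr <- as.matrix(tissues[el])
  if (any(fr < 0 | fr > 1)) abort("element mass fractions must lie in [0, 1]")
  tot <- rowSums(fr)
  bad <- abs(tot - 1) > 0.005
  if (any(bad)) {
    abort(sprintf(
      "composition of %s sums to %.4f, not 1",
      tissues$tissue[which(bad)[1]], tot[which(bad)[1]]
    ))
  }
  for (col in intersect(c("density", "rsp", "i_ev"), names(tissues))) {
    v <- tissues[[col]]
    if (any(!is.na(v) & v <= 0)) abort(sprintf("column '%s' must be positive", col))
  }
  invisible(tissues)
}

# Internal: N x n_element fraction matrix aligned with `elements`, erroring on
# any element column not present in the constants table.
composition_matrix <- function(tissues, elements) {
  el <- setdiff(names(tissues), .reserved_cols)
  if (length(el) == 0L) abort("tissue table has no element columns")
  unknown <- setdiff(el, elements$symbol)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  m <- as.matrix(tissues[el])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0     # an absent element is a zero mass fraction
  m
}

#' Mean Z/A of a material
#'
#' Appends `z_over_a`, the mass-fraction-weighted mean ratio of atomic number
#' to atomic mass, \eqn{\sum_i w_i Z_i / A_i} (mol electrons per gram relative
#' quantity). Linear in the mass fractions; fractions are used as given, with
#' no renormalization.
#'
#' @param tissues Tissue tibble (see [tissue_table()], [tissue_spec()]).
#' @param elements Elemental constants, see [element_table()].
#' @return `tissues` with a `z_over_a` column appended.
#' @export
#' @examples
#' tissue_table() |> z_over_a()
z_over_a <- function(tissues, elements = element_table()) {
  m <- composition_matrix(tissues, elements)
  za <- elements$atomic_number / elements$atomic_mass
  names(za) <- elements$symbol
  tissues$z_over_a <- as.vector(m %*% za[colnames(m)])
  tissues
}

# Z/A of the water reference, computed from its two-element composition.
water_z_over_a <- function(elements = element_table()) {
  z_over_a(water_spec(), elements)$z_over_a
}

#' Relative electron density
#'
#' Appends `rho_e`, the electron density relative to water at 1.000 g/cm^3:
#' \eqn{\rho_e = \rho \, (Z/A)_{material} / (Z/A)_{water}}. This is the
#' quantity a dual-energy CT material decomposition reports, and the one the
#' empirical conversion models consume.
#'
#' @inheritParams z_over_a
#' @param density Optional numeric vector of densities in g/cm^3 overriding
#'   the `density` column.
#' @return `tissues` with a `rho_e` column appended.
#' @export
#' @examples
#' tissue_table() |> relative_electron_density()
relative_electron_density <- function(tissues, elements = element_table(),
                                      density = NULL) {
  density <- density %||% tissues$density
  if (is.null(density)) abort("no density column or argument supplied")
  if (any(!is.finite(density)) || any(density <= 0)) {
    abort("density must be positive and finite")
  }
  tissues <- z_over_a(tissues, elements)
  tissues$rho_e <- density * tissues$z_over_a / water_z_over_a(elements)
  tissues
}

#' Mean excitation energy by Bragg additivity
#'
#' Appends `i_bragg`, the compound I-value from the Bragg additivity rule:
#' \deqn{\ln I = \frac{\sum_i w_i (Z_i/A_i) \ln I_i}{\sum_i w_i Z_i/A_i}.}
#' The result is invariant to uniform rescaling of the mass fractions and is
#' bounded by the smallest and largest elemental I-values present.
#'
#' Measured compound I-values are sensitive to the elemental convention used
#' (condensed-phase vs gas, and whether bound water is treated as a compound);
#' expect agreement with measured tables at the few-percent level only.
#'
#' @inheritParams z_over_a
#' @return `tissues` with an `i_bragg` column (eV) appended.
#' @export
#' @examples
#' water_spec() |> bragg_additivity_I()   # ~75.3 eV
bragg_additivity_I <- function(tissues, elements = element_table()) {
  m <- composition_matrix(tissues, elements)
  if (any(rowSums(m) <= 0)) abort("empty composition")
  za <- elements$atomic_number / elements$atomic_mass
  names(za) <- elements$symbol
  li <- log(elements$i_ev)
  names(li) <- elements$symbol
  wza <- sweep(m, 2, za[colnames(m)], "*")
  tissues$i_bragg <- exp(as.vector(wza %*% li[colnames(m)]) / rowSums(wza))
  tissues
}

#' Effective atomic number (power law)
#'
#' Appends `z_eff`, the power-law effective atomic number
#' \deqn{Z_{eff} = \left(\frac{\sum_i w_i (Z_i/A_i) Z_i^m}{\sum_i w_i Z_i/A_i}\right)^{1/m}}
#' with exponent `m = 3.1` by default (a common spectral-CT convention).
#'
#' @inheritParams z_over_a
#' @param m Power-law exponent.
#' @return `tissues` with a `z_eff` column appended.
#' @export
#' @examples
#' water_spec() |> effective_atomic_number()   # ~7.45
effective_atomic_number <- function(tissues, elements = element_table(), m = 3.1) {
  cm <- composition_matrix(tissues, elements)
  za <- elements$atomic_number / elements$atomic_mass
  zm <- elements$atomic_number^m
  names(za) <- names(zm) <- elements$symbol
  wza <- sweep(cm, 2, za[colnames(cm)], "*")
  tissues$z_eff <- (as.vector(wza %*% zm[colnames(cm)]) / rowSums(wza))^(1 / m)
  tissues
}

#' Proton beam specification
#'
#' The measurement beam and the water reference entering the Bethe stopping
#' power ratio. Defaults are the 150 MeV proton spot used for phantom
#' water-equivalent-thickness measurements, I_water = 75 eV, and Z/A of water
#' computed from its composition.
#'
#' @param kinetic_energy_mev Proton kinetic energy, MeV.
#' @param water_i_ev Water mean excitation energy, eV.
#' @param water_z_over_a Z/A of water; computed from composition if `NULL`.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(kinetic_energy_mev = 150, water_i_ev = 75,
                      water_z_over_a = NULL) {
  if (kinetic_energy_mev <= 0) abort("kinetic energy must be positive")
  if (water_i_ev <= 0) abort("water I-value must be positive")
  structure(
    list(
      kinetic_energy_mev = kinetic_energy_mev,
      water_i_ev = water_i_ev,
      water_z_over_a = water_z_over_a
    ),
    class = "beam_spec"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> %g MeV protons, I_water = %g eV\n",
    x$kinetic_energy_mev, x$water_i_ev
  ))
  invisible(x)
}

# beta^2 of a proton with kinetic energy T (MeV).
proton_beta_sq <- function(kinetic_energy_mev) {
  gamma <- 1 + kinetic_energy_mev / PROTON_REST_MEV
  1 - 1 / gamma^2
}

#' Theoretical relative stopping power (Bethe ratio)
#'
#' Appends `rsp_theoretical`, the ratio of the material's Bethe mass stopping
#' power to water's, scaled by relative electron density:
#' \deqn{RSP = \rho_e \,
#'   \frac{\ln(2 m_e c^2 \beta^2 / (I (1-\beta^2))) - \beta^2}
#'        {\ln(2 m_e c^2 \beta^2 / (I_w (1-\beta^2))) - \beta^2}.}
#' Used to cross-check measured RSP values from composition, density and I.
#'
#' @inheritParams relative_electron_density
#' @param beam A [beam_spec()].
#' @param i_ev Optional numeric vector of I-values (eV) overriding the `i_ev`
#'   column.
#' @return `tissues` with `rho_e` and `rsp_theoretical` columns appended.
#' @export
#' @examples
#' tissue_table() |> theoretical_rsp()
theoretical_rsp <- function(tissues, beam = beam_spec(),
                            elements = element_table(), density = NULL,
                            i_ev = NULL) {
  i_ev <- i_ev %||% tissues$i_ev
  if (is.null(i_ev)) abort("no i_ev column or argument supplied")
  beta2 <- proton_beta_sq(beam$kinetic_energy_mev)
  # Maximum energy-transfer argument of the Bethe logarithm, in eV.
  arg_max <- 2 * ELECTRON_REST_MEV * 1e6 * beta2 / (1 - beta2)
  if (any(i_ev <= 0) || any(i_ev >= arg_max)) {
    abort(sprintf(
      "I-values must lie in (0, %.0f) eV at %g MeV",
      arg_max, beam$kinetic_energy_mev
    ))
  }
  tissues <- relative_electron_density(tissues, elements, density = density)
  if (!is.null(beam$water_z_over_a)) {
    dens <- density %||% tissues$density
    tissues$rho_e <- dens * tissues$z_over_a / beam$water_z_over_a
  }
  num <- log(arg_max / i_ev) - beta2
  den <- log(arg_max / beam$water_i_ev) - beta2
  tissues$rsp_theoretical <- tissues$rho_e * num / den
  tissues
}

#' RSP from water-equivalent thickness
#'
#' The measurement-side definition: relative stopping power is the measured
#' water-equivalent thickness divided by the physical sample thickness.
#'
#' @param wet_mm Water-equivalent thickness, mm.
#' @param thickness_mm Physical thickness, mm. Must be positive.
#' @return Dimensionless RSP, vectorized.
#' @export
#' @examples
#' rsp_from_wet(61.33, 57)
rsp_from_wet <- function(wet_mm, thickness_mm) {
  if (any(thickness_mm <= 0)) abort("thickness must be positive")
  wet_mm / thickness_mm
}
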