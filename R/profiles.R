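#' pH-response profile of a variant's mating efficiency
#'
#' A fitness profile describes a variant's condition-dependent mating
#' efficiency `m` (the per-cycle selection coefficient during
#' mating--germination cycles, a probability in \[0, 1\]) and its vegetative
#' relative fitness `w` (per generation, used only in the non-mating
#' serial-passage regime).
#'
#' Three curve shapes are supported for `m(pH)`:
#' * `"flat"` -- constant `m_max` at every pH (pH-insensitive variants);
#' * `"alkaline"` -- logistic activation,
#'   `m = m_max * plogis((pH - ph_mid) / s)` (low at acidic pH, high at
#'   alkaline pH);
#' * `"acid"` -- the mirrored logistic,
#'   `m = m_max * plogis((ph_mid - pH) / s)`.
#'
#' @param type One of `"flat"`, `"alkaline"`, `"acid"`.
#' @param m_max Maximal mating efficiency in \[0, 1\].
#' @param ph_mid Midpoint pH of the logistic (ignored for `"flat"`).
#' @param s Logistic width in pH units (> 0; ignored for `"flat"`).
#' @param w Vegetative relative fitness per generation (> 0).
#' @return A `fitness_profile` object (list).
#' @examples
#' p <- fitness_profile("alkaline", m_max = 0.5, ph_mid = 6.5, s = 0.4)
#' ph_response(p, 6.5)  # 0.25: the logistic midpoint is m_max / 2
#' @export
fitness_profile <- function(type = c("flat", "alkaline", "acid"),
                            m_max = 0.6, ph_mid = 6.5, s = 0.5, w = 1) {
  type <- match.arg(type)
  stopifnot(m_max >= 0, m_max <= 1, w > 0, s > 0)
  structure(list(type = type, m_max = m_max, ph_mid = ph_mid, s = s, w = w),
            class = "fitness_profile")
}

#' Named profile presets
#'
#' Shorthand constructors for the qualitative pH-response classes observed
#' among M-factor variants:
#' * `"WT-like"` -- broad, pH-insensitive high mating efficiency.
#' * `"P6D-like"` -- acid-activated: mating efficiency at pH 4-5 the highest
#'   in the panel and more than two-fold above its pH 5.5 level, collapsing
#'   to near-sterility at pH >= 6.5.
#' * `"P6H-like"` -- alkaline-activated: near-sterile at the standard pH 5.5,
#'   about half of cells mating at pH >= 7.5.
#' * `"Y7W-like"` -- flat high efficiency across the whole gradient.
#' * `"T2Q-like"` -- antagonistic pleiotropy: elevated mating efficiency at
#'   any pH, reduced vegetative fitness (prolonged lag in rich medium).
#' * `"impaired"` -- low residual mating efficiency, pH-insensitive.
#' * `"dead"` -- zero mating efficiency everywhere.
#'
#' @param name Preset name (see above).
#' @return A `fitness_profile`.
#' @export
profile_preset <- function(name = c("WT-like", "P6D-like", "P6H-like",
                                    "Y7W-like", "T2Q-like", "impaired",
                                    "dead")) {
  name <- match.arg(name)
  switch(name,
    "WT-like"  = fitness_profile("flat", m_max = 0.60, w = 1),
    "P6D-like" = fitness_profile("acid", m_max = 0.65, ph_mid = 5.2,
                                 s = 0.45, w = 1),
    "P6H-like" = fitness_profile("alkaline", m_max = 0.55, ph_mid = 6.5,
                                 s = 0.3, w = 1),
    "Y7W-like" = fitness_profile("flat", m_max = 0.60, w = 1),
    "T2Q-like" = fitness_profile("flat", m_max = 0.75, w = 0.95),
    "impaired" = fitness_profile("flat", m_max = 0.05, w = 1),
    "dead"     = fitness_profile("flat", m_max = 0, w = 1)
  )
}

#' Evaluate a fitness profile's mating efficiency at a given pH
#'
#' @param profile A `fitness_profile`.
#' @param pH Numeric vector of pH values in \[3, 10\].
#' @return Mating efficiency in \[0, 1\], same length as `pH`.
#' @export
ph_response <- function(profile, pH) {
  stopifnot(inherits(profile, "fitness_profile"))
  if (any(pH < 3 | pH > 10)) stop("pH out of bounds [3, 10]")
  m <- switch(profile$type,
    flat     = rep(profile$m_max, length(pH)),
    alkaline = profile$m_max * stats::plogis((pH - profile$ph_mid) / profile$s),
    acid     = profile$m_max * stats::plogis((profile$ph_mid - pH) / profile$s)
  )
  pmin(pmax(m, 0), 1)
}

#' Evaluate mating-efficiency and vegetative-fitness vectors for a library
#'
#' @param profiles Named list of `fitness_profile`s, one per variant id.
#' @param library A `variant_library`; profiles must cover all its variants.
#' @param pH pH at which to evaluate mating efficiency.
#' @return For `efficiency_vector()`, a named numeric vector of `m` values in
#'   library order; for `vegetative_vector()`, the named `w` vector.
#' @export
efficiency_vector <- function(profiles, library, pH) {
  ids <- library$variants$variant_id
  missing <- setdiff(ids, names(profiles))
  if (length(missing) > 0L) {
    stop("profiles missing for variants: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  vapply(profiles[ids], ph_response, numeric(1), pH = pH)
}

#' @rdname efficiency_vector
#' @export
vegetative_vector <- function(profiles, library) {
  ids <- library$variants$variant_id
  vapply(profiles[ids], function(p) p$w, numeric(1))
}

#' Default per-variant fitness profiles for the 153-genotype panel
#'
#' `default_fitness_profiles()` encodes the qualitative fitness classes of
#' the M-factor variant panel as the simulator's ground truth: P6H is
#' alkaline-activated, P6D acid-activated, Y7W flat-high, substitutions at
#' position 2 show the mating/vegetative trade-off, other substitutions at
#' the C-terminal residues 5-8 are impaired, and everything else is WT-like.
#'
#' `recapitulation_profiles()` is the minimal contrast scenario used in
#' validation: exactly one alkaline-activated variant (default `"P6H"`), one
#' acid-activated variant (default `"P6D"`), and flat WT-like profiles for
#' the remaining 151 genotypes.
#'
#' @param library A `variant_library`.
#' @return Named list of `fitness_profile`s covering every library variant.
#' @export
default_fitness_profiles <- function(library) {
  v <- library$variants
  profiles <- vector("list", nrow(v))
  names(profiles) <- v$variant_id
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    profiles[[i]] <- if (id == "WT") {
      profile_preset("WT-like")
    } else if (id == "P6H") {
      profile_preset("P6H-like")
    } else if (id == "P6D") {
      profile_preset("P6D-like")
    } else if (id == "Y7W") {
      profile_preset("Y7W-like")
    } else if (!is.na(v$position[i]) && v$position[i] == 2L) {
      profile_preset("T2Q-like")
    } else if (!is.na(v$position[i]) && v$position[i] >= 5L) {
      profile_preset("impaired")
    } else {
      profile_preset("WT-like")
    }
  }
  profiles
}

#' @rdname default_fitness_profiles
#' @param alkaline_variant,acid_variant Variant ids carrying the
#'   alkaline-activated and acid-activated profiles.
#' @export
recapitulation_profiles <- function(library, alkaline_variant = "P6H",
                                    acid_variant = "P6D") {
  ids <- library$variants$variant_id
  stopifnot(alkaline_variant %in% ids, acid_variant %in% ids)
  profiles <- stats::setNames(
    replicate(length(ids), profile_preset("WT-like"), simplify = FALSE), ids)
  profiles[[alkaline_variant]] <- profile_preset("P6H-like")
  profiles[[acid_variant]] <- profile_preset("P6D-like")
  profiles
}

#' Experimental condition descriptor
#'
#' @param medium Medium name (e.g. `"SSA"`, `"MEA"`, `"YEA"`, `"EMM2"`).
#' @param pH Medium pH in \[3, 10\].
#' @param temperature_C Incubation temperature.
#' @param mating_permissive `FALSE` for the rich-medium (YEA) serial-passage
#'   control regime, where selection acts on vegetative fitness only.
#' @return An `assay_condition` object (list).
#' @export
condition <- function(medium = "SSA", pH = 5.5, temperature_C = 30,
                      mating_permissive = !identical(medium, "YEA")) {
  if (pH < 3 || pH > 10) stop("pH out of bounds [3, 10]")
  structure(list(medium = medium, pH = pH, temperature_C = temperature_C,
                 mating_permissive = isTRUE(mating_permissive)),
            class = "assay_condition")
}
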