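# RNG hygiene: generators restore the caller's RNG state so that
# simulation is a pure function of (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate per-donor shape-class count tables
#'
#' Emulates SEM shape counting across a donor panel: for each donor,
#' `cells_per_donor` cells are drawn multinomially from the
#' condition's class probability vector. Optional donor heterogeneity is
#' modeled as Dirichlet-multinomial: each donor's probability vector is
#' drawn from a Dirichlet with mean `prob` and concentration
#' `overdispersion` (larger = more homogeneous donors;
#' `Inf`/`NULL` = pure multinomial). The study design emulated is 30
#' donors; class counts per donor default to 1000.
#'
#' @param prob named probability vector over shape classes (e.g. from
#'   [reference_probabilities()]); must be non-negative and sum to 1
#'   within 1e-9.
#' @param n_donors number of donors (default 30).
#' @param cells_per_donor cells counted per donor (default 1000).
#' @param condition condition label stored in the output.
#' @param overdispersion Dirichlet concentration parameter (sum of
#'   Dirichlet alphas); default 1500 gives between-donor spread of the
#'   discocyte fraction on the order of the reference SEMs. `NULL` or
#'   `Inf` disables donor heterogeneity.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return data.frame in the counts CSV schema: `donor_id`, `condition`,
#'   `shape_class`, `count`.
#' @examples
#' tab <- simulate_counts(reference_probabilities("control", quiet = TRUE),
#'                        n_donors = 3, seed = 1)
#' head(tab)
#' @export
simulate_counts <- function(prob, n_donors = 30, cells_per_donor = 1000,
                            condition = "control", overdispersion = 1500,
                            seed = NULL) {
  if (is.null(names(prob)) || any(!nzchar(names(prob))))
    stop("prob must be a named probability vector over shape classes",
         call. = FALSE)
  if (any(prob < 0)) stop("negative class probability", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-9)
    stop("class probabilities must sum to 1 (got ", format(sum(prob)), ")",
         call. = FALSE)
  if (cells_per_donor <= 0) stop("cells_per_donor must be positive", call. = FALSE)
  if (n_donors < 1) stop("need at least one donor", call. = FALSE)

  dirichlet <- !is.null(overdispersion) && is.finite(overdispersion)
  if (dirichlet && overdispersion <= 0)
    stop("overdispersion must be positive", call. = FALSE)

  with_seed(seed, {
    rows <- lapply(seq_len(n_donors), function(d) {
      p <- prob
      if (dirichlet) {
        g <- stats::rgamma(length(prob), shape = prob * overdispersion)
        # classes with probability exactly 0 stay at 0
        g[prob == 0] <- 0
        p <- g / sum(g)
      }
      cnt <- drop(stats::rmultinom(1, size = cells_per_donor, prob = p))
      data.frame(donor_id = sprintf("donor%02d", d), condition = condition,
                 shape_class = names(prob), count = as.integer(cnt),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default Gaussian band templates for the three hemoglobin species
#'
#' Literature-standard band positions used to give simulated spectra a
#' realistic shape: oxyhemoglobin with the Soret band at 415 nm and
#' Q-bands at 542/576 nm, deoxyhemoglobin at 430/555 nm, methemoglobin
#' at 406/500/630 nm, each with an aromatic protein band at 280 nm.
#' Heights are apparent extinctions (absorbance per mol/L at 1 cm);
#' anchor-wavelength consistency of simulated spectra does not depend on
#' these shapes (see [simulate_spectrum()]).
#'
#' @return Named list (HbO2, Hb, MtHb) of data.frames with columns
#'   `center_nm`, `width_nm`, `height`.
#' @export
default_band_templates <- function() {
  list(
    HbO2 = data.frame(center_nm = c(415, 542, 576, 280),
                      width_nm  = c(10, 12, 10, 15),
                      height    = c(1.25e5, 1.4e4, 1.5e4, 3.0e4)),
    Hb   = data.frame(center_nm = c(430, 555, 280),
                      width_nm  = c(12, 15, 15),
                      height    = c(1.3e5, 1.3e4, 3.0e4)),
    MtHb = data.frame(center_nm = c(406, 500, 630, 280),
                      width_nm  = c(10, 14, 12, 15),
                      height    = c(1.5e5, 9e3, 4e3, 3.0e4))
  )
}

gaussian_template <- function(wavelength, bands) {
  out <- numeric(length(wavelength))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$height[i] *
      exp(-0.5 * ((wavelength - bands$center_nm[i]) / bands$width_nm[i])^2)
  out
}

#' Simulate an absorption spectrum for a known hemoglobin speciation
#'
#' Builds a noiseless spectrum as the concentration-weighted sum of the
#' per-species Gaussian band templates, then adds the unique quadratic
#' correction through the three anchor residuals so that the noiseless
#' trace evaluated at exactly 577, 569 and 500 nm equals the anchor
#' triple `E c` predicted by the deconvolution model -- i.e. the
#' simulated spectrum is exactly consistent with the speciation it was
#' generated from. Finally, independent Gaussian photometric noise of
#' standard deviation `noise_sd` (default 0.001 Abs, the instrument's
#' photometric repeatability) is added pointwise.
#'
#' @param conc numeric triple of concentrations (HbO2, Hb, MtHb), mol/L.
#' @param model a [hb_deconvolution_model()].
#' @param templates per-species band templates,
#'   default [default_band_templates()].
#' @param wavelength grid in nm, default `seq(200, 700, by = 0.1)`; must
#'   cover the anchor wavelengths.
#' @param noise_sd photometric noise standard deviation in absorbance
#'   units, default 0.001.
#' @param seed integer seed; identical seeds give identical spectra.
#' @param condition,donor_id metadata labels.
#' @return An [absorption_spectrum()].
#' @examples
#' s <- simulate_spectrum(c(5e-6, 3e-6, 1e-6), noise_sd = 0, seed = 1)
#' speciate(anchors_from_spectrum(s))$concentrations  # recovers the input
#' @export
simulate_spectrum <- function(conc, model = hb_deconvolution_model(),
                              templates = default_band_templates(),
                              wavelength = seq(200, 700, by = 0.1),
                              noise_sd = 0.001, seed = NULL,
                              condition = NA_character_,
                              donor_id = NA_character_) {
  conc <- as.numeric(conc)
  stopifnot(length(conc) == 3, all(is.finite(conc)), noise_sd >= 0)
  anchors <- model$anchors_nm
  if (any(anchors < min(wavelength) | anchors > max(wavelength)))
    stop("wavelength grid must cover the anchor wavelengths (500-577 nm)",
         call. = FALSE)
  for (tt in templates)
    if (any(tt$width_nm <= 0)) stop("template widths must be positive", call. = FALSE)

  base <- numeric(length(wavelength))
  base_at_anchor <- numeric(3)
  for (i in seq_along(conc)) {
    bands <- templates[[i]]
    base <- base + conc[i] * gaussian_template(wavelength, bands)
    base_at_anchor <- base_at_anchor + conc[i] * gaussian_template(anchors, bands)
  }
  # quadratic through the three anchor residuals: exact anchor consistency
  target <- drop(model$E %*% conc)
  resid <- target - base_at_anchor
  qc <- solve(outer(anchors, 0:2, `^`), resid)
  base <- base + drop(outer(wavelength, 0:2, `^`) %*% qc)

  noisy <- if (noise_sd > 0)
    with_seed(seed, base + stats::rnorm(length(base), sd = noise_sd))
  else base
  absorption_spectrum(wavelength, noisy, condition = condition,
                      donor_id = donor_id)
}

#' Closed-form noise propagation through the deconvolution
#'
#' With independent photometric noise of standard deviation `noise_sd`
#' at each anchor wavelength, the standard deviation of each recovered
#' concentration is `noise_sd * 1e-4 * sqrt(sum(C[species, ]^2))` --
#' linear error propagation through the coefficient matrix.
#'
#' @param noise_sd per-anchor absorbance noise sd.
#' @param model a [hb_deconvolution_model()].
#' @return Named numeric vector of concentration standard deviations
#'   (mol/L) for HbO2, Hb, MtHb.
#' @export
propagated_concentration_sd <- function(noise_sd,
                                        model = hb_deconvolution_model()) {
  noise_sd * model$scale * sqrt(rowSums(model$C^2))
}
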