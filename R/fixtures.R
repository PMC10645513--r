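#' Catalogue of named slip profiles and amplitude presets
#'
#' Lists the built-in fixtures: the Drosophila shifted-sine slip, the
#' single-mode profiles `mode-1` .. `mode-4`, the symmetric sine of the
#' reduced model, and two synthetic cortical-amplitude presets.
#'
#' The amplitude presets are *shape stand-ins*: their Gaussian peaks are
#' placed at plausible cell-cycle contraction times, but only their total
#' \eqn{\chi = \int V\,dt} is calibrated — to 129 \eqn{\mu m}
#' (`"wild-type-like"`, the mean \eqn{\chi} estimated for wild-type
#' embryos) and 57 \eqn{\mu m} (`"mutant-like"`, the dampened-flow PP1
#' mutant estimate). The underlying experimental flow curves are not
#' reproduced here.
#'
#' @return A tibble with columns `name`, `kind`, `description`.
#' @export
fixture_catalog <- function() {
  tibble::tibble(
    name = c("drosophila", paste0("mode-", 1:4), "symmetric-sine",
             "wild-type-like", "mutant-like"),
    kind = c(rep("slip", 6), rep("amplitude", 2)),
    description = c(
      "Shifted-sine cortical slip of Drosophila cell cycles 4-6 (unit amplitude)",
      sprintf("Single-mode slip B_n = delta_{n,%d}", 1:4),
      "Symmetrized sine slip of the reduced 1D model",
      "3-Gaussian amplitude preset, total chi = 129 um (synthetic shape)",
      "2-Gaussian amplitude preset, total chi = 57 um (synthetic shape)"
    )
  )
}

#' Retrieve a named slip profile fixture
#'
#' @param name One of `"drosophila"`, `"mode-1"` .. `"mode-4"`,
#'   `"symmetric-sine"`.
#' @param geometry An [embryo_geometry()] (required by the mode
#'   profiles).
#' @return A [slip_profile()].
#' @export
slip_fixture <- function(name, geometry = embryo_geometry(110, 270)) {
  if (name == "drosophila") return(slip_drosophila())
  if (name == "symmetric-sine") return(slip_symmetric_sine())
  m <- regmatches(name, regexec("^mode-([0-9]+)$", name))[[1]]
  if (length(m) == 2) return(slip_mode(as.integer(m[2]), geometry))
  stop(sprintf("unknown slip fixture '%s'; see fixture_catalog().", name),
       call. = FALSE)
}

#' Retrieve a named cortical amplitude preset
#'
#' Synthetic Gaussian-sum amplitude histories whose total
#' \eqn{\chi = \int_0^\infty V\,dt} equals the declared estimate (129 or
#' 57 \eqn{\mu m}) to within 0.1\%; peak times span three (respectively
#' two) contraction cycles about 10 minutes apart, and the tallest peak
#' of the wild-type-like preset is 0.3 \eqn{\mu m\,s^{-1}}, the cortical
#' amplitude at the cell-cycle-6 contraction peak.
#'
#' @param name `"wild-type-like"` or `"mutant-like"`.
#' @return An [amplitude_gaussians()] series.
#' @export
amplitude_preset <- function(name) {
  if (name == "wild-type-like") {
    a <- c(0.18, 0.24, 0.30)
    b <- c(600, 1200, 1800)
    cc <- rep(129 / (sum(a) * sqrt(2 * pi)), 3)
    return(amplitude_gaussians(a, b, cc))
  }
  if (name == "mutant-like") {
    a <- c(0.10, 0.13)
    b <- c(900, 1800)
    cc <- rep(57 / (sum(a) * sqrt(2 * pi)), 2)
    return(amplitude_gaussians(a, b, cc))
  }
  stop(sprintf("unknown amplitude preset '%s'; see fixture_catalog().", name),
       call. = FALSE)
}
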