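#' Air density from measurement altitude (standard-atmosphere troposphere)
#'
#' Measurement campaigns on hovering animals span sea level to high-altitude
#' field sites; air density enters the lift coefficient and Reynolds number
#' directly. Density is computed from the US standard-atmosphere troposphere
#' law (identical across the 1962/1976 editions below 11 km):
#' \deqn{\rho(h) = \rho_0 \left(1 - \frac{L h}{T_0}\right)^{g/(L R_{gas}) - 1}}
#' with \eqn{\rho_0 = 1.225\,kg\,m^{-3}}, \eqn{T_0 = 288.15\,K},
#' lapse rate \eqn{L = 0.0065\,K\,m^{-1}} and
#' \eqn{R_{gas} = 287.053\,J\,kg^{-1}K^{-1}}.
#'
#' @param h altitude above sea level in metres; vectorised. Must lie in
#'   `[0, 11000]` (troposphere only).
#' @return Air density in kg m^-3; strictly decreasing in `h`.
#' @examples
#' density_from_altitude(0)      # 1.225
#' density_from_altitude(2000)
#' @export
density_from_altitude <- function(h) {
  if (!is.numeric(h) || anyNA(h))
    stop("altitude must be numeric and non-missing")
  if (any(h < 0 | h > 11000))
    stop("altitude outside troposphere range [0, 11000] m")
  rho0 <- 1.225; T0 <- 288.15; L <- 0.0065; g <- 9.80665; R_gas <- 287.053
  rho0 * (1 - L * h / T0)^(g / (L * R_gas) - 1)
}

# Native-unit column schema for observation tables (the canonical CSV header).
.obs_native_cols <- function() {
  c(species = "species", mass_mg = "mass_mg",
    wing_length_mm = "wing_length_mm", wing_area_mm2 = "wing_area_mm2",
    body_length_mm = "body_length_mm", frequency_hz = "frequency_hz",
    amplitude_deg = "amplitude_deg", pitch_deg = "pitch_deg",
    altitude_m = "altitude_m", density_kgm3 = "density_kgm3",
    n_meas = "n_meas", source = "source")
}

#' Validate a native-unit observation table and convert it to SI
#'
#' Takes a data frame in the canonical native units of the comparative
#' hovering dataset (mass in mg, lengths in mm, areas in mm^2, angles in
#' degrees, frequency in Hz) and returns validated SI observation records.
#' Rows violating the invariants (non-positive mass/length/area, stroke
#' amplitude outside (0, 360) degrees, non-positive frequency, `n_meas < 1`,
#' empty species) are rejected; the rejection report is attached as the
#' `"rejected"` attribute rather than aborting the run, so one bad literature
#' row never discards a dataset.
#'
#' Air density is resolved per row: reported density if present, else
#' [density_from_altitude()] of the reported altitude, else the sea-level
#' 1.225 kg m^-3.
#'
#' @param df data frame with columns `species`, `mass_mg`, `wing_length_mm`,
#'   `wing_area_mm2` (required) and optionally `body_length_mm`,
#'   `frequency_hz`, `amplitude_deg`, `pitch_deg`, `altitude_m`,
#'   `density_kgm3`, `n_meas`, `source`.
#' @param synonyms optional two-column data frame (`from`, `to`) of species
#'   name changes, applied before any tree matching.
#' @return A data frame of class `"hover_obs"` with SI columns `species`,
#'   `m` (kg), `R` (m), `S` (m^2), `R_b` (m), `f` (Hz), `Phi` (rad,
#'   peak-to-peak), `theta_m` (rad), `altitude` (m), `rho` (kg m^-3),
#'   `n_meas`, `source`. Attributes: `"rejected"` (data frame of row index
#'   and reason) and `"n_accepted"`.
#' @seealso [read_observations()], [write_observations()]
#' @export
as_observations <- function(df, synonyms = NULL) {
  req <- c("species", "mass_mg", "wing_length_mm", "wing_area_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  opt <- c("body_length_mm", "frequency_hz", "amplitude_deg", "pitch_deg",
           "altitude_m", "density_kgm3", "n_meas", "source")
  for (col in opt) if (is.null(df[[col]])) df[[col]] <- NA
  if (all(is.na(df$n_meas))) df$n_meas <- 1L
  df$n_meas[is.na(df$n_meas)] <- 1L
  df$source <- as.character(df$source)

  num_cols <- c("mass_mg", "wing_length_mm", "wing_area_mm2",
                "body_length_mm", "frequency_hz", "amplitude_deg",
                "pitch_deg", "altitude_m", "density_kgm3", "n_meas")
  reasons <- character(nrow(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(as.character(v)))
      bad <- !is.na(v) & v != "" & is.na(coerced)
      reasons[bad] <- paste0(reasons[bad], "non-numeric ", col, "; ")
      df[[col]] <- coerced
    }
  }
  chk <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reasons[bad] <<- paste0(reasons[bad], why, "; ")
  }
  chk(is.na(df$species) | !nzchar(trimws(df$species)), "empty species")
  chk(is.na(df$mass_mg) | df$mass_mg <= 0, "mass not positive")
  chk(is.na(df$wing_length_mm) | df$wing_length_mm <= 0,
      "wing length not positive")
  chk(is.na(df$wing_area_mm2) | df$wing_area_mm2 <= 0,
      "wing area not positive")
  chk(!is.na(df$body_length_mm) & df$body_length_mm <= 0,
      "body length not positive")
  chk(!is.na(df$frequency_hz) & df$frequency_hz <= 0,
      "frequency not positive")
  chk(!is.na(df$amplitude_deg) &
        (df$amplitude_deg <= 0 | df$amplitude_deg >= 360),
      "amplitude outside (0, 360) deg")
  chk(!is.na(df$density_kgm3) & df$density_kgm3 <= 0,
      "density not positive")
  chk(!is.na(df$altitude_m) & (df$altitude_m < 0 | df$altitude_m > 11000),
      "altitude outside [0, 11000] m")
  chk(df$n_meas < 1 | df$n_meas != round(df$n_meas),
      "n_meas not a positive integer")

  ok <- !nzchar(reasons)
  rejected <- data.frame(row = which(!ok),
                         reason = sub("; $", "", reasons[!ok]),
                         stringsAsFactors = FALSE)
  acc <- df[ok, , drop = FALSE]

  species <- trimws(acc$species)
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    idx <- match(species, synonyms$from)
    species[!is.na(idx)] <- synonyms$to[idx[!is.na(idx)]]
  }
  rho <- acc$density_kgm3
  use_alt <- is.na(rho) & !is.na(acc$altitude_m)
  rho[use_alt] <- density_from_altitude(acc$altitude_m[use_alt])
  rho[is.na(rho)] <- 1.225

  out <- data.frame(
    species = species,
    m = acc$mass_mg * 1e-6,
    R = acc$wing_length_mm * 1e-3,
    S = acc$wing_area_mm2 * 1e-6,
    R_b = acc$body_length_mm * 1e-3,
    f = acc$frequency_hz,
    Phi = acc$amplitude_deg * pi / 180,
    theta_m = acc$pitch_deg * pi / 180,
    altitude = acc$altitude_m,
    rho = rho,
    n_meas = as.integer(acc$n_meas),
    source = acc$source,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hover_obs", "data.frame")
  attr(out, "rejected") <- rejected
  attr(out, "n_accepted") <- nrow(out)
  out
}

#' Read an observation table from a delimited file
#'
#' Reads the canonical CSV format (UTF-8, `.` decimal, header columns
#' `species, mass_mg, wing_length_mm, wing_area_mm2, body_length_mm,
#' frequency_hz, amplitude_deg, pitch_deg, altitude_m, density_kgm3,
#' n_meas, source`) and validates/converts it with [as_observations()].
#' The number of accepted and rejected rows is reported via `message()`.
#'
#' @param path path to a CSV file.
#' @param synonyms optional species-synonym map, see [as_observations()].
#' @param sep field separator (default `","`).
#' @return A `"hover_obs"` data frame in SI units.
#' @export
read_observations <- function(path, synonyms = NULL, sep = ",") {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  obs <- as_observations(df, synonyms = synonyms)
  rej <- attr(obs, "rejected")
  message(sprintf("accepted %d observation row(s), rejected %d",
                  nrow(obs), nrow(rej)))
  if (nrow(rej))
    message(paste(sprintf("  row %d: %s", rej$row, rej$reason),
                  collapse = "\n"))
  obs
}

#' Write observation records back to the canonical native-unit CSV
#'
#' Inverse of [read_observations()]: converts SI records back to the native
#' units (mg, mm, mm^2, Hz, degrees) and writes the canonical header. The
#' SI-to-native round trip is exact to floating-point rounding, so reading a
#' file and re-writing it conserves every accepted row.
#'
#' @param obs a `"hover_obs"` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- observations_to_native(obs)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert SI observation records to the native-unit table
#'
#' @param obs a `"hover_obs"` data frame (SI).
#' @return Data frame in the canonical native-unit columns.
#' @export
observations_to_native <- function(obs) {
  data.frame(
    species = obs$species,
    mass_mg = obs$m * 1e6,
    wing_length_mm = obs$R * 1e3,
    wing_area_mm2 = obs$S * 1e6,
    body_length_mm = obs$R_b * 1e3,
    frequency_hz = obs$f,
    amplitude_deg = obs$Phi * 180 / pi,
    pitch_deg = obs$theta_m * 180 / pi,
    altitude_m = obs$altitude,
    density_kgm3 = obs$rho,
    n_meas = obs$n_meas,
    source = obs$source,
    stringsAsFactors = FALSE
  )
}

#' Read a species phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] with the validation this analysis
#' needs: unique tip labels, and branch lengths present. Taxonomy-derived
#' trees (cladograms) carry no branch lengths; these are assigned unit
#' length with a warning — the PGLS slope is invariant under uniform branch
#' rescaling, so the absolute scale is immaterial.
#'
#' @param path Newick file path, or a Newick string.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @export
read_phylogeny <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path)
          else ape::read.tree(text = path)
  if (is.null(tree)) stop("could not parse Newick input: ", path)
  validate_phylogeny(tree)
}

#' Validate (and if needed repair) a phylogeny for comparative analysis
#'
#' @param tree a `phylo` object.
#' @return The tree, with unit branch lengths assigned (with a warning) if
#'   none were present.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; assigning unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (any(depths <= 0))
    stop("zero root-to-tip path length after length assignment")
  tree
}
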