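#' @importFrom utils read.csv write.csv
#' @importFrom stats setNames
NULL

#' Organ sets used by the whole-body model
#'
#' The platform body is represented by 15 organs plus plasma, blood-cell and
#' lymph-node pools; the male reproductive tract (MRT) adds five organs with
#' epithelial/barrier and luminal sub-compartments, a rete-testis transit
#' compartment, and a sequential luminal (seminal-fluid) chain.
#'
#' @name organ_sets
NULL

#' @rdname organ_sets
#' @export
PLATFORM_ORGANS <- c(
  "lung", "heart", "kidney", "muscle", "skin", "brain", "adipose", "thymus",
  "liver", "spleen", "pancreas", "small_intestine", "large_intestine",
  "bone", "other"
)

#' @rdname organ_sets
#' @export
MRT_ORGANS <- c(
  "testis", "epididymis", "vas_deferens", "seminal_vesicle", "prostate_gland"
)

# splanchnic organs drain through the liver vascular space
SPLANCHNIC_ORGANS <- c("spleen", "pancreas", "small_intestine", "large_intestine")

# organs with a smooth-muscle transit layer
MUSCULAR_ORGANS <- c("vas_deferens", "seminal_vesicle", "prostate_gland")

.SPECIES <- c("mouse", "rat", "monkey", "human")

.ORGAN_FIELDS <- c(
  "plasma_flow", "blood_cell_flow", "lymph_flow",
  "vascular_volume", "endosomal_volume", "interstitial_volume",
  "epithelial_volume", "muscular_volume", "luminal_volume",
  "rete_testis_volume", "total_volume"
)

#' Default body weights (kg)
#'
#' The source tables do not print body weights; these defaults are the
#' conventional reference weights for adult males of each species and can be
#' overridden in [load_species_physiology()].
#'
#' @param species one of `"mouse"`, `"rat"`, `"monkey"`, `"human"`.
#' @return body weight in kg.
#' @export
default_body_weight <- function(species) {
  species <- match.arg(species, .SPECIES)
  c(mouse = 0.028, rat = 0.25, monkey = 6.2, human = 71)[[species]]
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "mrtpbpk")
  if (!nzchar(path)) {
    # during development (package loaded with load_all) fall back to inst/
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", file)
  path
}

# read a long-format (organ, field, value, unit) table into a wide data.frame
# with canonical units; rows restricted to `species`
.read_physiology_table <- function(path, species) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "organ", "field", "value", "unit")
  if (!all(need %in% names(raw))) {
    stop("physiology file must have columns: ", paste(need, collapse = ", "))
  }
  raw <- raw[raw$species == species, , drop = FALSE]
  if (nrow(raw) == 0L) return(NULL)
  if (any(!is.finite(raw$value))) {
    stop("non-finite value in physiology file: ", path)
  }
  if (any(raw$value < 0)) {
    bad <- raw[raw$value < 0, ][1, ]
    stop(sprintf("negative physiological value: %s %s = %g", bad$organ, bad$field, bad$value))
  }
  raw$value <- mapply(.to_canonical, raw$value, raw$unit)
  organs <- unique(raw$organ)
  wide <- as.data.frame(
    matrix(NA_real_, nrow = length(organs), ncol = length(.ORGAN_FIELDS),
           dimnames = list(organs, .ORGAN_FIELDS))
  )
  for (i in seq_len(nrow(raw))) {
    if (!raw$field[i] %in% .ORGAN_FIELDS) {
      stop("unknown physiology field: ", raw$field[i])
    }
    wide[raw$organ[i], raw$field[i]] <- raw$value[i]
  }
  wide$organ <- organs
  rownames(wide) <- NULL
  wide[, c("organ", .ORGAN_FIELDS)]
}

# fill derived quantities: lymph flow (plasma/200), endosomal volume
# (0.5% of total), organ totals, and zero the sub-compartments an organ
# does not possess
.complete_organ_row <- function(row) {
  zero_ok <- c("epithelial_volume", "muscular_volume", "luminal_volume",
               "rete_testis_volume")
  for (f in zero_ok) if (is.na(row[[f]])) row[[f]] <- 0
  vol_fields <- c("vascular_volume", "endosomal_volume", "interstitial_volume",
                  "epithelial_volume", "muscular_volume", "luminal_volume",
                  "rete_testis_volume")
  if (is.na(row[["total_volume"]])) {
    if (is.na(row[["endosomal_volume"]])) {
      # endosome = 0.5% of total and total = sum of parts, solved jointly
      known <- sum(unlist(row[setdiff(vol_fields, "endosomal_volume")]), na.rm = TRUE)
      row[["total_volume"]] <- known / (1 - 0.005)
      row[["endosomal_volume"]] <- 0.005 * row[["total_volume"]]
    } else {
      row[["total_volume"]] <- sum(unlist(row[vol_fields]), na.rm = TRUE)
    }
  }
  if (is.na(row[["endosomal_volume"]])) {
    row[["endosomal_volume"]] <- 0.005 * row[["total_volume"]]
  }
  if (is.na(row[["interstitial_volume"]])) {
    stop("missing interstitial volume for organ '", row[["organ"]],
         "': provide an explicit file value")
  }
  if (is.na(row[["lymph_flow"]]) && !is.na(row[["plasma_flow"]])) {
    row[["lymph_flow"]] <- row[["plasma_flow"]] / 200
  }
  row
}

#' Load species physiology for the whole-body model
#'
#' Assembles the full set of organ flows and sub-compartment volumes for one
#' species, in canonical units (h, L). MRT organ values come from the packaged
#' physiology tables (or a user file via `source`); platform-organ values come
#' from a packaged representative parameter set (see the package vignette for
#' its provenance) and, for species other than mouse, are obtained by
#' allometric scaling of the mouse values (flows with exponent 0.75, volumes
#' with exponent 1). Lymph flows are derived as plasma flow / 200 and
#' endosomal volumes as 0.5% of the organ total wherever the tables omit
#' them. The lung plasma flow is set to close the circulatory loop (sum of
#' all organ plasma flows plus the lung lymph flow).
#'
#' @param species one of `"mouse"`, `"rat"`, `"monkey"`, `"human"`.
#' @param source optional path to an MRT physiology CSV
#'   (columns species, organ, field, value, unit) overriding the packaged
#'   tables.
#' @param platform_source optional path overriding the packaged platform
#'   organ parameter file.
#' @param body_weight body weight in kg; defaults to [default_body_weight()].
#' @return an object of class `species_physiology`: a list with elements
#'   `species`, `body_weight`, `organs` (one row per organ, canonical units)
#'   and `pools` (named vector of plasma, blood-cell and lymph-node volumes).
#' @examples
#' mouse <- load_species_physiology("mouse")
#' subset(mouse$organs, organ == "testis")$epithelial_volume  # 1.74e-4 L
#' @export
load_species_physiology <- function(species, source = NULL,
                                    platform_source = NULL,
                                    body_weight = NULL) {
  species <- match.arg(species, .SPECIES)
  if (is.null(body_weight)) body_weight <- default_body_weight(species)
  if (body_weight <= 0) stop("body weight must be positive")

  mrt_path <- if (is.null(source)) .extdata("mrt_physiology.csv") else source
  plat_path <- if (is.null(platform_source)) {
    .extdata("platform_physiology_mouse_synthetic.csv")
  } else {
    platform_source
  }

  mrt <- .read_physiology_table(mrt_path, species)
  missing_mrt <- setdiff(MRT_ORGANS, mrt$organ)
  if (length(missing_mrt) > 0L) {
    stop("structural error: MRT organ(s) missing from physiology table: ",
         paste(missing_mrt, collapse = ", "))
  }

  plat <- .read_physiology_table(plat_path, "mouse")
  pools_idx <- plat$organ %in% c("plasma", "blood_cell", "lymph_node")
  pools <- setNames(plat$total_volume[pools_idx], plat$organ[pools_idx])
  plat <- plat[!pools_idx, , drop = FALSE]
  missing_plat <- setdiff(PLATFORM_ORGANS, plat$organ)
  if (length(missing_plat) > 0L) {
    stop("structural error: platform organ(s) missing: ",
         paste(missing_plat, collapse = ", "))
  }
  if (length(setdiff(names(pools), c("plasma", "blood_cell", "lymph_node"))) ||
      length(pools) != 3L) {
    stop("platform file must define plasma, blood_cell and lymph_node pools")
  }

  if (species != "mouse") {
    # platform organs and pools are translated allometrically from mouse
    bw_mouse <- default_body_weight("mouse")
    flow_fields <- c("plasma_flow", "blood_cell_flow", "lymph_flow")
    vol_fields <- setdiff(.ORGAN_FIELDS, flow_fields)
    for (f in flow_fields) {
      plat[[f]] <- allometric_scale(plat[[f]], bw_mouse, body_weight, 0.75)
    }
    for (f in vol_fields) {
      plat[[f]] <- allometric_scale(plat[[f]], bw_mouse, body_weight, 1)
    }
    pools <- allometric_scale(pools, bw_mouse, body_weight, 1)
  }

  organs <- rbind(plat, mrt)
  organs <- organs[match(c(PLATFORM_ORGANS, MRT_ORGANS), organs$organ), ]
  for (i in seq_len(nrow(organs))) {
    organs[i, ] <- .complete_organ_row(organs[i, ])
  }

  # close the circulatory loop: lung receives the whole plasma/blood-cell flow
  others <- organs$organ != "lung"
  s_pl <- sum(organs$plasma_flow[others])
  organs$plasma_flow[!others] <- s_pl * 200 / 199  # includes its own lymph
  organs$lymph_flow[!others] <- organs$plasma_flow[!others] / 200
  organs$blood_cell_flow[!others] <- sum(organs$blood_cell_flow[others])
  rownames(organs) <- NULL

  structure(
    list(species = species, body_weight = body_weight,
         organs = organs, pools = pools),
    class = "species_physiology"
  )
}

#' @method print species_physiology
#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s, body weight %g kg\n", x$species, x$body_weight))
  cat(sprintf("  %d organs (%d platform + %d MRT), pools: plasma %.3g L, blood cells %.3g L, lymph node %.3g L\n",
              nrow(x$organs), length(PLATFORM_ORGANS), length(MRT_ORGANS),
              x$pools[["plasma"]], x$pools[["blood_cell"]], x$pools[["lymph_node"]]))
  invisible(x)
}

#' Allometric scaling of a physiological parameter
#'
#' Interspecies translation with the standard power law
#' `value * (bw_target / bw_ref)^exponent`; exponent 0.75 for flows and
#' 1.0 for volumes.
#'
#' @param value parameter value (any unit).
#' @param bw_ref,bw_target reference and target body weights (kg), > 0.
#' @param exponent allometric exponent.
#' @return scaled value.
#' @examples
#' allometric_scale(0.003078, 0.028, 0.25, 0.75)  # approx 0.0159 L/min
#' @export
allometric_scale <- function(value, bw_ref, bw_target, exponent) {
  if (any(bw_ref <= 0) || any(bw_target <= 0)) {
    stop("body weights must be positive")
  }
  value * (bw_target / bw_ref)^exponent
}

#' Translate a physiology to another species
#'
#' Builds the target-species physiology: MRT organ values are taken from the
#' packaged species tables where printed, and platform organs (plus any
#' missing fields) are scaled allometrically (flows ^0.75, volumes ^1).
#'
#' @param from source species (must be `"mouse"`, the reference species).
#' @param to target species.
#' @param body_weight optional target body weight (kg).
#' @param ... passed to [load_species_physiology()].
#' @return a `species_physiology` for the target species.
#' @export
translate_physiology <- function(from = "mouse", to, body_weight = NULL, ...) {
  from <- match.arg(from, .SPECIES)
  if (from != "mouse") {
    stop("translation is anchored at the mouse reference physiology")
  }
  load_species_physiology(to, body_weight = body_weight, ...)
}

#' Validate a species physiology
#'
#' Checks the structural and numerical invariants of a physiology object and
#' returns findings rather than raising conditions. Printed-table
#' inconsistencies known from the source tables (the blood-flow column
#' interpretation, implausibly large epithelial volumes in the human table)
#' are reported as warnings, not errors.
#'
#' @param sp a `species_physiology`.
#' @return a data.frame with columns `level` ("error" or "warning"),
#'   `organ`, `field`, `message`; zero rows when every invariant holds.
#' @export
validate_physiology <- function(sp) {
  stopifnot(inherits(sp, "species_physiology"))
  f <- list()
  add <- function(level, organ, field, message) {
    f[[length(f) + 1L]] <<- data.frame(level = level, organ = organ,
                                       field = field, message = message)
  }
  org <- sp$organs

  missing <- setdiff(c(PLATFORM_ORGANS, MRT_ORGANS), org$organ)
  for (m in missing) add("error", m, "", "organ required by the model topology is absent")
  if (anyDuplicated(org$organ)) {
    add("error", org$organ[duplicated(org$organ)][1], "", "duplicated organ")
  }

  for (i in seq_len(nrow(org))) {
    o <- org$organ[i]
    for (fl in .ORGAN_FIELDS) {
      v <- org[[fl]][i]
      if (is.na(v)) next
      if (v < 0) add("error", o, fl, sprintf("negative value %g", v))
    }
    if (!is.na(org$lymph_flow[i]) && !is.na(org$plasma_flow[i]) &&
        org$lymph_flow[i] > org$plasma_flow[i]) {
      add("error", o, "lymph_flow",
          "lymph flow exceeds plasma flow (rule: lymph = plasma/200)")
    }
    # 0.5% endosome rule (warning when the table departs from it)
    if (!is.na(org$endosomal_volume[i]) && org$total_volume[i] > 0) {
      ratio <- org$endosomal_volume[i] / org$total_volume[i]
      if (abs(ratio / 0.005 - 1) > 0.25) {
        add("warning", o, "endosomal_volume",
            sprintf("endosomal volume is %.2g%% of organ total (rule: 0.5%%)", 100 * ratio))
      }
    }
    # hematocrit consistency of the two flow columns
    if (!is.na(org$blood_cell_flow[i]) && !is.na(org$plasma_flow[i]) &&
        org$plasma_flow[i] > 0) {
      r <- org$blood_cell_flow[i] / org$plasma_flow[i]
      if (abs(r / (0.45 / 0.55) - 1) > 0.2) {
        add("warning", o, "blood_cell_flow",
            sprintf("blood-cell/plasma flow ratio %.2f departs from hematocrit 0.45 split", r))
      }
    }
    # modelled sub-volumes must fit inside the organ total
    sub <- sum(org$vascular_volume[i], org$endosomal_volume[i],
               org$interstitial_volume[i], org$epithelial_volume[i],
               org$muscular_volume[i], org$luminal_volume[i],
               org$rete_testis_volume[i], na.rm = TRUE)
    if (sub > org$total_volume[i] * (1 + 1e-6)) {
      add("warning", o, "total_volume",
          sprintf("sub-compartment volumes (%.3g L) exceed organ total (%.3g L) as printed",
                  sub, org$total_volume[i]))
    }
  }

  # circulatory closure
  lung <- org[org$organ == "lung", ]
  s_pl <- sum(org$plasma_flow[org$organ != "lung"]) + lung$lymph_flow
  if (abs(lung$plasma_flow / s_pl - 1) > 0.01) {
    add("warning", "lung", "plasma_flow",
        sprintf("lung plasma flow %.3g L/h does not close the circulatory loop (expected %.3g)",
                lung$plasma_flow, s_pl))
  }

  # standing note: the printed mouse table's "Blood Flow" column is the
  # blood-cell flow (ratio to plasma flow matches a 0.45 hematocrit split)
  add("warning", "", "blood_cell_flow",
      "table column 'Blood Flow' interpreted as blood-cell flow (hematocrit 0.45 split)")

  do.call(rbind, f)
}
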