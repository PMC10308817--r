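# File interfaces. Angles are stored in degrees in all files and converted
# to radians internally; atom identifiers in files are 1-based (PDB serial
# convention) and map directly onto the package's 1-based atom indices.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Read and write Boresch restraint JSON
#'
#' File format: an object with `anchors` (`a`, `b`, `c`, `A`, `B`, `C`,
#' 1-based atom identifiers), `equilibrium` (`r` in Å; `thetaA`, `thetaB`,
#' `phiA`, `phiB`, `phiC` in degrees) and `force_constants` (`r` in
#' kcal mol⁻¹ Å⁻², angles in kcal mol⁻¹ rad⁻²).
#'
#' @param path File path.
#' @return `read_boresch_json()` returns a [boresch_restraint()];
#'   `write_boresch_json()` returns `path` invisibly.
#' @export
read_boresch_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  eq <- x$equilibrium
  k <- x$force_constants
  boresch_restraint(
    anchors = x$anchors,
    r0 = eq$r,
    theta_A0 = .deg2rad(eq$thetaA), theta_B0 = .deg2rad(eq$thetaB),
    phi_A0 = .deg2rad(eq$phiA), phi_B0 = .deg2rad(eq$phiB),
    phi_C0 = .deg2rad(eq$phiC),
    k_r = k$r,
    k_theta_A = k$thetaA, k_theta_B = k$thetaB,
    k_phi_A = k$phiA, k_phi_B = k$phiB, k_phi_C = k$phiC
  )
}

#' @rdname read_boresch_json
#' @param restraint A [boresch_restraint()].
#' @export
write_boresch_json <- function(restraint, path) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  eq <- restraint$equilibrium
  k <- restraint$force_constants
  obj <- list(
    anchors = as.list(restraint$anchors),
    equilibrium = list(
      r = eq[["r"]],
      thetaA = .rad2deg(eq[["theta_A"]]), thetaB = .rad2deg(eq[["theta_B"]]),
      phiA = .rad2deg(eq[["phi_A"]]), phiB = .rad2deg(eq[["phi_B"]]),
      phiC = .rad2deg(eq[["phi_C"]])
    ),
    force_constants = list(
      r = k[["r"]],
      thetaA = k[["theta_A"]], thetaB = k[["theta_B"]],
      phiA = k[["phi_A"]], phiB = k[["phi_B"]], phiC = k[["phi_C"]]
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write distance-restraint-set JSON
#'
#' File format: an array of objects, each with `receptor_atom`,
#' `ligand_atom` (1-based identifiers), `r0` (Å), `r_fb` (Å) and `K`
#' (kcal mol⁻¹ Å⁻²) - a distance restraint dictionary per pair.
#'
#' @param path File path.
#' @param label Label assigned to the set on reading.
#' @return `read_distance_set_json()` returns a [distance_restraint_set()];
#'   `write_distance_set_json()` returns `path` invisibly.
#' @export
read_distance_set_json <- function(path, label = "") {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  distance_restraint_set(tibble::as_tibble(x), label = label)
}

#' @rdname read_distance_set_json
#' @param set A [distance_restraint_set()].
#' @export
write_distance_set_json <- function(set, path) {
  stopifnot(inherits(set, "distance_restraint_set"))
  jsonlite::write_json(set$restraints, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stage contributions for cycle assembly
#'
#' Accepts CSV or JSON (by file extension) with fields `label`, `value`,
#' and optionally `uncertainty` and `sign_role`.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble suitable for [cycle_ledger()].
#' @export
read_stage_contributions <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}

#' Run configuration
#'
#' Collects the tunable parameters of a full selection-and-correction run,
#' with the package defaults: temperature 298 K, V° = 1660 Å³, grid element
#' 0.25 Å, buffer 5 Å, 30 orientations per 2 pi, angle filter 30-150°,
#' collinearity threshold 10 kT, 200 lowest-SD pairs, 10 Å contact cutoff,
#' 95% confidence. Serialised (with a content hash) alongside outputs for
#' provenance.
#'
#' @param ... Overrides of the defaults listed above.
#' @return A list of class `run_config` with attribute `hash`.
#' @export
run_config <- function(...) {
  cfg <- list(
    temperature = 298,
    standard_volume = 1660,
    element = 0.25,
    buffer = 5,
    orientations = 30,
    angle_min_deg = 30,
    angle_max_deg = 150,
    collinearity_threshold_kT = 10,
    top_n = 200,
    contact_cutoff = 10,
    confidence = 0.95
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
      call. = FALSE
    )
  }
  cfg[names(over)] <- over
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a results report with configuration provenance
#'
#' JSON output keeps full precision and embeds the configuration and its
#' hash; CSV output starts with a `# config_hash:` comment line. Field order
#' is deterministic. Human-readable tables are available through
#' [format_report()], which rounds to 2 decimal places.
#'
#' @param results Data frame of results.
#' @param path Output path (`.json` or `.csv`).
#' @param config A [run_config()].
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = run_config()) {
  results <- tibble::as_tibble(results)
  results <- results[, sort(names(results))] # deterministic field order
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        config_hash = attr(config, "hash"),
        config = unclass(config),
        results = results
      ),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash: %s", attr(config, "hash")), con)
    utils::write.csv(results, con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @param digits Decimal places for the formatted table. Default 2.
#' @return `format_report()` returns a data frame of formatted strings.
#' @export
format_report <- function(results, digits = 2) {
  results <- tibble::as_tibble(results)
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) sprintf("%.*f", digits, x))
  as.data.frame(results)
}
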