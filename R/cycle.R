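# Thermodynamic-cycle accounting: assembling per-stage free energy
# contributions into the bound-leg and overall standard binding free
# energies, with symmetry corrections, Boltzmann combination of binding
# poses, replicate aggregation and the preorganization estimate.

#' Symmetry correction for equivalent states excluded by restraints
#'
#' Restraints that confine the ligand to one of `n` equivalent states (for
#' example one binding site of a homotrimer, possibly times a ligand symmetry
#' multiplicity) remove a factor `n` of configurational volume; the
#' correction is `-kB T log(n)`. It is exactly additive over factorisations:
#' `symmetry_correction(n * m) = symmetry_correction(n) +
#' symmetry_correction(m)`.
#'
#' @param equivalent_states Integer count >= 1 (product of site and ligand
#'   symmetry multiplicities).
#' @param context A [thermo_context()].
#' @return Correction in kcal mol⁻¹ (0 for a single state, negative
#'   otherwise).
#' @examples
#' symmetry_correction(3) # three equivalent sites: ~ -0.65 at 298 K
#' symmetry_correction(6) # plus a two-fold ligand symmetry: ~ -1.06
#' @export
symmetry_correction <- function(equivalent_states,
                                context = thermo_context()) {
  context <- as_thermo_context(context)
  if (any(equivalent_states < 1) ||
    any(abs(equivalent_states - round(equivalent_states)) > 1e-9)) {
    stop("equivalent_states must be an integer >= 1", call. = FALSE)
  }
  -context$kT * log(equivalent_states)
}

.scheme_labels <- list(
  boresch_or_naive = c(
    "Release", "Bound.Vanish", "Bound.Discharge", "Bound.Restrain",
    "Sym.Corr."
  ),
  intramol_rigid = c(
    "Release", "Bound.Vanish", "Bound.Discharge", "Bound.Restrain",
    "Sym.Corr.", "Rigid.Lig.", "Rigid.Recept.", "Rigid.Complex"
  ),
  release_to_single = c(
    "Release", "Bound.Vanish", "Bound.Discharge", "Bound.Restrain",
    "Sym.Corr.", "To.Dist.Rest."
  )
)

#' Cycle ledger of bound-leg stage contributions
#'
#' Collects the per-stage free energy contributions of one restraint scheme's
#' bound leg. Values are entered in the table convention: each `value` is the
#' contribution as it enters the bound-leg total (so the release stage is
#' entered as `-dG_release`, a positive number for stiff restraints), with
#' `sign_role = "add"`. A `sign_role` of `"subtract"` flips the sign of a raw
#' stage value instead.
#'
#' Required labels per scheme: all schemes use `Release`, `Bound.Vanish`,
#' `Bound.Discharge`, `Bound.Restrain`, `Sym.Corr.`; `intramol_rigid` adds
#' `Rigid.Lig.`, `Rigid.Recept.`, `Rigid.Complex`; `release_to_single` adds
#' `To.Dist.Rest.`. Each must appear exactly once.
#'
#' @param contributions Data frame with columns `label`, `value`
#'   (kcal mol⁻¹), optionally `uncertainty` (95% CI half-width, >= 0;
#'   defaults to 0, appropriate for deterministic corrections) and
#'   `sign_role` (`"add"`/`"subtract"`, defaults to `"add"`).
#' @param scheme One of `"boresch_or_naive"`, `"intramol_rigid"`,
#'   `"release_to_single"`.
#' @param context A [thermo_context()].
#' @return An object of class `cycle_ledger`.
#' @export
cycle_ledger <- function(contributions,
                         scheme = c(
                           "boresch_or_naive", "intramol_rigid",
                           "release_to_single"
                         ),
                         context = thermo_context()) {
  scheme <- match.arg(scheme)
  context <- as_thermo_context(context)
  contributions <- tibble::as_tibble(contributions)
  stopifnot(all(c("label", "value") %in% names(contributions)))
  if (!"uncertainty" %in% names(contributions)) contributions$uncertainty <- 0
  if (!"sign_role" %in% names(contributions)) contributions$sign_role <- "add"
  contributions$uncertainty[is.na(contributions$uncertainty)] <- 0
  if (any(contributions$uncertainty < 0)) {
    stop("uncertainties must be >= 0", call. = FALSE)
  }
  if (!all(contributions$sign_role %in% c("add", "subtract"))) {
    stop("sign_role must be 'add' or 'subtract'", call. = FALSE)
  }
  required <- .scheme_labels[[scheme]]
  counts <- table(contributions$label)
  missing <- setdiff(required, names(counts))
  if (length(missing)) {
    stop(sprintf(
      "ledger for scheme '%s' is missing label(s): %s",
      scheme, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  dup <- names(counts)[counts > 1]
  if (length(dup)) {
    stop(sprintf("duplicate label(s): %s", paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  unknown <- setdiff(contributions$label, required)
  if (length(unknown)) {
    stop(sprintf(
      "label(s) not allowed for scheme '%s': %s",
      scheme, paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(contributions = contributions, scheme = scheme, context = context),
    class = "cycle_ledger"
  )
}

#' @export
print.cycle_ledger <- function(x, ...) {
  cat(sprintf("<cycle_ledger> scheme: %s\n", x$scheme))
  print(x$contributions)
  invisible(x)
}

#' Assemble the bound-leg free energy from a ledger
#'
#' Sums the signed stage contributions and propagates their 95% CI
#' half-widths in quadrature. The per-term audit trail is attached as
#' attribute `audit` (a tibble with the signed value of every term); the
#' reported value equals the sum of the audit rows exactly.
#'
#' @param ledger A [cycle_ledger()].
#' @return One-row tibble: `value` (dG_Bound°, kcal mol⁻¹), `uncertainty`,
#'   `scheme`, `n_terms`; attribute `audit`.
#' @examples
#' lg <- cycle_ledger(data.frame(
#'   label = c(
#'     "Release", "Bound.Discharge", "Bound.Vanish", "Bound.Restrain",
#'     "Sym.Corr."
#'   ),
#'   value = c(9.76, -2.66, -10.77, -1.90, -1.06)
#' ))
#' assemble_bound_leg(lg) # -6.63
#' @export
assemble_bound_leg <- function(ledger) {
  stopifnot(inherits(ledger, "cycle_ledger"))
  audit <- dplyr::mutate(
    ledger$contributions,
    signed = ifelse(.data$sign_role == "subtract", -.data$value, .data$value)
  )
  out <- tibble::tibble(
    value = sum(audit$signed),
    uncertainty = sqrt(sum(audit$uncertainty^2)),
    scheme = ledger$scheme,
    n_terms = nrow(audit)
  )
  attr(out, "audit") <- audit
  out
}

#' Combine the bound and free legs into the binding free energy
#'
#' `dG_Bind° = dG_Bound° + dG_Free`, uncertainties in quadrature.
#'
#' @param bound,free Each either a numeric vector `c(value, uncertainty)`
#'   (uncertainty optional, default 0) or a one-row data frame with `value`
#'   and `uncertainty` columns (e.g. from [assemble_bound_leg()]).
#' @return One-row tibble: `value`, `uncertainty` (kcal mol⁻¹).
#' @examples
#' assemble_binding(c(-6.89, 0.74), c(-3.08, 0.14))
#' @export
assemble_binding <- function(bound, free) {
  b <- .as_value_unc(bound)
  f <- .as_value_unc(free)
  tibble::tibble(
    value = b[1] + f[1],
    uncertainty = sqrt(b[2]^2 + f[2]^2)
  )
}

.as_value_unc <- function(x) {
  if (is.data.frame(x)) {
    c(x$value[1], if ("uncertainty" %in% names(x)) x$uncertainty[1] else 0)
  } else {
    c(x[1], if (length(x) > 1) x[2] else 0)
  }
}

#' Boltzmann combination of binding poses
#'
#' Combines bound-leg free energies of alternative binding poses:
#' `dG = -kB T log(sum_i exp(-beta dG_i))`. The uncertainty uses first-order
#' propagation with Boltzmann weights `w_i = exp(-beta dG_i) / sum`:
#' `sigma = sqrt(sum w_i^2 sigma_i^2)`. The combined value can never lie
#' above the most favourable pose, and adding a pose never increases it.
#'
#' @param poses Data frame with columns `value` and `uncertainty`
#'   (kcal mol⁻¹), one row per pose (>= 1).
#' @param context A [thermo_context()].
#' @return One-row tibble: `value`, `uncertainty`; attribute `weights`.
#' @examples
#' combine_poses(data.frame(
#'   value = c(-6.28, -6.63),
#'   uncertainty = c(0.49, 1.11)
#' )) # -6.89 +/- 0.74
#' @export
combine_poses <- function(poses, context = thermo_context()) {
  context <- as_thermo_context(context)
  poses <- tibble::as_tibble(poses)
  stopifnot("value" %in% names(poses), nrow(poses) >= 1)
  if (!"uncertainty" %in% names(poses)) poses$uncertainty <- 0
  # factor out the minimum for numerical stability
  g0 <- min(poses$value)
  w_raw <- exp(-context$beta * (poses$value - g0))
  w <- w_raw / sum(w_raw)
  out <- tibble::tibble(
    value = g0 - context$kT * log(sum(w_raw)),
    uncertainty = sqrt(sum(w^2 * poses$uncertainty^2))
  )
  attr(out, "weights") <- w
  out
}

#' Aggregate replicate free energies
#'
#' Mean and Student-t confidence half-width across independent replicate
#' runs, assuming Gaussian scatter: `CI = t_(n-1, 1-alpha/2) * s / sqrt(n)`
#' with the sample SD `s` (for n = 5 and 95% confidence the multiplier is
#' 2.776).
#'
#' @param values Numeric vector of replicate results (n >= 2).
#' @param confidence Confidence level. Default 0.95.
#' @return One-row tibble: `value` (mean), `uncertainty` (CI half-width),
#'   `n`.
#' @export
aggregate_replicates <- function(values, confidence = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least two replicates", call. = FALSE)
  tibble::tibble(
    value = mean(values),
    uncertainty = stats::qt(1 - (1 - confidence) / 2, df = n - 1) *
      stats::sd(values) / sqrt(n),
    n = n
  )
}

#' Preorganization free energy estimate
#'
#' Rough estimate of the cost of straining the receptor and the decoupled
#' ligand into the restrained anchor geometry, from the three rigidification
#' stages of the intramolecular-rigidification scheme:
#' `dG_Preorg ~ dG_Rigid.Recept. + dG_Rigid.Lig. - dG_Rigid.Complex`.
#' Uncertainties are propagated in quadrature. The estimate should be
#' non-negative; a negative value indicates noise and triggers a warning.
#'
#' @param rigid_lig,rigid_recept,rigid_complex Each a numeric
#'   `c(value, uncertainty)` (uncertainty optional) or a one-row data frame
#'   with `value`/`uncertainty`.
#' @return One-row tibble: `value`, `uncertainty`.
#' @examples
#' preorg_estimate(c(0.50, 0.00), c(10.36, 0.09), c(8.31, 0.08)) # 2.55
#' @export
preorg_estimate <- function(rigid_lig, rigid_recept, rigid_complex) {
  l <- .as_value_unc(rigid_lig)
  r <- .as_value_unc(rigid_recept)
  cx <- .as_value_unc(rigid_complex)
  value <- r[1] + l[1] - cx[1]
  if (value < 0) {
    warning(
      "negative preorganization estimate: expected >= 0, likely noise",
      call. = FALSE
    )
  }
  tibble::tibble(
    value = value,
    uncertainty = sqrt(l[2]^2 + r[2]^2 + cx[2]^2)
  )
}
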