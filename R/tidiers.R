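# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Boresch restraint
#'
#' @param x A [boresch_restraint()].
#' @param ... Unused.
#' @return A tibble with one row per degree of freedom: `dof`, `equilibrium`
#'   (Å or degrees), `force_constant`, `units`.
#' @export
tidy.boresch_restraint <- function(x, ...) {
  eq <- x$equilibrium
  tibble::tibble(
    dof = .boresch_dof_names,
    equilibrium = unname(c(eq[["r"]], .rad2deg(eq[-1]))),
    force_constant = unname(x$force_constants),
    units = c("Å", rep("degrees", 5))
  )
}

#' Tidy a distance restraint set
#'
#' @param x A [distance_restraint_set()].
#' @param ... Unused.
#' @return The restraint tibble (one row per pair).
#' @export
tidy.distance_restraint_set <- function(x, ...) x$restraints

#' Tidy / summarise a cycle ledger
#'
#' `tidy()` returns the per-stage audit rows (with signed values);
#' `glance()` returns the assembled bound-leg value and uncertainty.
#'
#' @param x A [cycle_ledger()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cycle_ledger <- function(x, ...) {
  attr(assemble_bound_leg(x), "audit")
}

#' @rdname tidy.cycle_ledger
#' @export
glance.cycle_ledger <- function(x, ...) {
  assemble_bound_leg(x)
}
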